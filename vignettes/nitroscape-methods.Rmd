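---
title: "Methods: phylo-structural analysis of nitrogenase evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylo-structural analysis of nitrogenase evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nitrogenase — the metalloenzyme family that reduces N~2~ to NH~3~ — is one
of the oldest enzymes on Earth, and its major clades (Nif-I, Nif-II,
Nif-III, Vnf, Anf) differ in metal dependence, host ecology and gene-network
complexity. Tracing how the enzyme's *structure* changed across billions of
years requires combining three kinds of evidence: ancestral sequence
reconstruction (ASR) on a rooted phylogeny, large-scale structure
prediction for extant and ancestral sequences, and comparative structural
analysis that maps what it finds back onto the tree.

`nitroscape` implements the analysis side of that programme as a reusable,
tested pipeline. It deliberately does **not** perform structure prediction
or ASR itself — predicted structures (PDB files carrying per-residue pLDDT
in the B-factor column) and site-wise posterior probability tables are
inputs. A fully seeded synthetic-data generator stands in for the GPU
prediction stage, so every downstream method can be validated at desk
scale against planted ground truth.

## Data model

* **Structure** — a flat atom table (chain, author residue number,
  insertion code, atom name, element, coordinates, occupancy, confidence)
  plus a separate ligand table for HETATM records. For predicted models
  the confidence column is pLDDT (0–100); for experimental models it is
  the crystallographic B-factor. Alternate locations are reduced to the
  highest-occupancy conformer on read.
* **Phylogeny** — a rooted `ape::phylo` whose every node (tip and
  internal) carries a unique label; internal labels are the ancestor ids
  that link the tree to posterior tables and predicted structures. Clade
  labels live in a named attribute.
* **PosteriorMatrix** — a sites × 20 matrix of ancestral-state posterior
  probabilities (rows sum to 1), read from either a sparse
  `site AA:prob ...` table or a dense 20-column numeric table.

## Ancestral variants

For each ancestral node the study design carries six sequences:

* **ML** — per site, the state of maximal posterior (ties broken by fixed
  alphabetical order of one-letter codes; the choice is arbitrary but must
  be deterministic);
* **altall** — at every *ambiguous* site (maximum posterior < 0.7, the
  threshold used for the reconstruction, exposed as a parameter), the
  second-most-probable state;
* **alt2–alt5** — at ambiguous sites, states drawn from the full 20-state
  site posterior (not a renormalised top-2): the alternatives are meant to
  sample reconstruction uncertainty, and truncating the posterior would
  understate it. Unambiguous sites always carry the ML state, so every
  variant differs from ML only where the reconstruction is genuinely
  uncertain — this is asserted as a property test.

All sampling flows through an explicit integer seed and restores the
caller's RNG state, so variant sets are exactly reproducible.

`census_counts()` keeps the design's bookkeeping honest: 385 extant
targets and 384 ancestors × (1 ML + 5 alternatives) give 2689 unique
variants; with the two complexes predicted per variant (the HH reductase
homodimer and the DDKK catalytic heterotetramer) that is 5378 structures,
split 770 extant / 4608 ancestral.

## Structure comparison

**Correspondence.** Homologous multimers are matched chain-by-chain
(after template renaming by best sequence identity, greedy and bijective)
with global Needleman–Wunsch alignment under BLOSUM62 and affine gap
penalties 11/1, concatenated in template chain order. Cross-chain
pairings are never produced. A full heuristic structural-alignment search
is out of scope on purpose: nitrogenase homologs are sequence-alignable,
and the metrics — not the aligner — are the object of interest here.

**Superposition.** Kabsch least-squares fitting via SVD of the 3×3
cross-covariance, with the reflection corrected so the rotation is always
proper (det = +1). Degenerate inputs (fewer than 3 atoms, rank < 2) are
rejected. The implementation is checked against a dense SO(3) grid-search
oracle to 10^-3^ Å.

**Metrics.**

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\sum_i^N \left(x_i^{\mathrm{ref}} - x_i\right)^2},
\qquad
\mathrm{RMSD}_{100} = \mathrm{RMSD}\cdot\frac{1}{1 + \ln\sqrt{L/100}},$$

$$\mathrm{TM} = \max\left(\frac{1}{L^{\mathrm{ref}}}\sum_i^{L}
  \frac{1}{1 + (d_i/d_0(L^{\mathrm{ref}}))^2}\right),
\qquad d_0(L) = 1.24\,(L-15)^{1/3} - 1.8 .$$

RMSD is computed on Cα coordinates by default (all shared atoms
optionally, for crystal comparisons). RMSD~100~ removes the alignment-
length bias of RMSD and equals it at L = 100. The TM-score maximisation
is approximated by iterative superposition: fit on all aligned pairs,
then repeatedly re-fit on the pairs currently closer than 8 Å, keeping
the best score (≤ 10 iterations, 10^-4^ convergence). The d~0~ floor is
0.5 Å; d~0~ is undefined below L ≈ 15, so L ≥ 20 is required.

**Refined-core RMSD.** `rmsd()` exposes the same iterative d < 8 Å
refinement (off by default). All-vs-all matrices use it by default:
structural aligners report RMSD over the structurally aligned core, and
with a purely sequence-guided correspondence a single stray gap placement
at an insertion boundary can contribute one huge inter-residue distance
that dominates an otherwise sub-Ångström comparison. Both modes are
exported; pairwise TM-scores are normalised by the longer partner of each
pair so the matrix is exactly symmetric.

**Local comparisons.** `per_residue_deviation()` returns Cα–Cα distances
after the global fit (their root mean square reproduces the superposition
RMSD exactly — an identity used as a test); `local_site_rmsd()` re-fits
only the residues within a radius of a named site (e.g. the FeMoco or
P-cluster environment) so active-site conservation can be scored
independently of global drift.

## Structural attributes

* **SASA** — Shrake–Rupley quadrature with a deterministic golden-spiral
  point set (960 points/atom, probe 1.4 Å), van der Waals radii from a
  small element table that includes the metals found in nitrogenase
  cofactors. Verified against the analytic sphere area within 2%.
* **Radius of gyration** — unweighted, Cα or all atoms.
* **Charged fraction** — D, E, K, R over all subunits; histidine is
  excluded from the default charged set (borderline pK~a~), configurable.
* **Interface contacts** — a residue pair across two chain groups counts
  once if any heavy-atom pair is within 5.5 Å, classified by residue-class
  pair with the contact model's convention (charged includes H; apolar
  A V L I M F W P G C; polar the rest).
* **Binding-affinity score** — the published linear contact-based model:
  ΔG = −0.09459·IC~cc~ − 0.10007·IC~ca~ + 0.19577·IC~pp~ − 0.22671·IC~pa~
  + 0.18681·%NIS~apolar~ + 0.13810·%NIS~charged~ − 15.9433, where the
  non-interacting surface (NIS) is the set of residues with relative SASA
  ≥ 5% taking part in no interface contact. The model is exactly linear
  in its features (asserted as a test), and lower values mean stronger
  predicted binding.
* **Contact networks** — Cα-distance graph (6.5 Å, sequence separation
  ≥ 2 within a chain); only summary counts are consumed downstream, so
  typed interactions (H-bond, π–π geometry) are not modelled.
* **GNM modes** — Kirchhoff (graph-Laplacian) matrix of the Cα contact
  graph at 7.5 Å; a connected graph has exactly one zero eigenvalue
  (multiplicity equals the number of components — the function refuses
  disconnected graphs and names the component count); residue
  fluctuations come from the pseudo-inverse diagonal and the slowest
  nonzero mode is reported per residue.

## Phylogenetic mapping

Root distances are path sums of branch lengths (root = 0). Attribute–
depth association uses Spearman rank correlation (average ranks for
ties) with a seeded permutation p-value — no analytic approximation, the
sample sizes here make permutation exact enough and assumption-free.
Structure-distance matrices are clustered with average linkage; clade
recovery is scored with the adjusted Rand index computed from the
contingency table (checked against an independent implementation).

**Insertion events.** Alignment columns containing gaps are merged into
blocks while adjacent columns have similar presence sets — Jaccard ≥ 0.9
*or* one set nested in the other. The nesting rule is what keeps a
progressively elongating terminal extension (the K-subunit N-terminus
style, ~8 → ~40 residues) a *single* block: its columns have strictly
nested presence, and splitting it would turn one evolutionary event into
several. Blocks shorter than 5 columns are discarded (micro-indels are
alignment noise at this scale; the events of interest are ≥ ~8 residues).
Presence/absence of each block is then mapped onto the tree: read
directly from ancestral alignment rows when the alignment has them,
otherwise reconstructed by Fitch parsimony with ties resolved by
preferring absence at the root — so clade-restricted blocks are explained
as insertions rather than ancient presence plus repeated deletion
whenever the change count allows. Every edge where the state flips is an
event (0→1 insertion, 1→0 deletion) attributed to the child branch.
`length_trajectory()` counts block residues for every node on a
root-to-tip path, which is how progressive elongation is exhibited.
Intervals are 0-based and half-open throughout.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with full ground truth:

* a Yule-topology tree with exponential branch lengths, cut into labelled
  clades (default 24 leaves, 4 clades — standing in for the major
  nitrogenase groups at desk scale);
* sequences evolved by a per-branch Poisson substitution process (uniform
  over the 19 alternatives, positions drawn with replacement so sites can
  revert) from a 120-residue root, with three planted clade-specific
  insertions mirroring the studied events: a 60-residue C-terminal
  extension, a 55-residue internal insertion, and an N-terminal extension
  elongating 8 → 20 → 40 along the deepest lineage of the clade that can
  host the schedule;
* Cα toy structures built as an ideal helix in alignment-column space
  plus clade-level noise (σ = 1.5 Å) and node-level noise (σ = 0.3 Å) —
  the 5× ratio makes between-clade divergence dominate within-clade
  divergence, which is the regime in which clustering is expected to
  recover the clades exactly;
* posterior matrices with a controlled ambiguous-site fraction (default
  0.15; ambiguous sites put 0.4–0.7 on the true state with the remainder
  on 2–3 decoys).

What it does **not** emulate: real folds (structures are helices — only
divergence geometry matters downstream), indel rate heterogeneity,
realistic pLDDT error structure (confidence is a constant column), or an
empirical substitution model (the analysis consumes divergence structure,
not LG parameters). Passing tests on this generator therefore validate
the *algorithms* — recovery of planted signal under the assumed noise
model — not the biological realism of any particular dataset.

`build_toy_structure()` itself renders a plain ideal helix (rise 1.5 Å,
radius 2.3 Å, 100° twist); insertion geometry is realised by the dataset
generator's column-space construction rather than by per-sequence loop
modelling, which keeps the helix-spacing invariant exact and the
structural consequence of an insertion (extra, divergent coordinates)
where the downstream methods actually see it.

## Numerical choices and degenerate inputs

* Ties in argmax operations (ML state, second state, chain assignment)
  are broken by fixed alphabetical/input order — never RNG.
* Posterior rows must sum to 1 within 10^-3^ on read (10^-6^ for
  constructed matrices); violations name the offending site.
* Kabsch refuses n < 3 and rank-deficient configurations; RMSD~100~
  refuses L ≤ 13 (denominator ≤ 0); TM-score refuses L^ref^ < 20.
* Confidence trimming removes terminal runs only, so author residue
  numbering stays valid for downstream alignment; a chain entirely below
  threshold is removed with a warning. The pLDDT threshold (default 70)
  is a parameter because no single value is canonical.
* The pipeline (`run_pipeline()`) is a pure function of inputs, config
  and seed; its manifest records an md5 per output so reruns can be
  verified byte-identical.

## Problem sizes

The shipped defaults are sized for interactive use and continuous
testing: 24-leaf/4-clade datasets (47 structures, ~280 alignment
columns), 276-pair all-vs-all matrices, 10 000-draw sampling checks, and
100-replicate sign-recovery experiments on 80-leaf trees. All of these
run in seconds to a couple of minutes on one CPU; the same code paths
scale to the full 769-node, 5378-structure design unchanged, since every
stage is O(pairs × residues) or better.

## Known limitations

* Correspondence is sequence-guided; at very low sequence identity a
  true structural aligner would recover better correspondences. The
  refined-core mode mitigates, but does not remove, this.
* The TM-score maximisation is a local iterative scheme seeded from the
  global-fit superposition, not a full heuristic search; on pathological
  inputs it can undershoot the true maximum.
* Interface classification uses a single heavy-atom cutoff; no
  solvent-mediated or typed interactions.
* Metal cofactors are carried as ligand records but play no role in any
  computation (consistent with predictors that ignore them).
* mmCIF is not read; PDB fixed-column is the canonical structure format
  here.
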