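# Ancestral sequence variants from site-wise posterior distributions.
#
# For every ancestral node the study design carries six sequences: the
# maximum-likelihood ancestor ("ml"), the "altall" sequence taking the
# second-most-probable state at every ambiguous site (maximum posterior
# below the ambiguity threshold, 0.7 by default), and four sequences drawn
# by sampling the full site posterior at ambiguous sites ("alt2".."alt5").

# argmax with fixed alphabetical tie-break (columns are in AA_ALPHABET order)
.site_argmax <- function(p, rank = 1L) {
  apply(p, 1, function(row) {
    ord <- order(-row, AA_ALPHABET)  # prob desc, then alphabet
    AA_ALPHABET[ord[rank]]
  })
}

#' Maximum-likelihood ancestral sequence
#'
#' Per site, the amino acid of maximal posterior probability; ties broken
#' by fixed alphabetical order of one-letter codes.
#'
#' @param p a `posterior_matrix`
#' @return a single sequence string
#' @export
ml_sequence <- function(p) {
  if (!inherits(p, "posterior_matrix")) stopf("`p` must be a posterior_matrix")
  paste(.site_argmax(unclass(p)), collapse = "")
}

#' "altall" alternative ancestral sequence
#'
#' A site is ambiguous iff its maximum posterior is below `threshold`;
#' ambiguous sites take the second-most-probable state, all other sites the
#' ML state.
#'
#' @param p a `posterior_matrix`
#' @param threshold ambiguity threshold in (0, 1]; default 0.7
#' @return a single sequence string
#' @export
altall_sequence <- function(p, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  m <- unclass(p)
  ml <- .site_argmax(m)
  second <- .site_argmax(m, rank = 2L)
  amb <- apply(m, 1, max) < threshold
  paste(ifelse(amb, second, ml), collapse = "")
}

#' Ambiguous-site mask of a posterior matrix
#' @param p a `posterior_matrix`
#' @param threshold ambiguity threshold
#' @return logical vector, TRUE where max posterior < threshold
#' @export
ambiguous_sites <- function(p, threshold = 0.7)
  apply(unclass(p), 1, max) < threshold

#' Sample alternative ancestral sequences from the posterior
#'
#' Unambiguous sites carry the ML state; at each ambiguous site a state is
#' drawn from the full 20-state site posterior. Output is reproducible for
#' identical seeds.
#'
#' @param p a `posterior_matrix`
#' @param n number of sequences to draw (>= 1)
#' @param seed integer seed
#' @param threshold ambiguity threshold; default 0.7
#' @return character vector of `n` sequences
#' @export
sample_variant_sequences <- function(p, n, seed, threshold = 0.7) {
  if (n < 1) stopf("n must be >= 1")
  m <- unclass(p)
  ml <- .site_argmax(m)
  amb <- which(apply(m, 1, max) < threshold)
  with_seed(seed, {
    draws <- matrix(rep(ml, each = n), nrow = n)
    for (s in amb)
      draws[, s] <- sample(AA_ALPHABET, n, replace = TRUE, prob = m[s, ])
    apply(draws, 1, paste, collapse = "")
  })
}

#' Build the full six-sequence variant set for an ancestral node
#'
#' @param p a `posterior_matrix`
#' @param seed integer seed for the sampled variants
#' @param n_alt number of sampled variants (default 4, giving ml + altall +
#'   alt2..alt5 = 1 ML + 5 alternatives)
#' @param threshold ambiguity threshold; default 0.7
#' @return list with fields node_id, ml, altall, alts (named alt2..),
#'   seed, ambiguity_threshold
#' @export
build_variant_set <- function(p, seed, n_alt = 4, threshold = 0.7) {
  node <- attr(p, "node_id")
  alts <- sample_variant_sequences(p, n_alt, seed = seed,
                                   threshold = threshold)
  names(alts) <- paste0("alt", seq_len(n_alt) + 1L)
  structure(list(node_id = node,
                 ml = ml_sequence(p),
                 altall = altall_sequence(p, threshold),
                 alts = alts, seed = seed,
                 ambiguity_threshold = threshold),
            class = "variant_set")
}

#' Variant set as a named sequence vector (FASTA-ready)
#' @param vs a `variant_set`
#' @return named character vector `<node>_ml`, `<node>_altall`,
#'   `<node>_alt2` ...
#' @export
variant_sequences <- function(vs) {
  stats::setNames(c(vs$ml, vs$altall, unname(vs$alts)),
                  paste0(vs$node_id, "_", c("ml", "altall", names(vs$alts))))
}

#' Pipeline census: variant and structure counts of the study design
#'
#' With `n_extant` extant targets (one sequence each), `n_ancestral_nodes`
#' ancestors carrying 1 ML + `n_alt_per_ancestor` alternative sequences,
#' and `n_complexes_per_variant` multimeric complexes predicted per
#' sequence (HH and DDKK: 2), returns the total variant and structure
#' counts and their extant/ancestral split.
#'
#' @param n_extant extant sequence targets
#' @param n_ancestral_nodes ancestral nodes
#' @param n_alt_per_ancestor alternative sequences per ancestor
#' @param n_complexes_per_variant complexes predicted per variant
#' @return list: n_variants, n_structures, n_extant_structures,
#'   n_ancestral_structures
#' @export
census_counts <- function(n_extant, n_ancestral_nodes,
                          n_alt_per_ancestor, n_complexes_per_variant) {
  cnt <- c(n_extant, n_ancestral_nodes, n_alt_per_ancestor,
           n_complexes_per_variant)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stopf("census fields must be non-negative integers")
  n_anc_variants <- n_ancestral_nodes * (1 + n_alt_per_ancestor)
  list(n_variants = n_extant + n_anc_variants,
       n_structures = (n_extant + n_anc_variants) * n_complexes_per_variant,
       n_extant_structures = n_extant * n_complexes_per_variant,
       n_ancestral_structures = n_anc_variants * n_complexes_per_variant)
}
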