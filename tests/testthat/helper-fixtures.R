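# Fixture builders used across the suite. Everything is constructed in
# code; no binary data.

# Calpha-only structure from a coordinate matrix
mk_ca_structure <- function(coords, aa = NULL, chain = "A", id = "fix",
                            confidence = 90,
                            model_kind = "predicted", resno = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("G", n)
  if (is.null(resno)) resno <- seq_len(n)
  resname <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
               G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
               M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
               S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")[aa]
  new_structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", chain = chain,
    resno = resno, insert = "", resname = unname(resname),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, confidence = confidence, stringsAsFactors = FALSE),
    id = id, model_kind = model_kind)
}

# small two-chain all-atom complex: each residue gets N, CA, C, O placed
# around a backbone point; chains run antiparallel `gap` Angstrom apart
mk_dimer <- function(n_res = 6, gap = 4, id = "dimer",
                     aa_a = rep("K", n_res), aa_b = rep("D", n_res)) {
  one_chain <- function(chain, aa, y0, serial0) {
    rows <- list()
    offs <- rbind(N = c(-0.7, 0.6, 0), CA = c(0, 0, 0),
                  C = c(0.7, 0.6, 0), O = c(0.9, 1.7, 0))
    for (i in seq_along(aa)) for (at in rownames(offs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial0 + length(rows), name = at,
        element = substr(at, 1, 1), chain = chain, resno = i, insert = "",
        resname = c(K = "LYS", D = "ASP", G = "GLY", S = "SER",
                    L = "LEU", R = "ARG", E = "GLU", N = "ASN")[aa[i]],
        x = 3.8 * (i - 1) + offs[at, 1], y = y0 + offs[at, 2],
        z = offs[at, 3], occupancy = 1, confidence = 90,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  atoms <- rbind(one_chain("D", aa_a, 0, 1),
                 one_chain("K", aa_b, gap, 1000))
  new_structure(atoms, id = id, model_kind = "predicted")
}

# hand-written minimal PDB text, two chains, used for parser tests
toy_pdb_lines <- function() c(
  "HEADER    TOY COMPLEX",
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 90.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 91.20           C",
  "ATOM      3  C   ALA A   1      10.938   6.992  -4.147  1.00 90.00           C",
  "ATOM      4  CA  GLY A   2      11.639   9.071  -2.147  1.00 88.00           C",
  "ATOM      5  CA  LYS B  -1       1.500   2.000   3.000  1.00 95.00           C",
  "ATOM      6  CA  ASP B   0       4.500   2.000   3.000  1.00 96.50           C",
  "HETATM    7 FE   FES B 101       2.000   0.000   0.000  1.00 30.00          FE",
  "END")

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}
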