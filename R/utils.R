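# Shared constants and small internal helpers.

# One-letter amino-acid alphabet in fixed alphabetical order; this order is
# the tie-break everywhere a "first by alphabet" rule applies.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M")

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Default charged set excludes histidine (configurable in callers).
AA_CHARGED <- c("D", "E", "K", "R")

# Residue classes used by the interface-contact / affinity model
# (charged includes H there, following the upstream contact model).
AA_CLASS_CHARGED <- c("D", "E", "K", "R", "H")
AA_CLASS_APOLAR  <- c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C")
AA_CLASS_POLAR   <- c("N", "Q", "S", "T", "Y")

#' Residue class ("charged", "polar", "apolar") of one-letter codes
#' @param aa character vector of one-letter amino-acid codes
#' @return character vector of classes; NA for non-standard letters
#' @keywords internal
residue_class <- function(aa) {
  out <- rep(NA_character_, length(aa))
  out[aa %in% AA_CLASS_CHARGED] <- "charged"
  out[aa %in% AA_CLASS_APOLAR]  <- "apolar"
  out[aa %in% AA_CLASS_POLAR]   <- "polar"
  out
}

# van der Waals radii (Angstrom) by element, protein/metallocluster scope.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  SE = 1.90, FE = 2.00, MO = 2.00, V = 2.00, MG = 1.73, ZN = 1.39,
  MN = 2.00, CA = 2.00, "NA" = 2.27, K = 2.75, CL = 1.75)

# Theoretical maximum solvent accessibility per residue (Angstrom^2),
# Tien et al. (2013)-style values, used for relative SASA.
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

#' Run code with a temporarily seeded RNG, restoring global state after
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Translate three-letter residue names to one-letter codes
#' @param resnames character vector of 3-letter codes
#' @return one-letter codes, "X" for unknown names
#' @keywords internal
three_to_one <- function(resnames) {
  out <- unname(AA_THREE_TO_ONE[toupper(resnames)])
  out[is.na(out)] <- "X"
  out
}
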