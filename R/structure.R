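# The in-memory structure model: a flat atom table plus metadata.
#
# A `nitro_structure` is a list with
#   id         - character identifier
#   model_kind - "predicted" or "experimental"
#   atoms      - data.frame: serial, name, element, chain, resno, insert,
#                resname, x, y, z, occupancy, confidence
#   ligands    - data.frame with the same columns (HETATM records)
# For predicted models `confidence` carries the per-residue pLDDT (0-100)
# read from / written to the B-factor column; for experimental models it is
# the crystallographic B-factor.

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns serial, name, element, chain, resno,
#'   insert, resname, x, y, z, occupancy, confidence
#' @param id structure identifier
#' @param model_kind "predicted" or "experimental"
#' @param ligands optional data.frame of HETATM records (same columns)
#' @return object of class `nitro_structure`
#' @export
new_structure <- function(atoms, id = "structure",
                          model_kind = c("predicted", "experimental"),
                          ligands = NULL) {
  model_kind <- match.arg(model_kind)
  need <- c("serial", "name", "element", "chain", "resno", "insert",
            "resname", "x", "y", "z", "occupancy", "confidence")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stopf("structure '%s' has no atoms", id)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in structure '%s'", id)
  if (any(nchar(atoms$chain) != 1L))
    stopf("chain ids must be single characters")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate (chain, residue, atom) key in structure '%s'", id)
  if (model_kind == "predicted" &&
      (any(atoms$confidence < 0) || any(atoms$confidence > 100)))
    stopf("predicted-model confidence (pLDDT) must lie in [0, 100]")
  if (is.null(ligands)) ligands <- atoms[0, , drop = FALSE]
  structure(list(id = id, model_kind = model_kind,
                 atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 ligands = as.data.frame(ligands, stringsAsFactors = FALSE)),
            class = "nitro_structure")
}

#' @export
print.nitro_structure <- function(x, ...) {
  cat(sprintf("<nitro_structure '%s' (%s): %d atoms, %d chains, %d residues>\n",
              x$id, x$model_kind, nrow(x$atoms),
              length(chain_ids(x)), n_residues(x)))
  invisible(x)
}

#' Chain identifiers of a structure, in order of first appearance
#' @param s a `nitro_structure`
#' @return character vector of chain ids
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

# Residue keys: "chain|resno|insert" uniquely identify a residue.
residue_key <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", "", insert),
        sep = "|")
}

#' Per-residue table of a structure (one row per residue, CA-based)
#'
#' @param s a `nitro_structure`
#' @param chain optional chain id filter
#' @return data.frame: key, chain, resno, insert, resname, aa (one-letter),
#'   x, y, z (CA coordinates), confidence (CA confidence)
#' @export
residue_table <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  ca <- a[a$name == "CA", , drop = FALSE]
  data.frame(key = residue_key(ca$chain, ca$resno, ca$insert),
             chain = ca$chain, resno = ca$resno, insert = ca$insert,
             resname = ca$resname, aa = three_to_one(ca$resname),
             x = ca$x, y = ca$y, z = ca$z, confidence = ca$confidence,
             stringsAsFactors = FALSE)
}

n_residues <- function(s) nrow(residue_table(s))

#' One-letter sequence of each chain (CA-bearing residues, file order)
#' @param s a `nitro_structure`
#' @return named character vector, one gapless sequence per chain
#' @export
chain_sequences <- function(s) {
  rt <- residue_table(s)
  vapply(chain_ids(s), function(ch)
    paste(rt$aa[rt$chain == ch], collapse = ""), character(1))
}

#' Cα coordinate matrix of a structure
#' @param s a `nitro_structure`
#' @param chain optional chain filter
#' @return n x 3 matrix with residue keys as rownames
#' @export
ca_coords <- function(s, chain = NULL) {
  rt <- residue_table(s, chain)
  m <- as.matrix(rt[, c("x", "y", "z")])
  rownames(m) <- rt$key
  m
}
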