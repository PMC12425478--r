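# PDB reading/writing (fixed-column), backed by bio3d.

#' Read a PDB file into a structure object
#'
#' ATOM records become the atom table; HETATM records (cofactors, waters)
#' are retained in a separate `ligands` table. Insertion codes and author
#' residue numbering are preserved. Alternate locations are reduced to the
#' highest-occupancy conformer. The B-factor column is read into
#' `confidence`: for predicted models it is interpreted as per-residue
#' pLDDT (0-100).
#'
#' @param path path to a PDB file
#' @param id structure identifier; defaults to the file base name
#' @param model_kind "predicted", "experimental", or "auto" (predicted iff
#'   all B-factors lie in [0, 100])
#' @return a [new_structure()] object
#' @export
read_pdb <- function(path, id = NULL, model_kind = "auto") {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stopf("no ATOM/HETATM records in '%s'", path)
  # pre-scan coordinate fields so malformed input fails with a line number
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(
      c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
        substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stopf("malformed coordinate field at line %d of '%s'", i, path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {  # derive element from the atom name when absent
    nm <- gsub("[0-9']", "", a$elety[bad])
    elem[bad] <- ifelse(toupper(nm) %in% names(VDW_RADII) & nchar(nm) > 1,
                        toupper(nm), substr(nm, 1, 1))
  }
  tab <- data.frame(serial = a$eleno, name = a$elety, element = toupper(elem),
                    chain = a$chain, resno = a$resno, insert = a$insert,
                    resname = a$resid, x = a$x, y = a$y, z = a$z,
                    occupancy = a$o, confidence = a$b,
                    type = a$type, alt = ifelse(is.na(a$alt), "", a$alt),
                    stringsAsFactors = FALSE)
  # alternate locations: keep the highest-occupancy conformer per atom
  key <- paste(tab$type, tab$chain, tab$resno, tab$insert, tab$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -tab$occupancy, seq_len(nrow(tab)))
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(key[ord]), , drop = FALSE]
    tab <- tab[order(tab$serial), , drop = FALSE]
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  if (model_kind == "auto")
    model_kind <- if (all(tab$confidence >= 0 & tab$confidence <= 100))
      "predicted" else "experimental"
  atoms <- tab[tab$type == "ATOM", setdiff(names(tab), c("type", "alt")),
               drop = FALSE]
  ligs <- tab[tab$type == "HETATM", setdiff(names(tab), c("type", "alt")),
              drop = FALSE]
  if (nrow(atoms) == 0L) stopf("no ATOM records in '%s'", path)
  new_structure(atoms, id = id, model_kind = model_kind, ligands = ligs)
}

#' Write a structure object to a fixed-column PDB file
#'
#' `confidence` is written to the B-factor column with two decimals.
#'
#' @param s a `nitro_structure`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "nitro_structure")) stopf("`s` must be a nitro_structure")
  a <- rbind(cbind(s$atoms, type = "ATOM"),
             if (nrow(s$ligands)) cbind(s$ligands, type = "HETATM"))
  if (nrow(a) == 0L) stopf("refusing to write a structure with 0 atoms")
  if (any(nchar(a$chain) != 1L)) stopf("chain ids must be single characters")
  bio3d::write.pdb(pdb = NULL, file = path, type = a$type,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occupancy, b = a$confidence, elesy = a$element,
                   verbose = FALSE)
  invisible(path)
}
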