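# FASTA / A3M sequence IO and alignment (MSA) helpers.

#' Read a FASTA or A3M file
#'
#' A3M conventions are normalised on read: lowercase insert states are
#' uppercased and '.' gap characters become '-'.
#'
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("\\.", "-", as.character(set)))
  names(seqs) <- ids
  seqs
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap width
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stopf("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a gapped alignment (equal row lengths, unique ids)
#' @param msa named character vector of gapped sequences
#' @return `msa`, invisibly, after validation
#' @export
validate_msa <- function(msa) {
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stopf("alignment rows must carry unique names")
  if (length(unique(nchar(msa))) != 1L)
    stopf("alignment rows differ in length")
  invisible(msa)
}

#' Alignment as a character matrix (rows = sequences, cols = columns)
#' @param msa named character vector of equal-length gapped sequences
#' @return character matrix with row names
#' @export
msa_matrix <- function(msa) {
  validate_msa(msa)
  m <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Remove gaps from a gapped sequence
#' @param x character vector of gapped sequences
#' @return ungapped sequences
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
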