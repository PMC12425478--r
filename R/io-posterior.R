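# Site-wise ancestral-state posterior tables.
#
# A posterior matrix is a sites x 20 numeric matrix (columns = one-letter
# amino acids in fixed alphabetical order) with attribute "node_id" and
# class "posterior_matrix". Rows are indexed by ungapped ancestral site.

#' Construct and validate a posterior matrix
#' @param probs sites x 20 numeric matrix; columns named by one-letter codes
#' @param node_id ancestral node identifier
#' @param tol row-sum tolerance
#' @return a `posterior_matrix`
#' @export
new_posterior_matrix <- function(probs, node_id, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L) stopf("posterior matrix must have 20 columns")
  if (is.null(colnames(probs))) colnames(probs) <- AA_ALPHABET
  probs <- probs[, AA_ALPHABET, drop = FALSE]
  if (nrow(probs) == 0L) stopf("posterior matrix has no sites")
  if (any(probs < 0) || any(probs > 1))
    stopf("posterior probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(probs) - 1) > tol)
  if (length(bad))
    stopf("posterior row(s) not summing to 1: site %s",
          paste(bad, collapse = ", "))
  structure(probs, node_id = node_id, class = c("posterior_matrix", "matrix"))
}

#' Read a site-wise posterior probability table
#'
#' Two tab/space-separated dialects are accepted:
#' * sparse, rst-like: `site<TAB>AA:prob<TAB>AA:prob ...` — unlisted amino
#'   acids get probability 0;
#' * dense: a numeric table of 20 columns (optionally preceded by a site
#'   column), with a header row of one-letter codes or none.
#'
#' @param path file path
#' @param node_id ancestral node id; defaults to the file base name
#' @param tol row-sum tolerance (rows must sum to 1 within `tol`)
#' @return a `posterior_matrix`
#' @export
read_posterior_table <- function(path, node_id = NULL, tol = 1e-3) {
  if (!file.exists(path)) stopf("posterior table not found: %s", path)
  if (is.null(node_id)) node_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) stopf("empty posterior table: %s", path)
  sparse <- grepl("[A-Y]:", lines[[1]])
  if (sparse) {
    rows <- lapply(seq_along(lines), function(i) {
      tok <- strsplit(lines[[i]], "[\t ]+")[[1]]
      pairs <- tok[grepl(":", tok, fixed = TRUE)]
      aa <- sub(":.*$", "", pairs)
      pr <- suppressWarnings(as.numeric(sub("^.*:", "", pairs)))
      if (anyNA(pr) || !all(aa %in% AA_ALPHABET))
        stopf("malformed posterior entry at line %d of '%s'", i, path)
      v <- stats::setNames(numeric(20), AA_ALPHABET)
      v[aa] <- pr
      v
    })
    probs <- do.call(rbind, rows)
  } else {
    has_header <- grepl("[A-Za-z]", lines[[1]])
    if (has_header) {
      hdr <- strsplit(lines[[1]], "[\t ]+")[[1]]
      lines <- lines[-1]
    }
    num <- lapply(lines, function(l)
      suppressWarnings(as.numeric(strsplit(l, "[\t ]+")[[1]])))
    wid <- unique(lengths(num))
    if (length(wid) != 1L || !wid %in% c(20L, 21L))
      stopf("dense posterior table must have 20 (or site + 20) columns")
    probs <- do.call(rbind, num)
    if (wid == 21L) probs <- probs[, -1, drop = FALSE]
    colnames(probs) <- if (has_header) utils::tail(hdr, 20) else AA_ALPHABET
  }
  new_posterior_matrix(probs, node_id = node_id, tol = tol)
}

#' Write a posterior matrix in the dense 20-column dialect
#' @param p a `posterior_matrix`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_posterior_table <- function(p, path) {
  m <- unclass(p)
  attr(m, "node_id") <- NULL
  utils::write.table(
    data.frame(site = seq_len(nrow(m)), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
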