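# All-vs-all structure similarity matrices.

#' Pairwise structure-similarity matrix
#'
#' Computes every unordered pair with the chosen metric. The diagonal is 0
#' for rmsd/rmsd100 and 1 for tm. TM-scores are normalized by the longer
#' structure of each pair so the matrix is exactly symmetric. RMSD-type
#' entries are computed over the structurally consistent core of each
#' correspondence (`refine = TRUE` by default), the way all-vs-all RMSD
#' matrices from structural aligners are reported. A pair that fails to
#' align is recorded as NA (missing), never silently as zero.
#'
#' @param structures named list of `nitro_structure` objects (names become
#'   row/column ids; unnamed lists use structure ids)
#' @param metric "rmsd", "tm", or "rmsd100"
#' @param atoms atom selection for rmsd-type metrics
#' @param refine iterative-core refinement for rmsd-type metrics (see
#'   [rmsd()])
#' @return symmetric numeric matrix with id dimnames
#' @export
pairwise_matrix <- function(structures, metric = c("rmsd", "tm", "rmsd100"),
                            atoms = "ca", refine = TRUE) {
  metric <- match.arg(metric)
  if (length(structures) < 2) stopf("need at least 2 structures")
  ids <- names(structures)
  if (is.null(ids)) ids <- vapply(structures, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate structure ids")
  n <- length(structures)
  M <- matrix(if (metric == "tm") 1 else 0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    val <- tryCatch({
      ap <- sequence_correspondence(structures[[i]], structures[[j]])
      switch(metric,
             rmsd = rmsd(structures[[i]], structures[[j]], ap,
                         atoms = atoms, refine = refine),
             rmsd100 = {
               r <- .rmsd_core(structures[[i]], structures[[j]], ap,
                               atoms = atoms, refine = refine)
               rmsd100(r$rmsd, r$n)
             },
             tm = tm_score(structures[[i]], structures[[j]], ap,
                           normalize_by = "longer"))
    }, error = function(e) {
      warnf("pair (%s, %s) failed: %s", ids[i], ids[j], conditionMessage(e))
      NA_real_
    })
    M[i, j] <- M[j, i] <- val
  }
  M
}

#' Write a similarity matrix as TSV with id header row/column
#' @param m matrix from [pairwise_matrix()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_matrix_tsv()]
#' @param path TSV path
#' @return numeric matrix with id dimnames
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
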