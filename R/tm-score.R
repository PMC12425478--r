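# TM-score: length-normalized structural similarity in [0, 1].
#
#   TM = max over superpositions of (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)
#
# with d0 the size-dependent normalization d0(L) = 1.24 (L-15)^(1/3) - 1.8
# (floored at 0.5 Angstrom). The maximization is approximated by iterative
# superposition: superpose on all aligned pairs, then repeatedly
# re-superpose on the pairs currently closer than a distance cutoff,
# keeping the best score seen.

#' TM-score normalization distance d0
#' @param L normalization length (residues), must be >= 20
#' @param floor lower bound in Angstrom
#' @return d0 in Angstrom
#' @export
tm_d0 <- function(L, floor = 0.5) {
  if (L < 20) stopf("d0 undefined for L < 20 (got %d)", L)
  max(1.24 * (L - 15)^(1 / 3) - 1.8, floor)
}

#' TM-score of two aligned structures
#'
#' @param ref,query `nitro_structure` objects
#' @param ap aligned pair from [sequence_correspondence()]
#' @param normalize_by "ref" (default), "query", or "longer" (the longer
#'   of the two, which makes all-vs-all matrices symmetric)
#' @param optimize iterate superpositions to maximize the score (default
#'   TRUE); FALSE evaluates the formula on the coordinates as given,
#'   without any superposition
#' @param cutoff distance cutoff (Angstrom) selecting the pairs kept for
#'   refinement iterations
#' @param max_iter,tol iteration limit and score-convergence tolerance
#' @return TM-score in [0, 1]
#' @export
tm_score <- function(ref, query, ap, normalize_by = c("ref", "query", "longer"),
                     optimize = TRUE, cutoff = 8, max_iter = 10, tol = 1e-4) {
  normalize_by <- match.arg(normalize_by)
  L_norm <- switch(normalize_by,
                   ref = ap$L_ref, query = ap$L_query,
                   longer = max(ap$L_ref, ap$L_query))
  d0 <- tm_d0(L_norm)
  co <- aligned_coords(ref, query, ap, atoms = "ca")
  score_of <- function(d) sum(1 / (1 + (d / d0)^2)) / L_norm
  if (!optimize) {
    d <- sqrt(rowSums((co$ref - co$query)^2))
    return(min(score_of(d), 1))
  }
  sp <- kabsch_superpose(co$ref, co$query)
  d <- sqrt(rowSums((co$ref - apply_superposition(co$query, sp))^2))
  best <- score_of(d)
  prev_keep <- NULL
  for (it in seq_len(max_iter)) {
    keep <- d < cutoff
    if (sum(keep) < 3) break
    if (!is.null(prev_keep) && all(keep == prev_keep)) break
    prev_keep <- keep
    sp <- kabsch_superpose(co$ref[keep, , drop = FALSE],
                           co$query[keep, , drop = FALSE])
    d <- sqrt(rowSums((co$ref - apply_superposition(co$query, sp))^2))
    sc <- score_of(d)
    if (sc > best) {
      if (sc - best < tol) { best <- sc; break }
      best <- sc
    } else break
  }
  min(best, 1)
}
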