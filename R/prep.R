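# Structure preparation: template chain renaming and confidence trimming.

# percent sequence identity between two gapless sequences, via global
# alignment (BLOSUM62, affine 11/1)
chain_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  Biostrings::pid(aln)
}

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

#' Rename chains of a query structure to match a template
#'
#' Each query chain is relabelled with the id of the template chain it best
#' matches by global sequence identity, using greedy bijective assignment
#' (highest identity first; ties broken by input order). This mirrors the
#' bookkeeping step that brings every predicted multimer into a common
#' chain naming before comparison.
#'
#' @param query a `nitro_structure`
#' @param template a `nitro_structure` with the reference chain naming
#' @return the query structure with relabelled chains
#' @export
rename_chains_to_template <- function(query, template) {
  qc <- chain_ids(query); tc <- chain_ids(template)
  if (length(qc) != length(tc))
    stopf("chain-count mismatch: query %d vs template %d",
          length(qc), length(tc))
  qs <- chain_sequences(query); ts <- chain_sequences(template)
  idm <- outer(seq_along(qc), seq_along(tc),
               Vectorize(function(i, j) chain_identity(qs[[i]], ts[[j]])))
  mapping <- rep(NA_character_, length(qc))
  used_q <- used_t <- rep(FALSE, length(qc))
  for (step in seq_along(qc)) {
    m <- idm
    m[used_q, ] <- -Inf; m[, used_t] <- -Inf
    # ties broken by input order: which.max scans row-major over queries first
    best <- arrayInd(which.max(m), dim(m))
    i <- best[1]; j <- best[2]
    mapping[i] <- tc[j]
    used_q[i] <- TRUE; used_t[j] <- TRUE
  }
  if (anyNA(mapping) || anyDuplicated(mapping))
    stopf("chain assignment is not bijective")
  relab <- stats::setNames(mapping, qc)
  out <- query
  out$atoms$chain <- unname(relab[out$atoms$chain])
  if (nrow(out$ligands)) {
    known <- out$ligands$chain %in% names(relab)
    out$ligands$chain[known] <- unname(relab[out$ligands$chain[known]])
  }
  # restore template chain order
  out$atoms <- out$atoms[order(match(out$atoms$chain, tc)), , drop = FALSE]
  out
}

#' Trim low-confidence terminal regions of a predicted structure
#'
#' Removes, per chain, the contiguous run of residues at either terminus
#' whose per-residue mean confidence (pLDDT) falls below `threshold`.
#' Interior residues are never removed and retained coordinates and
#' numbering are untouched. A chain entirely below threshold is removed
#' with a warning.
#'
#' @param s a predicted `nitro_structure`
#' @param threshold pLDDT cutoff in [0, 100] (default 70)
#' @return the trimmed structure
#' @export
trim_low_confidence <- function(s, threshold = 70) {
  if (s$model_kind != "predicted")
    stopf("confidence trimming applies to predicted models only")
  if (threshold < 0 || threshold > 100)
    stopf("threshold must lie in [0, 100]")
  keep_keys <- character(0)
  for (ch in chain_ids(s)) {
    a <- s$atoms[s$atoms$chain == ch, , drop = FALSE]
    keys <- unique(residue_key(a$chain, a$resno, a$insert))
    conf <- vapply(keys, function(k)
      mean(a$confidence[residue_key(a$chain, a$resno, a$insert) == k]),
      numeric(1))
    low <- conf < threshold
    n <- length(keys)
    first <- if (all(low)) n + 1L else which(!low)[1]
    last <- if (all(low)) 0L else max(which(!low))
    if (first > last) {
      warnf("chain %s of '%s' entirely below pLDDT %g; chain removed",
            ch, s$id, threshold)
      next
    }
    keep_keys <- c(keep_keys, keys[first:last])
  }
  akeys <- residue_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  atoms <- s$atoms[akeys %in% keep_keys, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stopf("all residues of '%s' fall below pLDDT %g", s$id, threshold)
  new_structure(atoms, id = s$id, model_kind = s$model_kind,
                ligands = s$ligands)
}
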