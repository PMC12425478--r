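# Residue correspondence between two structures, guided by sequence.
#
# Homologous multimers are matched chain-by-chain (chains must already
# share the template naming; see rename_chains_to_template) with global
# Needleman-Wunsch alignment under BLOSUM62 and affine gap penalties 11/1,
# then concatenated in template chain order. Cross-chain pairings are never
# produced.

#' Residue correspondence between two structures
#'
#' @param ref,query `nitro_structure` objects with matching chain naming
#' @param gap_opening,gap_extension affine gap penalties (positive)
#' @return an `aligned_pair`: list with `ref_id`, `query_id`, `pairs`
#'   (data.frame ref_key/query_key in increasing order), `L` (aligned
#'   pairs), `L_ref`, `L_query` (full residue counts), and `low_coverage`
#'   (TRUE when fewer than 10 pairs aligned)
#' @export
sequence_correspondence <- function(ref, query, gap_opening = 11,
                                    gap_extension = 1) {
  common <- intersect(chain_ids(ref), chain_ids(query))
  if (!length(common))
    stopf("no chain of '%s' maps onto '%s'", query$id, ref$id)
  pairs <- list()
  for (ch in common) {
    rt_r <- residue_table(ref, ch)
    rt_q <- residue_table(query, ch)
    if (!nrow(rt_r) || !nrow(rt_q)) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(rt_r$aa, collapse = "")),
      Biostrings::AAString(paste(rt_q$aa, collapse = "")),
      substitutionMatrix = blosum62(), gapOpening = gap_opening,
      gapExtension = gap_extension, type = "global")
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ri <- qi <- 0L
    idx <- matrix(0L, nrow = 0, ncol = 2)
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ri <- ri + 1L
      if (sa[k] != "-") qi <- qi + 1L
      if (pa[k] != "-" && sa[k] != "-") idx <- rbind(idx, c(ri, qi))
    }
    if (nrow(idx))
      pairs[[ch]] <- data.frame(ref_key = rt_r$key[idx[, 1]],
                                query_key = rt_q$key[idx[, 2]],
                                stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    stopf("no aligned residues between '%s' and '%s'", ref$id, query$id)
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  L <- nrow(pairs)
  out <- structure(list(ref_id = ref$id, query_id = query$id, pairs = pairs,
                        L = L, L_ref = n_residues(ref),
                        L_query = n_residues(query),
                        low_coverage = L < 10),
                   class = "aligned_pair")
  if (out$low_coverage)
    warnf("only %d aligned residue pairs between '%s' and '%s'",
          L, ref$id, query$id)
  out
}

#' Coordinates of the aligned residues of a pair
#'
#' For `atoms = "ca"` one row per aligned residue (its Cα); for "all", all
#' atoms shared by name within each aligned residue pair. Aligned residues
#' with an empty selection are dropped with a warning.
#'
#' @param ref,query `nitro_structure` objects
#' @param ap an `aligned_pair`
#' @param atoms "ca" or "all"
#' @return list of matched matrices `ref` and `query` (rownames: reference
#'   residue keys; for "all", key:atom)
#' @export
aligned_coords <- function(ref, query, ap, atoms = c("ca", "all")) {
  atoms <- match.arg(atoms)
  if (atoms == "ca") {
    rc <- ca_coords(ref); qc <- ca_coords(query)
    ok <- ap$pairs$ref_key %in% rownames(rc) &
      ap$pairs$query_key %in% rownames(qc)
    if (!all(ok))
      warnf("%d aligned residue(s) lack a Calpha atom; dropped", sum(!ok))
    p <- ap$pairs[ok, , drop = FALSE]
    return(list(ref = rc[p$ref_key, , drop = FALSE],
                query = qc[p$query_key, , drop = FALSE]))
  }
  rk <- residue_key(ref$atoms$chain, ref$atoms$resno, ref$atoms$insert)
  qk <- residue_key(query$atoms$chain, query$atoms$resno, query$atoms$insert)
  R <- Q <- list()
  dropped <- 0L
  for (i in seq_len(nrow(ap$pairs))) {
    ra <- ref$atoms[rk == ap$pairs$ref_key[i], , drop = FALSE]
    qa <- query$atoms[qk == ap$pairs$query_key[i], , drop = FALSE]
    shared <- intersect(ra$name, qa$name)
    if (!length(shared)) { dropped <- dropped + 1L; next }
    ra <- ra[match(shared, ra$name), , drop = FALSE]
    qa <- qa[match(shared, qa$name), , drop = FALSE]
    m_r <- as.matrix(ra[, c("x", "y", "z")])
    m_q <- as.matrix(qa[, c("x", "y", "z")])
    rownames(m_r) <- rownames(m_q) <- paste0(ap$pairs$ref_key[i], ":", shared)
    R[[i]] <- m_r; Q[[i]] <- m_q
  }
  if (dropped) warnf("%d aligned residue(s) share no atom names; dropped",
                     dropped)
  list(ref = do.call(rbind, R), query = do.call(rbind, Q))
}
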