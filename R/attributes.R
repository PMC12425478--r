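# Structural attributes mapped across the tree: geometry, composition,
# interface contacts, contact-based binding affinity, residue networks,
# and Gaussian-network-model modes.

#' Radius of gyration
#' @param s a `nitro_structure`
#' @param atoms "ca" or "all"
#' @return unweighted radius of gyration in Angstrom
#' @export
radius_of_gyration <- function(s, atoms = c("ca", "all")) {
  atoms <- match.arg(atoms)
  xyz <- if (atoms == "ca") ca_coords(s)
         else as.matrix(s$atoms[, c("x", "y", "z")])
  if (nrow(xyz) == 0L) stopf("no atoms selected")
  sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
}

#' Fraction of charged residues, pooled over sequences
#'
#' @param sequences character vector of one-letter sequences (e.g. all
#'   subunits of a complex)
#' @param charged charged set; default D, E, K, R (histidine excluded)
#' @return fraction in [0, 1]
#' @export
charged_fraction <- function(sequences, charged = AA_CHARGED) {
  aa <- unlist(strsplit(paste(sequences, collapse = ""), ""))
  std <- aa %in% AA_ALPHABET
  if (any(!std))
    warnf("%d non-standard letter(s) excluded from charged fraction",
          sum(!std))
  aa <- aa[std]
  if (!length(aa)) stopf("no standard residues in input")
  mean(aa %in% charged)
}

#' Intersubunit interface contacts, classified by residue class
#'
#' A residue pair across the two chain groups is counted once if any
#' heavy-atom pair lies within `cutoff`, and is classified by the
#' unordered pair of residue classes (charged/polar/apolar, with the
#' contact model's convention of counting histidine as charged).
#'
#' @param s a `nitro_structure`
#' @param group_a,group_b disjoint chain-id vectors
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5.5)
#' @return `interface_contacts`: list with `counts` (cc, cp, ca, pp, pa,
#'   aa), `cutoff`, and `pairs` (residue-key pairs in contact)
#' @export
interface_contacts <- function(s, group_a, group_b, cutoff = 5.5) {
  if (length(intersect(group_a, group_b)))
    stopf("chain groups must be disjoint")
  a <- s$atoms[s$atoms$chain %in% group_a & s$atoms$element != "H", ]
  b <- s$atoms[s$atoms$chain %in% group_b & s$atoms$element != "H", ]
  if (!nrow(a) || !nrow(b)) stopf("empty chain group")
  ka <- residue_key(a$chain, a$resno, a$insert)
  kb <- residue_key(b$chain, b$resno, b$insert)
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  # squared-distance matrix between all heavy atoms of the two groups
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- unique(data.frame(a_key = ka[hit[, 1]], b_key = kb[hit[, 2]],
                             a_aa = three_to_one(a$resname[hit[, 1]]),
                             b_aa = three_to_one(b$resname[hit[, 2]]),
                             stringsAsFactors = FALSE))
  counts <- c(cc = 0L, cp = 0L, ca = 0L, pp = 0L, pa = 0L, aa = 0L)
  if (nrow(pairs)) {
    cls <- cbind(residue_class(pairs$a_aa), residue_class(pairs$b_aa))
    key <- apply(cls, 1, function(x) {
      x <- sort(substr(x, 1, 1))            # c < a < p alphabetically
      paste0(x, collapse = "")
    })
    # map sorted class-initial pairs onto the count keys
    lut <- c(cc = "cc", cp = "cp", ac = "ca", pp = "pp", ap = "pa", aa = "aa")
    tab <- table(factor(unname(lut[key]), levels = names(counts)))
    counts <- counts + as.integer(tab)
    names(counts) <- c("cc", "cp", "ca", "pp", "pa", "aa")
  }
  structure(list(counts = counts, cutoff = cutoff, pairs = pairs),
            class = "interface_contacts")
}

#' Non-interacting-surface composition of a complex
#'
#' The non-interacting surface (NIS) is the set of solvent-exposed
#' residues (relative SASA of the complex at least `rel_sasa_cutoff`) that
#' take part in no interface contact. Returns the percentage of charged,
#' polar and apolar residues on that surface.
#'
#' @param s a `nitro_structure`
#' @param group_a,group_b chain groups defining the interface
#' @param rel_sasa_cutoff relative-SASA exposure threshold (default 0.05)
#' @param icc optional precomputed [interface_contacts()]
#' @param rel_sasa optional precomputed [relative_sasa()] vector
#' @return list: percent_charged, percent_polar, percent_apolar,
#'   n_nis_residues, rel_sasa_cutoff
#' @export
nis_composition <- function(s, group_a, group_b, rel_sasa_cutoff = 0.05,
                            icc = NULL, rel_sasa = NULL) {
  if (is.null(icc)) icc <- interface_contacts(s, group_a, group_b)
  if (is.null(rel_sasa)) rel_sasa <- relative_sasa(s)
  rt <- residue_table(s)
  iface <- unique(c(icc$pairs$a_key, icc$pairs$b_key))
  nis <- rt$key[rel_sasa[rt$key] >= rel_sasa_cutoff & !(rt$key %in% iface)]
  cls <- residue_class(rt$aa[match(nis, rt$key)])
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stopf("no non-interacting surface residues")
  pct <- 100 * table(factor(cls, c("charged", "polar", "apolar"))) /
    length(cls)
  list(percent_charged = as.numeric(pct["charged"]),
       percent_polar = as.numeric(pct["polar"]),
       percent_apolar = as.numeric(pct["apolar"]),
       n_nis_residues = length(cls), rel_sasa_cutoff = rel_sasa_cutoff)
}

#' Default coefficients of the contact-based binding-affinity model
#'
#' The published linear model combining interface-contact counts by class
#' pair with non-interacting-surface percentages:
#' \deqn{\Delta G = -0.09459\,IC_{cc} - 0.10007\,IC_{ca} + 0.19577\,IC_{pp}
#'  - 0.22671\,IC_{pa} + 0.18681\,\%NIS_{apolar} + 0.13810\,\%NIS_{charged}
#'  - 15.9433}
#' @return named list of coefficients (kcal/mol per unit feature) and
#'   intercept
#' @export
affinity_coefficients <- function() {
  list(cc = -0.09459, ca = -0.10007, pp = 0.19577, pa = -0.22671,
       nis_apolar = 0.18681, nis_charged = 0.13810, intercept = -15.9433)
}

#' Contact-based intersubunit binding-affinity score
#'
#' Linear combination of interface-contact counts and NIS percentages;
#' lower (more negative) values mean stronger predicted binding.
#'
#' @param icc [interface_contacts()] result
#' @param nis [nis_composition()] result
#' @param coefficients coefficient list; see [affinity_coefficients()]
#' @return predicted binding free energy (kcal/mol-scale score)
#' @export
affinity_score <- function(icc, nis, coefficients = affinity_coefficients()) {
  need <- c("cc", "ca", "pp", "pa", "nis_apolar", "nis_charged", "intercept")
  miss <- setdiff(need, names(coefficients))
  if (length(miss))
    stopf("missing affinity coefficient(s): %s", paste(miss, collapse = ", "))
  k <- coefficients
  k$cc * icc$counts[["cc"]] + k$ca * icc$counts[["ca"]] +
    k$pp * icc$counts[["pp"]] + k$pa * icc$counts[["pa"]] +
    k$nis_apolar * nis$percent_apolar +
    k$nis_charged * nis$percent_charged + k$intercept
}

# Calpha adjacency by distance cutoff; sequence separation >= min_sep
# within a chain, cross-chain pairs always eligible.
ca_adjacency <- function(s, cutoff, min_sep = 0L) {
  rt <- residue_table(s)
  xyz <- as.matrix(rt[, c("x", "y", "z")])
  n <- nrow(xyz)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  adj <- d2 <= cutoff^2
  diag(adj) <- FALSE
  if (min_sep > 0L) {
    pos <- stats::ave(seq_len(n), rt$chain, FUN = seq_along)
    sep <- abs(outer(pos, pos, "-"))
    same <- outer(rt$chain, rt$chain, "==")
    adj[same & sep < min_sep] <- FALSE
  }
  dimnames(adj) <- list(rt$key, rt$key)
  adj
}

#' Residue contact-network summary
#'
#' Graph over residues with an edge when Cα distance is at most `cutoff`
#' and sequence separation is at least 2 (cross-chain contacts always
#' eligible).
#'
#' @param s a `nitro_structure`
#' @param cutoff Cα distance cutoff in Angstrom (default 6.5)
#' @return list: n_nodes, n_edges, mean_degree
#' @export
contact_network_counts <- function(s, cutoff = 6.5) {
  adj <- ca_adjacency(s, cutoff, min_sep = 2L)
  n <- nrow(adj)
  if (n < 2) stopf("need at least 2 residues")
  e <- sum(adj) / 2
  list(n_nodes = n, n_edges = e, mean_degree = 2 * e / n)
}

#' Gaussian-network-model modes from the Cα contact topology
#'
#' Builds the Kirchhoff (graph Laplacian) matrix of the Cα contact graph
#' and eigendecomposes it. A connected graph has exactly one zero
#' eigenvalue; residue fluctuations are read off the diagonal of the
#' pseudo-inverse, and the slowest (first nonzero) mode's per-residue
#' squared fluctuations are reported separately.
#'
#' @param s a `nitro_structure`
#' @param cutoff contact cutoff in Angstrom (default 7.5)
#' @return list: `eigenvalues` (ascending), `kirchhoff`, `fluctuations`
#'   (pseudo-inverse diagonal, named by residue key), and
#'   `slowest_mode_fluctuations` (v^2/lambda of the first nonzero mode)
#' @export
gnm_modes <- function(s, cutoff = 7.5) {
  adj <- ca_adjacency(s, cutoff, min_sep = 0L)
  n <- nrow(adj)
  # connectivity check (BFS)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    ncomp <- 1L
    rest <- which(!seen)
    while (length(rest)) {  # count remaining components for the message
      comp_seen <- logical(n); comp_seen[rest[1]] <- TRUE; q <- rest[1]
      while (length(q)) {
        v <- q[[1]]; q <- q[-1]
        nb <- which(adj[v, ] & !comp_seen)
        comp_seen[nb] <- TRUE; q <- c(q, nb)
      }
      rest <- setdiff(rest, which(comp_seen))
      ncomp <- ncomp + 1L
    }
    stopf("contact graph disconnected at cutoff %g (%d components)",
          cutoff, ncomp)
  }
  K <- -1 * adj
  diag(K) <- rowSums(adj)
  eig <- eigen(K, symmetric = TRUE)
  lambda <- rev(eig$values)                       # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  nz <- which(lambda > 1e-9)
  flucts <- rowSums(sweep(vecs[, nz, drop = FALSE]^2, 2, lambda[nz], "/"))
  slowest <- vecs[, nz[1]]^2 / lambda[nz[1]]
  list(eigenvalues = lambda, kirchhoff = K,
       fluctuations = stats::setNames(flucts, rownames(adj)),
       slowest_mode_fluctuations = stats::setNames(slowest, rownames(adj)))
}

#' Attribute table over a set of structures
#'
#' One record per structure: total SASA, radius of gyration, charged
#' fraction, intersubunit contact count, affinity score and the mean
#' slowest-mode fluctuation. Interface attributes need two chain groups;
#' when `groups` is NULL they are inferred for 2+-chain structures by
#' splitting the chain list in half (DDKK-style complexes: D chains vs K
#' chains). Failing fields are recorded as NA and the run continues.
#'
#' @param structures named list of `nitro_structure` objects
#' @param groups optional list(a = chains, b = chains)
#' @param contact_cutoff,gnm_cutoff distance cutoffs in Angstrom
#' @return data.frame, one row per structure
#' @export
attribute_table <- function(structures, groups = NULL,
                            contact_cutoff = 5.5, gnm_cutoff = 7.5) {
  ids <- names(structures)
  if (is.null(ids)) ids <- vapply(structures, `[[`, character(1), "id")
  one <- function(s) {
    try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    rec <- list(structure_id = s$id,
                total_sasa = try_na(sasa(s)$total),
                radius_of_gyration = try_na(radius_of_gyration(s)),
                charged_fraction = try_na(charged_fraction(chain_sequences(s))),
                n_intersubunit_contacts = NA_real_,
                affinity_score = NA_real_,
                slow_mode_mean_fluct = try_na(
                  mean(gnm_modes(s, gnm_cutoff)$slowest_mode_fluctuations)))
    ch <- chain_ids(s)
    grp <- groups
    if (is.null(grp) && length(ch) >= 2)
      grp <- list(a = ch[seq_len(floor(length(ch) / 2))],
                  b = ch[-seq_len(floor(length(ch) / 2))])
    if (!is.null(grp)) {
      icc <- tryCatch(interface_contacts(s, grp$a, grp$b, contact_cutoff),
                      error = function(e) NULL)
      if (!is.null(icc)) {
        rec$n_intersubunit_contacts <- sum(icc$counts)
        rec$affinity_score <- try_na(
          affinity_score(icc, nis_composition(s, grp$a, grp$b, icc = icc)))
      }
    }
    rec
  }
  out <- do.call(rbind, lapply(structures, function(s)
    as.data.frame(one(s), stringsAsFactors = FALSE)))
  out$structure_id <- ids
  rownames(out) <- NULL
  out
}
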