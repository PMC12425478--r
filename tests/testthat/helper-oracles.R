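# Independent oracles the implementation is checked against. These stay
# deliberately naive: exhaustive enumeration, dense grids, direct formula
# evaluation.

# minimal superposition RMSD by hierarchical grid search over SO(3)
# (ZYZ Euler angles), refined to ~1e-4 rad; translation handled by
# centering. Uses the linearity of the objective in the rotation via
# rmsd^2 = (|Pc|^2 + |Qc|^2 - 2 tr(R M)) / n with M = Qc' Pc.
oracle_gridsearch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  c0 <- sum(Pc^2) + sum(Qc^2)
  M <- crossprod(Qc, Pc)
  euler_rot <- function(a, b, g) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(g)
  }
  score <- function(a, b, g) sum(euler_rot(a, b, g) * t(M))  # tr(R M)
  best <- c(0, 0, 0); best_s <- -Inf
  step <- 15 * pi / 180
  for (a in seq(0, 2 * pi, by = step)) for (b in seq(0, pi, by = step))
    for (g in seq(0, 2 * pi, by = step)) {
      s <- score(a, b, g)
      if (s > best_s) { best_s <- s; best <- c(a, b, g) }
    }
  for (lvl in 1:6) {
    step <- step / 4
    grid <- seq(-4, 4) * step
    for (da in grid) for (db in grid) for (dg in grid) {
      s <- score(best[1] + da, best[2] + db, best[3] + dg)
      if (s > best_s) { best_s <- s; best <- best + c(da, db, dg) }
    }
  }
  sqrt(max((c0 - 2 * best_s) / n, 0))
}

# naive O(n^3) average-linkage agglomeration: returns merge heights in
# order and the partition after each merge
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1) {
    m <- length(groups)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      h <- mean(D[groups[[i]], groups[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
    part <- integer(n)
    for (k in seq_along(groups)) part[groups[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# exhaustive minimum-change count for a binary character on a rooted tree
oracle_fitch_changes <- function(tree, leaf_states) {
  ids <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  leaf_vals <- as.integer(leaf_states[tree$tip.label] != 0)
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    internal <- as.integer(intToBits(mask)[seq_len(nint)])
    states <- c(leaf_vals, internal)
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# direct ARI formula check is delegated to mclust (independent code path)
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
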