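test_that("sequence correspondence handles identity, insertions and toy gaps", {
  seq50 <- paste(rep(c("A","C","D","E","F","G","H","I","K","L"), 5),
                 collapse = "")
  a <- build_toy_structure(seq50, id = "a")
  b <- build_toy_structure(seq50, id = "b")
  ap <- sequence_correspondence(a, b)
  expect_equal(ap$L, 50)
  expect_equal(ap$pairs$ref_key, ap$pairs$query_key)
  # 5-residue internal insertion stays unaligned
  ins <- paste0(substr(seq50, 1, 25), "WWWWW", substr(seq50, 26, 50))
  bi <- build_toy_structure(ins, id = "bi")
  api <- sequence_correspondence(a, bi)
  expect_equal(api$L, 50)
  # exhaustively checkable toy pair
  sa <- mk_ca_structure(build_toy_structure("ACDEF")$atoms[, c("x","y","z")],
                        aa = c("A","C","D","E","F"), id = "sa")
  sb <- mk_ca_structure(build_toy_structure("ACEF")$atoms[, c("x","y","z")],
                        aa = c("A","C","E","F"), id = "sb")
  expect_warning(apx <- sequence_correspondence(sa, sb), "aligned")
  expect_equal(apx$L, 4)
  expect_true(apx$low_coverage)
})

test_that("Kabsch superposition recovers rigid transforms and proper rotations", {
  set.seed(4)
  P <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0)
  expect_equal(kabsch_superpose(P, P)$rotation, diag(3), tolerance = 1e-10)
  # pure translation
  expect_lt(kabsch_superpose(P, sweep(P, 2, c(5, 0, 0), "+"))$rmsd, 1e-10)
  # rotation + translation, det stays +1
  for (i in 1:5) {
    R <- random_rotation()
    sp <- kabsch_superpose(P, P %*% t(R) + rep(1, 8) %o% c(1, -2, 3))
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch matches the SO(3) grid-search oracle on noised copies", {
  set.seed(7)
  for (i in 1:3) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- (P + matrix(rnorm(3 * n, sd = 0.5), n, 3)) %*% t(random_rotation())
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_gridsearch_rmsd(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("RMSD is zero on self and exact on a pinned construction", {
  s <- build_toy_structure(paste(rep("ADKL", 10), collapse = ""), id = "s")
  ap <- sequence_correspondence(s, s)
  expect_equal(rmsd(s, s, ap), 0)
  # square in the z=0 plane with alternating +/-1 A z displacement:
  # centroids coincide and the cross-covariance keeps the identity
  # rotation optimal, so the RMSD is exactly 1
  P <- rbind(c(5, 5, 0), c(-5, 5, 0), c(-5, -5, 0), c(5, -5, 0))
  D <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 1), c(0, 0, -1))
  sp <- kabsch_superpose(P, P + D)
  expect_equal(sp$rmsd, 1.0, tolerance = 1e-12)
})

test_that("RMSD is invariant under rigid motion of one partner", {
  s <- build_toy_structure(paste(rep("GDEKLVWY", 5), collapse = ""), id = "x")
  ap <- sequence_correspondence(s, s)
  set.seed(9)
  for (i in 1:5) {
    moved <- s
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
    moved$atoms[, c("x", "y", "z")] <-
      xyz %*% t(random_rotation()) + rep(1, nrow(xyz)) %o% rnorm(3, sd = 10)
    expect_lt(rmsd(s, moved, ap), 1e-6)
  }
})

test_that("RMSD100 follows the closed form and its length behaviour", {
  expect_equal(rmsd100(2.0, 100), 2.0)
  expect_equal(rmsd100(2.0, 400), 2 / (1 + log(2)))
  expect_equal(rmsd100(1.0, 25), 1 / (1 + log(0.5)))
  expect_error(rmsd100(1.0, 13), "undefined")
  # shrinks iff the alignment is longer than 100 residues
  expect_lt(rmsd100(2, 150), 2)
  expect_gt(rmsd100(2, 60), 2)
})

test_that("TM-score hits its closed-form anchors", {
  s <- build_toy_structure(paste(rep("ADKLVEFGHR", 10), collapse = ""),
                           id = "tm")
  ap <- sequence_correspondence(s, s)
  expect_equal(tm_score(s, s, ap), 1.0)
  # every aligned distance equal to d0 gives exactly 1/2 per term
  d0 <- tm_d0(100)
  shifted <- s
  shifted$atoms$x <- shifted$atoms$x + d0
  expect_equal(tm_score(s, shifted, ap, optimize = FALSE), 0.5)
  expect_error(tm_d0(19), "L < 20")
})

test_that("TM-score agrees with direct formula evaluation at the oracle fit", {
  s <- build_toy_structure(paste(rep("ADKLVEFGHR", 6), collapse = ""),
                           id = "h")
  q <- perturb_structure(s, 0.8, seed = 5)
  ap <- sequence_correspondence(s, q)
  co <- aligned_coords(s, q, ap)
  sp <- kabsch_superpose(co$ref, co$query)
  fitted <- co$query %*% t(sp$rotation) +
    rep(1, nrow(co$query)) %o% sp$translation
  d <- sqrt(rowSums((co$ref - fitted)^2))
  direct <- sum(1 / (1 + (d / tm_d0(ap$L_ref))^2)) / ap$L_ref
  expect_gte(tm_score(s, q, ap) + 1e-9, direct)
  expect_equal(tm_score(s, q, ap), direct, tolerance = 1e-3)
})

test_that("TM-score decays monotonically with coordinate noise", {
  s <- build_toy_structure(paste(rep("ADKLVEFGHR", 15), collapse = ""),
                           id = "m")
  ap <- sequence_correspondence(s, s)
  scores <- vapply(c(0.5, 1, 2, 4), function(sig)
    tm_score(s, perturb_structure(s, sig, seed = 21), ap), numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("per-residue deviations reconstruct the superposition RMSD", {
  s <- build_toy_structure(paste(rep("ADKLVEFGHR", 8), collapse = ""),
                           id = "p")
  q <- perturb_structure(s, 1.2, seed = 13)
  ap <- sequence_correspondence(s, q)
  dev <- per_residue_deviation(s, q, ap)
  expect_length(dev, ap$L)
  expect_equal(sqrt(mean(dev^2)), rmsd(s, q, ap), tolerance = 1e-9)
  expect_true(all(per_residue_deviation(s, s, ap) < 1e-10))
})

test_that("local site RMSD isolates a rigid site from global noise", {
  s <- build_toy_structure(paste(rep("ADKLVEFGHR", 6), collapse = ""),
                           id = "site")
  rt <- residue_table(s)
  site <- rt$key[28:32]
  # perturb only residues far from the site
  q <- s
  far <- abs(seq_len(60) - 30) > 12
  set.seed(31)
  q$atoms[far, c("x", "y", "z")] <- q$atoms[far, c("x", "y", "z")] +
    matrix(rnorm(3 * sum(far), sd = 2), ncol = 3)
  ap <- sequence_correspondence(s, q)
  expect_equal(local_site_rmsd(s, s, ap, site, radius = 8), 0)
  loc <- local_site_rmsd(s, q, ap, site, radius = 8)
  glob <- rmsd(s, q, ap)
  expect_lt(loc, glob)
  expect_error(local_site_rmsd(s, q, ap, "A|999|", radius = 8),
               "not in reference")
})

test_that("pairwise matrices are symmetric with the right diagonal", {
  s1 <- build_toy_structure(paste(rep("ADKLVEFGHR", 4), collapse = ""),
                            id = "s1")
  s2 <- perturb_structure(s1, 0.5, seed = 2); s2$id <- "s2"
  s3 <- perturb_structure(s1, 1.0, seed = 3); s3$id <- "s3"
  M <- pairwise_matrix(list(s1 = s1, s2 = s2, s3 = s3), metric = "rmsd")
  expect_equal(M, t(M))
  expect_equal(diag(M), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(all(M[upper.tri(M)] > 0))
  # identical structures give off-diagonal zero
  M0 <- pairwise_matrix(list(a = s1, b = s1), metric = "rmsd")
  expect_equal(M0["a", "b"], 0)
  # tm with longer-normalization is exactly symmetric, diagonal 1
  Mt <- pairwise_matrix(list(s1 = s1, s2 = s2, s3 = s3), metric = "tm")
  expect_equal(Mt, t(Mt))
  expect_equal(diag(Mt), c(s1 = 1, s2 = 1, s3 = 1))
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(M, f)
  expect_equal(read_matrix_tsv(f), M, tolerance = 1e-12)
})
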