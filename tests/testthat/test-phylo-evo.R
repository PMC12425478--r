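read_tree_text <- function(txt) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(txt, f)
  read_newick(f)
}

test_that("root distances sum branch lengths from the root", {
  tr <- read_tree_text("(A:1,B:2)R:0;")
  expect_equal(root_distances(tr), c(A = 1, B = 2, R = 0))
  tr2 <- read_tree_text("((A:1,B:0.5)X:1,C:3)R:0;")
  d <- root_distances(tr2)
  expect_equal(d[["A"]], 2)
  expect_equal(d[["X"]], 1)
  # random trees vs an independent recursive traversal
  for (seed in 1:3) {
    t3 <- simulate_tree(12, 3, seed = seed)
    d3 <- root_distances(t3)
    ids <- node_ids(t3)
    oracle <- function(num) {
      if (num == length(t3$tip.label) + 1L) return(0)
      e <- which(t3$edge[, 2] == num)
      t3$edge.length[e] + oracle(t3$edge[e, 1])
    }
    for (k in seq_along(ids))
      expect_equal(d3[[ids[k]]], oracle(k))
  }
})

test_that("spearman matches stats::cor and handles ties and permutations", {
  expect_equal(spearman(c(1, 2, 3), c(6, 5, 4))$rho, -1)
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  set.seed(3)
  x <- sample(1:5, 10, replace = TRUE)      # ties
  y <- rnorm(10)
  expect_equal(spearman(x, y)$rho, cor(x, y, method = "spearman"))
  # rank-invariance
  expect_equal(spearman(x, y)$rho, spearman(rank(x), rank(y))$rho)
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
  # permutation p under the null is comfortably non-significant
  set.seed(11)
  res <- spearman(rnorm(30), rnorm(30), n_perm = 500, seed = 2)
  expect_gt(res$p, 0.05)
  # perfectly monotone data get the smallest attainable p
  res2 <- spearman(1:20, (1:20)^2, n_perm = 500, seed = 2)
  expect_equal(res2$p, 1 / 501)
})

test_that("attribute-depth correlation joins nodes and reports overlap", {
  tr <- simulate_tree(15, 3, seed = 5)
  d <- root_distances(tr)
  tab <- data.frame(structure_id = names(d), charged_fraction = 1 - d,
                    stringsAsFactors = FALSE)
  res <- attribute_depth_correlation(tr, tab, "charged_fraction")
  expect_equal(res$rho, -1)
  # nodes missing from the table are excluded and n reports the overlap
  tab2 <- tab[1:10, ]
  res2 <- attribute_depth_correlation(tr, tab2, "charged_fraction")
  expect_equal(res2$n, 10)
  expect_error(attribute_depth_correlation(tr, tab, "nope"), "not in table")
})

test_that("average-linkage clustering matches the naive oracle", {
  set.seed(8)
  pts <- c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  res <- hierarchical_cluster(D, k = 2)
  expect_true(all(diff(res$hclust$height) >= -1e-12))
  oracle <- oracle_average_linkage(D)
  expect_equal(sort(res$hclust$height), sort(oracle$heights),
               tolerance = 1e-12)
  # two tight groups split perfectly at k = 2
  expect_equal(length(unique(res$labels[1:3])), 1L)
  expect_equal(length(unique(res$labels[4:6])), 1L)
  expect_false(res$labels[1] == res$labels[4])
  # k = n gives singletons; k > n errors
  expect_equal(length(unique(hierarchical_cluster(D, 6)$labels)), 6L)
  expect_error(hierarchical_cluster(D, 7), "exceeds")
})

test_that("adjusted Rand index matches mclust and is permutation-invariant", {
  a <- c(1, 1, 2, 2, 3, 3, 3, 1)
  b <- c("x", "x", "y", "y", "z", "z", "y", "x")
  names(a) <- names(b) <- paste0("s", 1:8)
  expect_equal(clade_recovery(a, a), 1.0)
  expect_equal(clade_recovery(a, b), oracle_ari(a, b))
  # label permutation does not matter
  b2 <- c(x = "q", y = "r", z = "s")[b]
  names(b2) <- names(b)
  expect_equal(clade_recovery(a, b2), clade_recovery(a, b))
  # singletons vs one blob sit at chance level
  expect_equal(clade_recovery(setNames(1:8, names(a)),
                              setNames(rep(1, 8), names(a))), 0)
  expect_error(clade_recovery(a, b[1:7]), "different ids")
})

test_that("indel block detection finds planted blocks and nothing else", {
  rows <- c(A = "AAAAAAAAAAAAAAAAAAAA", B = "AAAAAAAAAAAAAAAAAAAA",
            C = "AAAAAAAAAAAAAAAAAAAA", D = "AAAAAAAAAAAAAAAAAAAA")
  expect_length(detect_indel_blocks(rows), 0)
  # 10-column block carried only by C and D (columns 6..15)
  with_block <- c(A = paste0(strrep("A", 5), strrep("-", 10), strrep("A", 5)),
                  B = paste0(strrep("A", 5), strrep("-", 10), strrep("A", 5)),
                  C = strrep("A", 20), D = strrep("A", 20))
  blocks <- detect_indel_blocks(with_block)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$start, 5)
  expect_equal(blocks[[1]]$end, 15)
  expect_setequal(blocks[[1]]$presence, c("C", "D"))
  # two blocks separated by one fully occupied column stay distinct
  two <- c(A = paste0(strrep("-", 6), "A", strrep("A", 6)),
           B = paste0(strrep("A", 6), "A", strrep("-", 6)),
           C = strrep("A", 13), D = strrep("A", 13))
  expect_length(detect_indel_blocks(two, min_block = 5), 2)
  # blocks below min_block are discarded
  expect_length(detect_indel_blocks(with_block, min_block = 11), 0)
})

test_that("Fitch reconstruction is minimal and resolves ties to insertions", {
  for (seed in 1:6) {
    tr <- simulate_tree(sample(4:8, 1), 2, seed = seed)
    set.seed(seed + 100)
    states <- setNames(sample(c(0, 1), length(tr$tip.label), replace = TRUE),
                       tr$tip.label)
    if (!any(states == 1)) states[1] <- 1
    fit <- fitch_presence(tr, states)
    expect_equal(fit$n_changes, oracle_fitch_changes(tr, states))
  }
  # clade-restricted block -> single insertion above the clade ancestor
  tr <- read_tree_text("((A:1,B:1)X:1,(C:1,D:1)Y:1)R:0;")
  msa <- c(A = "AAAAA-----", B = "AAAAA-----",
           C = "AAAAAGGGGG", D = "AAAAAGGGGG")
  blocks <- detect_indel_blocks(msa)
  ev <- assign_events_to_branches(blocks, tr, msa)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_branch, "Y")
  expect_equal(ev[[1]]$direction, "insertion")
  # block present everywhere: ancestral at the root, no event
  all_msa <- c(A = "AAAAAGGGGG", B = "AAAAAGGGGG",
               C = "AAAAAGGGGG", D = "AAAAAGGGGG")
  expect_length(assign_events_to_branches(detect_indel_blocks(all_msa),
                                          tr, all_msa), 0)
  # a block absent from every leaf is rejected
  fake <- list(list(start = 0L, end = 5L, span = 5L, presence = character(0)))
  expect_error(assign_events_to_branches(fake, tr, msa), "no leaf")
})

test_that("length trajectories follow the lineage and respect the span", {
  tr <- read_tree_text("((A:1,B:1)X:1,(C:1,D:1)Y:1)R:0;")
  msa <- c(R = "AAAAA-----", X = "AAAAA-----", Y = "AAAAAGG---",
           A = "AAAAA-----", B = "AAAAA-----",
           C = "AAAAAGGGG-", D = "AAAAAGG---")
  ev <- list(start = 5L, end = 10L)
  tj <- length_trajectory(ev, tr, msa, "C")
  expect_equal(tj$node, c("R", "Y", "C"))
  expect_equal(tj$length, c(0L, 2L, 4L))
  expect_true(all(tj$length <= ev$end - ev$start))
  # lineage without the block: all zeros
  tj0 <- length_trajectory(ev, tr, msa, "A")
  expect_true(all(tj0$length == 0))
})
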