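test_that("SASA reproduces analytic sphere areas and burial", {
  lone <- new_structure(data.frame(
    serial = 1, name = "CA", element = "C", chain = "A", resno = 1,
    insert = "", resname = "GLY", x = 0, y = 0, z = 0, occupancy = 1,
    confidence = 90), id = "lone")
  res <- sasa(lone)
  expect_equal(res$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # far-apart atoms are additive
  pair <- mk_ca_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sasa(pair)$total, 2 * res$total, tolerance = 1e-6)
  # an atom caged by neighbours exposes ~nothing
  cage_pts <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                    z = c(-2, 0, 2)))
  cage <- mk_ca_structure(cage_pts)
  buried <- sasa(cage)$atom_area[14]   # centre of the 3x3x3 grid
  expect_lt(buried, 1e-6)
  # unknown element errors
  bad <- lone; bad$atoms$element <- "XX"
  expect_error(sasa(bad), "radius")
})

test_that("complex formation never increases total SASA", {
  apart <- mk_dimer(gap = 100)
  close <- mk_dimer(gap = 4)
  expect_lt(sasa(close)$total, sasa(apart)$total)
})

test_that("radius of gyration matches hand arithmetic", {
  expect_equal(radius_of_gyration(mk_ca_structure(rbind(c(1, 2, 3)))), 0)
  expect_equal(radius_of_gyration(
    mk_ca_structure(rbind(c(0, 0, 0), c(2, 0, 0)))), 1.0)
  sq <- mk_ca_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(1, 1, 0)))
  expect_equal(radius_of_gyration(sq), sqrt(0.5))
})

test_that("charged fraction counts the DEKR set and warns on oddities", {
  expect_equal(charged_fraction("DEKR"), 1.0)
  expect_equal(charged_fraction("GGGG"), 0.0)
  expect_equal(charged_fraction("DGKG"), 0.5)
  expect_equal(charged_fraction(c("DG", "KG")), 0.5)  # pooling
  expect_warning(v <- charged_fraction("DGX"), "non-standard")
  expect_equal(v, 0.5)
  # histidine stays out of the default charged set
  expect_equal(charged_fraction("HHHH"), 0.0)
})

test_that("interface contacts classify residue pairs and respect the cutoff", {
  none <- interface_contacts(mk_dimer(gap = 8), "D", "K", cutoff = 5.5)
  expect_true(all(none$counts == 0))
  one_res <- mk_dimer(n_res = 1, gap = 4)    # LYS vs ASP, ~4 A apart
  icc <- interface_contacts(one_res, "D", "K", cutoff = 5.5)
  expect_equal(icc$counts[["cc"]], 1L)
  expect_equal(sum(icc$counts), 1L)
  # symmetric in the group arguments
  icc_swap <- interface_contacts(one_res, "K", "D", cutoff = 5.5)
  expect_equal(icc$counts, icc_swap$counts)
  expect_error(interface_contacts(one_res, "D", "D", 5.5), "disjoint")
})

test_that("interface contacts match a brute-force pair scan", {
  s <- mk_dimer(n_res = 6, gap = 5,
                aa_a = c("K", "G", "S", "D", "L", "R"),
                aa_b = c("D", "S", "G", "K", "E", "L"))
  icc <- interface_contacts(s, "D", "K", cutoff = 5.5)
  # oracle: exhaustive heavy-atom double loop
  a <- s$atoms[s$atoms$chain == "D", ]
  b <- s$atoms[s$atoms$chain == "K", ]
  hits <- character(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((unlist(a[i, c("x","y","z")]) -
                   unlist(b[j, c("x","y","z")]))^2))
    if (d <= 5.5) hits <- c(hits, paste(a$resno[i], b$resno[j]))
  }
  expect_equal(sum(icc$counts), length(unique(hits)))
})

test_that("NIS composition tallies exposed non-interface residues", {
  s <- mk_dimer(n_res = 6, gap = 30,
                aa_a = c("K", "G", "S", "D", "L", "R"),
                aa_b = c("D", "S", "G", "K", "E", "L"))
  nis <- nis_composition(s, "D", "K")
  expect_equal(nis$percent_charged + nis$percent_polar + nis$percent_apolar,
               100, tolerance = 0.1)
  # chains 30 A apart: no interface, every residue exposed -> hand tally
  # charged: K,D,R + D,K,E = 6; polar: S + S = 2; apolar: G,L + G,L = 4
  expect_equal(nis$n_nis_residues, 12)
  expect_equal(nis$percent_charged, 100 * 6 / 12)
  expect_equal(nis$percent_polar, 100 * 2 / 12)
})

test_that("the affinity score is exactly linear with the published coefficients", {
  k <- affinity_coefficients()
  zero_icc <- list(counts = c(cc = 0, cp = 0, ca = 0, pp = 0, pa = 0, aa = 0))
  zero_nis <- list(percent_apolar = 0, percent_charged = 0, percent_polar = 0)
  expect_equal(affinity_score(zero_icc, zero_nis), k$intercept)
  icc1 <- list(counts = c(cc = 3, cp = 1, ca = 2, pp = 4, pa = 1, aa = 5))
  nis1 <- list(percent_apolar = 40, percent_charged = 25, percent_polar = 35)
  g1 <- affinity_score(icc1, nis1) - k$intercept
  icc2 <- list(counts = icc1$counts * 2)
  nis2 <- lapply(nis1, `*`, 2)
  expect_equal(affinity_score(icc2, nis2) - k$intercept, 2 * g1)
  # dot-product oracle
  expect_equal(g1, k$cc * 3 + k$ca * 2 + k$pp * 4 + k$pa * 1 +
                 k$nis_apolar * 40 + k$nis_charged * 25)
  expect_error(affinity_score(icc1, nis1, coefficients = list(cc = 1)),
               "missing affinity coefficient")
})

test_that("contact networks exclude short-range sequence neighbours", {
  far <- mk_ca_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(contact_network_counts(far)$n_edges, 0)
  # straight chain at 3.8 A: only i,i+1 within 6.5 A, excluded by separation
  chain <- mk_ca_structure(cbind(3.8 * (0:9), 0, 0))
  expect_equal(contact_network_counts(chain, cutoff = 6.5)$n_edges, 0)
  # toy cluster vs brute force
  set.seed(12)
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  cc <- contact_network_counts(mk_ca_structure(pts), cutoff = 6.5)
  brute <- 0
  for (i in 1:9) for (j in (i + 1):10)
    if (j - i >= 2 && sqrt(sum((pts[i, ] - pts[j, ])^2)) <= 6.5)
      brute <- brute + 1
  expect_equal(cc$n_edges, brute)
  expect_equal(cc$mean_degree, 2 * brute / 10)
})

test_that("GNM spectra match graph-Laplacian ground truth", {
  path3 <- mk_ca_structure(cbind(c(0, 3.8, 7.6), 0, 0))
  g <- gnm_modes(path3, cutoff = 4)
  expect_equal(g$eigenvalues, c(0, 1, 3), tolerance = 1e-9)
  expect_equal(sum(g$eigenvalues), sum(diag(g$kirchhoff)), tolerance = 1e-9)
  # 5-node toy vs an independent dense solver (svd)
  set.seed(5)
  pts <- matrix(rnorm(15, sd = 3), 5, 3)
  s5 <- mk_ca_structure(pts)
  g5 <- gnm_modes(s5, cutoff = 12)
  sv <- svd(g5$kirchhoff)$d
  expect_equal(sort(g5$eigenvalues), sort(sv), tolerance = 1e-9)
  # one zero mode per connected component
  expect_equal(sum(abs(g5$eigenvalues) < 1e-9), 1L)
  split <- mk_ca_structure(rbind(c(0, 0, 0), c(3, 0, 0),
                                 c(50, 0, 0), c(53, 0, 0)))
  expect_error(gnm_modes(split, cutoff = 7.5), "2 components")
})

test_that("attribute tables are complete, reproducible and serializable", {
  # offset chain K along x so only part of each chain forms the interface
  # (a fully interfacial complex has no non-interacting surface)
  mk_offset_dimer <- function(id) {
    s <- mk_dimer(n_res = 6, gap = 5, id = id)
    k <- s$atoms$chain == "K"
    s$atoms$x[k] <- s$atoms$x[k] + 12
    s
  }
  s1 <- mk_offset_dimer("dimer1")
  s2 <- mk_offset_dimer("dimer2")
  tab <- attribute_table(list(a = s1, b = s2))
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$total_sasa)))
  expect_true(all(is.finite(tab$affinity_score)))
  # identical structures give identical records (ids aside)
  expect_equal(tab$total_sasa[1], tab$total_sasa[2])
  expect_equal(tab$affinity_score[1], tab$affinity_score[2])
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(f, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back$charged_fraction, tab$charged_fraction, tolerance = 1e-12)
  # single-chain structures: interface fields go missing, run continues
  mono <- build_toy_structure("ACDEFGHIKL", id = "mono")
  tab2 <- attribute_table(list(mono = mono))
  expect_true(is.na(tab2$affinity_score))
  expect_true(is.finite(tab2$radius_of_gyration))
})
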