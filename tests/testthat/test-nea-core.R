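test_that("count_connecting_edges applies the within-set exclusion rule", {
  net <- toy_network()
  # A-C and B-C connect; C-D is within FGS, A-B within AGS
  expect_equal(count_connecting_edges(net, c("A", "B"), c("C", "D")), 2L)
  expect_equal(count_connecting_edges(net, "A", "D"), 0L)
  expect_equal(count_connecting_edges(net, c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_error(count_connecting_edges(net, "Z", "A"), "restrict")
})

test_that("edge counting is symmetric and matches brute force on random graphs", {
  for (s in 1:20) {
    net <- random_graph(sample(5:50, 1), p = 0.2, seed = s)
    set.seed(s + 100)
    A <- random_subset(net, sample(2:15, 1))
    F_ <- random_subset(net, sample(2:15, 1))
    expect_identical(count_connecting_edges(net, A, F_), bf_count_edges(net, A, F_))
    expect_identical(count_connecting_edges(net, A, F_), count_connecting_edges(net, F_, A))
    expect_identical(expected_edges(net, A, F_), expected_edges(net, F_, A))
  }
})

test_that("expected_edges follows the degree-sum formula", {
  net <- toy_network()
  expect_equal(expected_edges(net, c("A", "B"), c("C", "D")), 2.0)
  expect_equal(expected_edges(net, "A", "D"), 0.25)
  expect_equal(expected_edges(net, character(0), c("A", "B")), 0)
  empty <- new_network(character(0), character(0), nodes = c("A", "B"))
  expect_error(expected_edges(empty, "A", "B"), "no edges")
  # degree sums can dominate tiny networks; the implausible value is flagged
  tiny <- new_network("A", "B")
  expect_warning(expected_edges(tiny, c("A", "B"), c("A", "B"), strict_overlap = FALSE),
                 "exceeds N_total")
})

test_that("overlap accounting: default removes shared genes from degree sums", {
  net <- toy_network()
  # A shared: default expectation uses degrees of {B} x {C}
  expect_equal(expected_edges(net, c("A", "B"), c("A", "C")), 2 * 3 / 8)
  # full-set accounting uses all four degrees
  expect_equal(expected_edges(net, c("A", "B"), c("A", "C"), strict_overlap = FALSE), 4 * 5 / 8)
  # disjoint sets: both identical
  expect_identical(expected_edges(net, c("A", "B"), c("C", "D")),
                   expected_edges(net, c("A", "B"), c("C", "D"), strict_overlap = FALSE))
})

test_that("chi2_statistic reproduces hand-computed values in both variants", {
  expect_equal(chi2_statistic(2, 2.0, 4), 0)
  expect_equal(chi2_statistic(0, 0.25, 4), 0.25^2 / 0.25 + 0.25^2 / 3.75)
  expect_equal(chi2_statistic(0, 0.25, 4), 0.2666667, tolerance = 1e-6)
  # printed variant, frozen from the formula with !n = n_total - n
  expect_equal(chi2_statistic(2, 0.667, 4, variant = "printed"),
               (2 - 0.667)^2 / 2 + (2 - 3.333)^2 / 2)
  expect_equal(chi2_statistic(2, 0.667, 4, variant = "printed"), 1.776889, tolerance = 1e-6)
})

test_that("chi2_statistic handles degenerate cells: zero/zero, caps, fallback", {
  expect_equal(chi2_statistic(0, 0, 10), 0)
  expect_equal(chi2_statistic(3, 0, 10), 38^2)  # n_hat = 0, n > 0: capped at z = 38
  expect_warning(v <- chi2_statistic(0, 1.5, 10, variant = "printed"), "undefined")
  expect_equal(v, chi2_statistic(0, 1.5, 10, variant = "pearson"))
  expect_error(chi2_statistic(5, 1, 4), "exceeds")
  expect_error(chi2_statistic(-1, 1, 4), "non-negative")
})

test_that("chi2 is non-decreasing in |n - n_hat| at fixed expectation", {
  n_hat <- 7.3
  n_total <- 1000L
  for (base in c(0L, 3L, 12L)) {
    dev <- abs(seq(base, 40L) - n_hat)
    v <- chi2_statistic(seq(base, 40L), n_hat, n_total)
    expect_true(all(diff(v[order(dev)]) >= -1e-12))
  }
})

test_that("pair_stats ties together count, expectation, chi2, p and signed z", {
  net <- toy_network()
  ps <- pair_stats(net, "A", "D")
  expect_equal(ps$n_edges, 0L)
  expect_equal(ps$expected_edges, 0.25)
  expect_equal(ps$p, 0.6056, tolerance = 1e-4)
  expect_equal(ps$z, -0.516, tolerance = 1e-3)
  expect_equal(abs(ps$z), sqrt(ps$chi2), tolerance = 1e-6)
  # observed equal to expected: p = 1, z = 0
  ps0 <- pair_stats(net, c("A", "B"), c("C", "D"))
  expect_equal(ps0$n_edges, 2L)
  expect_equal(ps0$expected_edges, 2)
  expect_equal(ps0$p, 1)
  expect_identical(ps0$z, 0)
  # strong enrichment: p small, z positive
  star <- new_network(rep("hub", 6), paste0("leaf", 1:6))
  ps1 <- pair_stats(star, "hub", paste0("leaf", 1:6))
  expect_gt(ps1$z, 0)
  expect_lt(ps1$p, 0.05)
})

test_that("z sign encodes depletion vs enrichment over random pairs", {
  for (s in 1:10) {
    net <- random_graph(30, p = 0.2, seed = s)
    set.seed(s)
    ps <- pair_stats(net, random_subset(net, 8), random_subset(net, 8))
    if (ps$n_edges < ps$expected_edges) expect_lt(ps$z, 0)
    if (ps$n_edges > ps$expected_edges) expect_gt(ps$z, 0)
    if (ps$n_edges == ps$expected_edges) expect_identical(ps$z, 0)
    expect_equal(ps$z^2, ps$chi2, tolerance = 1e-6)
  }
})

test_that("bh_adjust performs the step-up adjustment and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.20)),
               c(0.04, 0.0533333333, 0.0533333333, 0.20), tolerance = 1e-9)
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("nea_render fills the grid, adjusts q jointly, and warns on few tests", {
  net <- toy_network()
  ags <- gene_set_collection(list(S = c("A", "B")), role = "AGS")
  fgs <- gene_set_collection(list(F1 = c("C", "D")))
  expect_warning(rm <- nea_render(net, ags, fgs), "q-values")
  expect_equal(nrow(rm), 1L)
  expect_equal(rm$q, rm$p)
  expect_error(suppressWarnings(nea_render(net, ags, gene_set_collection(list()))), "empty")
})

test_that("parallel partitioning never changes values or ordering", {
  net <- make_scalefree_network(500, 3, seed = 11)
  gsc <- make_random_gene_sets(net, 10, c(10, 25, 40), seed = 12)
  ags <- gsc; names(ags) <- paste0("a", seq_along(ags))
  r1 <- suppressWarnings(nea_render(net, ags, gsc, jobs = 1L))
  r4 <- suppressWarnings(nea_render(net, ags, gsc, jobs = 4L))
  attr(r1, "metadata") <- attr(r4, "metadata") <- NULL
  expect_identical(r1, r4)
})

test_that("rendered q-values never fall below their p-values", {
  net <- make_scalefree_network(500, 3, seed = 21)
  gsc <- make_random_gene_sets(net, 15, c(10, 30), seed = 22)
  ags <- gsc; names(ags) <- paste0("a", seq_along(ags))
  rm <- nea_render(net, ags, gsc)
  expect_true(all(rm$q >= rm$p))
  expect_true(all(rm$q <= 1))
})

test_that("single_gene_fgs yields one verbatim singleton per node", {
  net <- toy_network()
  fgs <- single_gene_fgs(net)
  expect_length(fgs, 4L)
  expect_identical(names(fgs), net$nodes)
  expect_true(all(lengths(fgs) == 1L))
  rm <- suppressWarnings(nea_render(net,
    gene_set_collection(list(S = c("A", "B")), role = "AGS"), fgs))
  expect_equal(rm$n_edges[rm$fgs_id == "C"], 2L)
})
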