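test_that("read_network collapses duplicates and reversed pairs, drops self-loops", {
  f <- write_tmp(c("A\tB", "B\tA", "A\tA", "B\tC"))
  expect_warning(net <- read_network(f), "self-loop")
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(net$n_total_edges, 2L)
  expect_equal(sum(net$degree), 2L * net$n_total_edges)
})

test_that("read_network reports degrees and N_total on a hand-counted file", {
  f <- write_tmp(c("# comment", "A\tB", "B\tC", "C\tA", "C\tD"))
  net <- read_network(f)
  expect_equal(net$degree[c("A", "B", "C", "D")], c(A = 2L, B = 2L, C = 3L, D = 1L))
  expect_equal(net$n_total_edges, 4L)
})

test_that("read_network rejects empty and malformed files with line numbers", {
  expect_error(read_network(write_tmp(character(0))), "no edges")
  expect_error(read_network(write_tmp(c("# only comments"))), "no edges")
  f <- write_tmp(c("A\tB", "B\tC", "oops"))
  expect_error(read_network(f), "line 3")
  f4 <- write_tmp(c("A\tB", "A\tB\tC\tD"))
  expect_error(read_network(f4), "line 2")
})

test_that("read_network parses but never scores the confidence column", {
  f <- write_tmp(c("A\tB\t0.9", "B\tC\t0.5"))
  net_w <- read_network(f, keep_weights = TRUE)
  net_nw <- read_network(f)
  expect_equal(net_w$weights, c(0.9, 0.5))
  expect_equal(net_w$degree, net_nw$degree)
  expect_equal(expected_edges(net_w, "A", "C"), expected_edges(net_nw, "A", "C"))
})

test_that("GMT reader deduplicates members and rejects duplicate set ids", {
  f <- write_tmp(c("S1\tdesc\tA\tB\tA", "S2\tdesc\tC"), ext = ".gmt")
  gsc <- read_gene_sets(f, format = "gmt")
  expect_equal(gsc$S1, c("A", "B"))
  expect_equal(gsc$S2, "C")
  fdup <- write_tmp(c("S1\td\tA", "S1\td\tB"), ext = ".gmt")
  expect_error(read_gene_sets(fdup, format = "gmt"), "duplicate")
  fempty <- write_tmp(c("S1\td\tA", "S2\td"), ext = ".gmt")
  expect_warning(g2 <- read_gene_sets(fempty, format = "gmt"), "empty")
  expect_named(g2, "S1")
})

test_that("long-format reader groups genes by set in file order", {
  f <- write_tmp(c("A\tS1", "B\tS1", "C\tS2"))
  gsc <- read_gene_sets(f, format = "long")
  expect_equal(unclass(gsc)[], list(S1 = c("A", "B"), S2 = "C"),
               ignore_attr = TRUE)
})

test_that("gene set round-trip through GMT preserves ids and members", {
  gsc <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("C", "D", "E")))
  f <- tempfile(fileext = ".gmt")
  write_gene_sets(gsc, f)
  back <- read_gene_sets(f, format = "gmt")
  expect_equal(names(back), names(gsc))
  expect_equal(back$S2, gsc$S2)
})

test_that("restrict_to_network intersects, warns, and errors when nothing is left", {
  net <- toy_network()
  expect_warning(r <- restrict_to_network(gene_set_collection(list(S1 = c("A", "Z"))), net),
                 "absent")
  expect_equal(r$S1, "A")
  inside <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("C", "D")))
  expect_identical(lapply(restrict_to_network(inside, net), identity),
                   lapply(inside, identity))
  expect_error(suppressWarnings(
    restrict_to_network(gene_set_collection(list(S1 = "Z")), net)), "all gene sets empty")
})

test_that("degree_sum matches hand counts, is additive, and insists on restriction", {
  net <- toy_network()
  expect_equal(degree_sum(net, c("A", "B")), 4L)
  expect_equal(degree_sum(net, c("C", "D")), 4L)
  expect_equal(degree_sum(net, character(0)), 0L)
  expect_error(degree_sum(net, c("A", "Z")), "not in network")
  # additivity over disjoint random splits
  g <- random_graph(20, seed = 42)
  for (s in 1:5) {
    set.seed(s)
    part <- sample(g$nodes, 12)
    a <- part[1:5]; b <- part[6:12]
    expect_identical(degree_sum(g, c(a, b)), degree_sum(g, a) + degree_sum(g, b))
  }
})

test_that("result matrices round-trip through the long TSV layout", {
  net <- toy_network()
  ags <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("A", "D")), role = "AGS")
  fgs <- gene_set_collection(list(F1 = c("C", "D"), F2 = "C", F3 = c("B", "C")))
  rm <- suppressWarnings(nea_render(net, ags, fgs))
  f <- tempfile(fileext = ".tsv")
  write_results(rm, f)
  back <- read_results(f)
  expect_equal(names(back),
               c("ags_id", "fgs_id", "n_edges", "expected_edges", "chi2", "z", "p", "q"))
  for (col in c("expected_edges", "chi2", "z", "p", "q"))
    expect_equal(back[[col]], rm[[col]], tolerance = 1e-12)
  expect_equal(back$n_edges, rm$n_edges)
})

test_that("wide layout writes the AGS x FGS grid of one statistic", {
  net <- toy_network()
  ags <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("A", "D")), role = "AGS")
  fgs <- gene_set_collection(list(F1 = c("C", "D"), F2 = "C", F3 = c("B", "C")))
  rm <- suppressWarnings(nea_render(net, ags, fgs))
  f <- tempfile(fileext = ".tsv")
  write_results(rm, f, layout = "wide:z")
  wide <- utils::read.delim(f, comment.char = "#", check.names = FALSE)
  expect_equal(dim(wide), c(2L, 4L))  # ags_id column + 3 FGS columns
  expect_equal(wide[wide$ags_id == "S1", "F2"],
               rm$z[rm$ags_id == "S1" & rm$fgs_id == "F2"])
  expect_error(write_results(rm, f, layout = "wide:bogus"), "unknown statistic")
})

test_that("a 1x1 result writes one data row under the header", {
  net <- toy_network()
  rm <- suppressWarnings(nea_render(net,
    gene_set_collection(list(S = c("A", "B")), role = "AGS"),
    gene_set_collection(list(F1 = c("C", "D")))))
  f <- tempfile(fileext = ".tsv")
  write_results(rm, f)
  lines <- readLines(f)
  data_lines <- lines[!startsWith(lines, "#")]
  expect_length(data_lines, 2L)  # header + one row
})
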