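#' Overlap-based gene set enrichment (Fisher's exact test)
#'
#' The conventional comparator of the network test: for every AGS-FGS
#' pair, the 2x2 table (a = shared genes, b = AGS only, c = FGS only,
#' d = rest of the universe) is scored with the one-sided (enrichment)
#' hypergeometric tail `P(X >= a)`, the cross-product odds ratio
#' `(a d)/(b c)` (Haldane 0.5 correction when any cell is zero), and
#' Benjamini-Hochberg q-values over all pairs jointly. Unlike the network
#' test it sees only gene identities, not edges.
#'
#' @param ags_coll,fgs_coll `gene_set_collection`s (or named lists).
#' @param universe character vector of gene ids containing every set
#'   member. Defaults to the nodes of `net` when a network is supplied,
#'   else to the union of all AGS and FGS genes.
#' @param net optional `nea_network` whose nodes define the universe.
#' @return a data.frame of class `gsea_result` with columns `ags_id`,
#'   `fgs_id`, `overlap`, `odds_ratio`, `p`, `q` and a `metadata`
#'   attribute recording the universe choice.
#' @export
gsea_render <- function(ags_coll, fgs_coll, universe = NULL, net = NULL) {
  if (!length(ags_coll) || !length(fgs_coll)) stop("empty gene set collection")
  ags_coll <- lapply(ags_coll, function(s) unique(as.character(s)))
  fgs_coll <- lapply(fgs_coll, function(s) unique(as.character(s)))
  all_genes <- unique(c(unlist(ags_coll, use.names = FALSE),
                        unlist(fgs_coll, use.names = FALSE)))
  source <- "explicit"
  if (is.null(universe)) {
    if (!is.null(net)) { universe <- net$nodes; source <- "network nodes" }
    else { universe <- all_genes; source <- "union of sets" }
  }
  universe <- unique(as.character(universe))
  if (!all(all_genes %in% universe))
    stop("universe is smaller than the union of the gene sets (",
         sum(!all_genes %in% universe), " gene(s) missing)")
  U <- length(universe)
  grid <- expand.grid(fi = seq_along(fgs_coll), ai = seq_along(ags_coll))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    A <- ags_coll[[grid$ai[r]]]; F_ <- fgs_coll[[grid$fi[r]]]
    a <- length(intersect(A, F_))
    b <- length(A) - a; c_ <- length(F_) - a; d <- U - a - b - c_
    # one-sided enrichment tail: P(X >= a), X ~ Hypergeom(|A|, U-|A|, |F|)
    p <- stats::phyper(a - 1L, length(A), U - length(A), length(F_), lower.tail = FALSE)
    cells <- c(a, b, c_, d)
    if (any(cells == 0L)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    c(overlap = a, odds_ratio = or, p = p)
  })
  stats_mat <- do.call(rbind, rows)
  res <- data.frame(
    ags_id = names(ags_coll)[grid$ai],
    fgs_id = names(fgs_coll)[grid$fi],
    overlap = as.integer(stats_mat[, "overlap"]),
    odds_ratio = stats_mat[, "odds_ratio"],
    p = stats_mat[, "p"],
    q = bh_adjust(stats_mat[, "p"]),
    stringsAsFactors = FALSE
  )
  attr(res, "metadata") <- list(universe_size = U, universe_source = source,
                                n_tests = nrow(res))
  class(res) <- c("gsea_result", "data.frame")
  res
}
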