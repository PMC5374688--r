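## Degree-preserving network randomization (Maslov-Sneppen rewiring) and
## the randomization-based z-test (NRZ) used to validate the parametric
## statistic. Rewiring repeatedly picks two edges (i,j), (k,l) and
## reconnects them as (i,l), (k,j) (or (i,k), (j,l)), rejecting self-loops
## and existing edges, so every node keeps its exact degree.

#' Rewire a network preserving all node degrees
#'
#' Performs `round(swaps_per_edge * N_total)` double-edge-swap attempts
#' (accepted or rejected) on a copy of the network, keeping the degree
#' sequence and the total edge count identical. Deterministic for a given
#' seed.
#'
#' @param net an `nea_network`.
#' @param swaps_per_edge average number of swap attempts per edge; 10 is
#'   a standard mixing heuristic.
#' @param seed integer RNG seed.
#' @return a rewired `nea_network` over the same nodes. Networks with a
#'   single edge admit no swap and are returned unchanged with a warning.
#' @export
rewire_network <- function(net, swaps_per_edge = 10, seed = 1L) {
  if (swaps_per_edge <= 0) stop("swaps_per_edge must be positive")
  if (net$n_total_edges < 2L) {
    warning("network has fewer than 2 edges; no swap is possible, returning a copy")
    return(net)
  }
  g <- .net_to_igraph(net)
  niter <- max(1L, round(swaps_per_edge * net$n_total_edges))
  set.seed(seed)
  gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
  .igraph_to_net(gr, net, name = paste0(net$name, "_rewired"))
}

# internal: pair-by-permutation matrix of connecting-edge counts over
# rewired instances; pairs in AGS-major vector order. Permutation k is
# seeded as seed + k so runs of different lengths share their prefix.
.perm_counts <- function(net, MA, MF, n_permutations, swaps_per_edge, seed) {
  g <- .net_to_igraph(net)
  niter <- max(1L, round(swaps_per_edge * net$n_total_edges))
  counts <- matrix(0L, ncol(MA) * ncol(MF), n_permutations)
  for (k in seq_len(n_permutations)) {
    set.seed(seed + k)
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
    el <- igraph::as_edgelist(gr, names = FALSE)
    counts[, k] <- as.vector(t(.count_between(el[, 1], el[, 2], MA, MF)))
  }
  counts
}

#' Network-randomization z-test (NRZ)
#'
#' The nonparametric comparator of the chi-squared binomial test: for each
#' AGS-FGS pair, the mean and sample standard deviation of the
#' connecting-edge count over degree-preserving rewired instances of the
#' network give `z = (n_observed - mean) / sd` and a two-sided Gaussian
#' p-value. Pairs whose count never varies across permutations (`sd = 0`)
#' are flagged: their z is undefined and p is 1 when the observed count
#' equals the permutation mean, else the representable minimum.
#'
#' @inheritParams nea_render
#' @param n_permutations number of rewired instances (>= 2).
#' @param swaps_per_edge,seed see [rewire_network()]; permutation k uses
#'   seed `seed + k`.
#' @return a data.frame of class `nrz_result` with columns `ags_id`,
#'   `fgs_id`, `n_edges`, `mean_edges`, `sd_edges`, `z_nrz`, `p_nrz`,
#'   `sd_zero`, plus a `metadata` attribute.
#' @export
nrz <- function(net, ags_coll, fgs_coll, n_permutations = 100L,
                swaps_per_edge = 10, seed = 1L) {
  if (n_permutations < 2L) stop("n_permutations must be at least 2")
  if (!length(ags_coll) || !length(fgs_coll)) stop("empty gene set collection")
  MA <- .membership(net, ags_coll)
  MF <- .membership(net, fgs_coll)
  obs <- as.vector(t(.count_between(net$edges[, 1], net$edges[, 2], MA, MF)))
  counts <- .perm_counts(net, MA, MF, n_permutations, swaps_per_edge, seed)
  m <- rowMeans(counts)
  s <- apply(counts, 1L, stats::sd)
  sd_zero <- s == 0
  z <- ifelse(sd_zero, NA_real_, (obs - m) / s)
  p_floor <- 2 * stats::pnorm(-.Z_CAP)
  p <- ifelse(sd_zero,
              ifelse(obs == m, 1, p_floor),
              pmax(2 * stats::pnorm(-abs((obs - m) / s)), p_floor))
  res <- data.frame(
    ags_id = rep(names(ags_coll), each = length(fgs_coll)),
    fgs_id = rep(names(fgs_coll), times = length(ags_coll)),
    n_edges = obs,
    mean_edges = m,
    sd_edges = s,
    z_nrz = z,
    p_nrz = p,
    sd_zero = sd_zero,
    stringsAsFactors = FALSE
  )
  attr(res, "metadata") <- list(
    network = net$name, n_permutations = n_permutations,
    swaps_per_edge = swaps_per_edge, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(res) <- c("nrz_result", "data.frame")
  res
}

#' Convergence of the randomization z-test toward the parametric test
#'
#' Scores all unordered pairs of one gene-set collection against itself
#' with both the parametric chi-squared binomial test (CSB) and the
#' randomization z-test (NRZ) at increasing numbers of rewired instances,
#' and reports the Spearman rank correlation between the two log10
#' p-value sets at each N. Because permutation k is always seeded as
#' `seed + k`, the N-run results are nested prefixes of one permutation
#' stream. The per-pair table carries the three factors known to bias the
#' randomization test - total set size in nodes (`size_sum`), total degree
#' sum (`degree_sum`) and the observed edge count - each cut into
#' exhaustive, disjoint strata for Q-Q-style inspection.
#'
#' @param net an `nea_network`.
#' @param gsc a `gene_set_collection`, used as both AGS and FGS sides
#'   (all-vs-all).
#' @param n_list increasing numbers of randomizations to evaluate.
#' @param seed,swaps_per_edge see [rewire_network()].
#' @param variant chi-squared convention for the CSB side.
#' @param min_observed_edges pairs with fewer observed connecting edges
#'   are excluded from the correlations (never-connected pairs carry no
#'   rank information); excluded pairs are counted, not silently dropped.
#' @param strict_overlap overlap accounting for the CSB expectation, see
#'   [expected_edges()].
#' @return a list of class `nea_convergence`: `correlations` (one row per
#'   N: `n_randomizations`, `spearman_r`, `n_pairs_used`, `n_excluded`),
#'   `pairs` (per-pair table with `p_csb` and one `p_nrz_<N>` column per
#'   N), and `metadata`.
#' @export
convergence_experiment <- function(net, gsc, n_list = c(3L, 10L, 30L, 100L, 300L),
                                   seed = 1L, swaps_per_edge = 10,
                                   variant = c("pearson", "printed"),
                                   min_observed_edges = 1L,
                                   strict_overlap = TRUE) {
  variant <- match.arg(variant)
  n_list <- sort(unique(as.integer(n_list)))
  if (length(gsc) < 2L) stop("need at least 2 gene sets for all-vs-all pairs")
  M <- .membership(net, gsc)
  S <- length(gsc)
  ut <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)  # i < j, column-major
  obs_mat <- .count_between(net$edges[, 1], net$edges[, 2], M, M)
  obs <- obs_mat[ut]
  deg <- as.numeric(colSums(M * net$degree))
  sizes <- colSums(M)
  if (strict_overlap) {
    ov <- crossprod(M * net$degree, M + 0)  # per-pair degree sum of shared genes
    expd <- (deg[ut[, 1]] - ov[ut]) * (deg[ut[, 2]] - ov[ut]) / (2 * net$n_total_edges)
  } else {
    expd <- (deg[ut[, 1]] * deg[ut[, 2]]) / (2 * net$n_total_edges)
  }
  chi2 <- chi2_statistic(obs, expd, net$n_total_edges, variant)
  p_csb <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  # pair index within the AGS-major vector used by .perm_counts (M vs M)
  vec_idx <- (ut[, 1] - 1L) * S + ut[, 2]
  counts <- .perm_counts(net, M, M, max(n_list), swaps_per_edge, seed)[vec_idx, , drop = FALSE]

  pairs <- data.frame(
    ags_id = names(gsc)[ut[, 1]],
    fgs_id = names(gsc)[ut[, 2]],
    size_sum = sizes[ut[, 1]] + sizes[ut[, 2]],
    degree_sum = deg[ut[, 1]] + deg[ut[, 2]],
    n_edges = obs,
    expected_edges = expd,
    p_csb = p_csb,
    stringsAsFactors = FALSE
  )
  p_floor <- 2 * stats::pnorm(-.Z_CAP)
  cors <- data.frame(n_randomizations = n_list, spearman_r = NA_real_,
                     n_pairs_used = NA_integer_, n_excluded = NA_integer_)
  for (idx in seq_along(n_list)) {
    N <- n_list[idx]
    sub <- counts[, seq_len(N), drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    z <- ifelse(s > 0, (obs - m) / s, NA_real_)
    p_nrz <- ifelse(s > 0, pmax(2 * stats::pnorm(-abs(z)), p_floor),
                    ifelse(obs == m, 1, p_floor))
    pairs[[paste0("p_nrz_", N)]] <- p_nrz
    pairs[[paste0("z_defined_", N)]] <- s > 0
    usable <- s > 0 & obs >= min_observed_edges
    if (sum(usable) >= 10L) {
      cors$spearman_r[idx] <- stats::cor(log10(pmax(p_nrz[usable], 1e-320)),
                                         log10(pmax(p_csb[usable], 1e-320)),
                                         method = "spearman")
    }
    cors$n_pairs_used[idx] <- sum(usable)
    cors$n_excluded[idx] <- sum(!usable)
  }
  if (max(cors$n_pairs_used) < 10L)
    stop("fewer than 10 usable pairs; increase the number of sets or network density")

  .tercile <- function(x) {
    br <- unique(stats::quantile(x, probs = c(0, 1/3, 2/3, 1)))
    if (length(br) < 2L) br <- c(min(x) - 1, max(x))
    cut(x, breaks = br, include.lowest = TRUE)
  }
  pairs$size_stratum <- cut(pairs$size_sum, breaks = c(0, 10, 30, Inf),
                            labels = c("<=10", "11-30", ">30"))
  pairs$degree_stratum <- .tercile(pairs$degree_sum)
  pairs$edges_stratum <- .tercile(pairs$n_edges)

  structure(list(
    correlations = cors,
    pairs = pairs,
    metadata = list(network = net$name, n_sets = S, n_list = n_list,
                    seed = seed, swaps_per_edge = swaps_per_edge,
                    variant = variant, min_observed_edges = min_observed_edges,
                    strict_overlap = strict_overlap)
  ), class = "nea_convergence")
}
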