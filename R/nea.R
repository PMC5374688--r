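## Parametric network-enrichment statistic (chi-squared binomial test).
##
## For an altered gene set (AGS) and a functional gene set (FGS) on a
## global network with N_total edges, the observed statistic is the number
## of edges connecting the two sets (edges lying entirely within either
## set are excluded), and the expected count under the configuration-model
## null is
##     n_hat = N_AGS * N_FGS / (2 * N_total)
## with N_AGS, N_FGS the degree sums of the sets. Enrichment/depletion is
## scored by a 1-df chi-squared on (n, N_total - n) against
## (n_hat, N_total - n_hat); z carries the direction.

# z cap used wherever a division by zero would send chi2 to infinity:
# pnorm(-38) underflows, so larger |z| is not representable as a p-value.
.Z_CAP <- 38
.CHI2_CAP <- .Z_CAP^2

#' Count network edges connecting two gene sets
#'
#' Counts edges with one endpoint in the AGS and the other in the FGS,
#' excluding any edge lying entirely within either set; equivalently, only
#' edges between `AGS \\ FGS` and `FGS \\ AGS` are counted. Symmetric in
#' its two set arguments.
#'
#' @param net an `nea_network`.
#' @param ags,fgs character vectors of gene ids, already restricted to the
#'   network's nodes.
#' @return a non-negative integer.
#' @export
count_connecting_edges <- function(net, ags, fgs) {
  ia <- match(unique(as.character(ags)), net$nodes)
  jf <- match(unique(as.character(fgs)), net$nodes)
  if (anyNA(ia) || anyNA(jf))
    stop("gene set contains genes absent from the network; restrict first")
  n <- length(net$nodes)
  inA <- inF <- logical(n)
  inA[ia] <- TRUE; inF[jf] <- TRUE
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  a1 <- inA[e1]; a2 <- inA[e2]; f1 <- inF[e1]; f2 <- inF[e2]
  sum((a1 & !f1) & (f2 & !a2)) + sum((f1 & !a1) & (a2 & !f2))
}

#' Expected number of connecting edges by chance
#'
#' The configuration-model expectation `N_AGS * N_FGS / (2 * N_total)`
#' from the degree sums of the two sets. Because the observed statistic
#' counts only edges between `AGS \\ FGS` and `FGS \\ AGS`, the default
#' (`strict_overlap = TRUE`) removes genes shared by both sets from both
#' degree sums, so that expectation and count refer to the same edge
#' population; without this the test is badly miscalibrated for
#' overlapping sets. `strict_overlap = FALSE` reproduces the historical
#' accounting over the full sets.
#'
#' @inheritParams count_connecting_edges
#' @param strict_overlap drop `AGS` \eqn{\cap} `FGS` genes from the degree
#'   sums (default); `FALSE` uses the full sets.
#' @return a non-negative double; warns when it exceeds `N_total`.
#' @export
expected_edges <- function(net, ags, fgs, strict_overlap = TRUE) {
  if (net$n_total_edges == 0L) stop("network has no edges")
  ags <- unique(as.character(ags)); fgs <- unique(as.character(fgs))
  if (strict_overlap) {
    both <- intersect(ags, fgs)
    ags <- setdiff(ags, both); fgs <- setdiff(fgs, both)
  }
  if (!length(ags) || !length(fgs)) return(0)
  e <- degree_sum(net, ags) * degree_sum(net, fgs) / (2 * net$n_total_edges)
  if (e > net$n_total_edges)
    warning(sprintf("expected edge count %.1f exceeds N_total = %d; degree sums dominate the network",
                    e, net$n_total_edges))
  e
}

#' Chi-squared score for an observed vs expected edge count
#'
#' One-degree-of-freedom chi-squared on the split of the network's
#' `n_total` edges into connecting (`n`) and other (`!n = n_total - n`)
#' edges. Two denominator conventions are available: the default
#' `"pearson"` divides the squared deviations by the expected counts; the
#' `"printed"` variant divides by the observed counts (and is undefined at
#' `n = 0`, where it falls back to the Pearson form with a warning).
#' Division-by-zero cells contribute 0 when their numerator is also 0;
#' otherwise the score is capped so that the derived |z| never exceeds 38.
#'
#' @param n integer vector of observed connecting-edge counts.
#' @param n_hat numeric vector of expected counts.
#' @param n_total total number of network edges.
#' @param variant `"pearson"` (expected denominators, default) or
#'   `"printed"` (observed denominators).
#' @return numeric vector of non-negative chi-squared scores (0 when
#'   `n == n_hat` exactly).
#' @export
chi2_statistic <- function(n, n_hat, n_total, variant = c("pearson", "printed")) {
  variant <- match.arg(variant)
  if (any(n < 0) || any(n_hat < 0)) stop("counts must be non-negative")
  if (any(n > n_total)) stop("observed count exceeds the number of network edges")
  k <- max(length(n), length(n_hat))
  n <- rep_len(as.numeric(n), k); n_hat <- rep_len(as.numeric(n_hat), k)
  xn <- n_total - n
  xnh <- n_total - n_hat
  term <- function(num, den) {
    ifelse(den > 0, num^2 / den, ifelse(num == 0, 0, Inf))
  }
  if (variant == "pearson") {
    chi2 <- term(n - n_hat, n_hat) + term(xn - xnh, xnh)
  } else {
    chi2 <- term(n - n_hat, n) + term(xn - xnh, xn)
    undef <- n == 0 & n_hat > 0
    if (any(undef)) {
      warning(sprintf("printed variant undefined for %d cell(s) with n = 0; using expected-count denominators there",
                      sum(undef)))
      chi2[undef] <- (term(n - n_hat, n_hat) + term(xn - xnh, xnh))[undef]
    }
  }
  pmin(chi2, .CHI2_CAP)
}

#' Enrichment statistics for a single AGS-FGS pair
#'
#' Combines the edge count, its expectation, the chi-squared score, the
#' upper-tail chi-squared p-value (1 df) and the direction-carrying
#' z-score. Because chi-squared lives on the non-negative axis, z is
#' recovered as `sqrt(chi2)` and coerced negative when the pair is
#' depleted (`n < n_hat`).
#'
#' @inheritParams expected_edges
#' @param variant see [chi2_statistic()].
#' @return a list with `n_edges`, `expected_edges`, `chi2`, `z`, `p` and
#'   `q` (`NA` until matrix-level adjustment, see [nea_render()]).
#' @export
pair_stats <- function(net, ags, fgs, variant = c("pearson", "printed"),
                       strict_overlap = TRUE) {
  variant <- match.arg(variant)
  n <- count_connecting_edges(net, ags, fgs)
  n_hat <- expected_edges(net, ags, fgs, strict_overlap = strict_overlap)
  chi2 <- chi2_statistic(n, n_hat, net$n_total_edges, variant)
  list(n_edges = n, expected_edges = n_hat, chi2 = chi2,
       z = sign(n - n_hat) * sqrt(chi2),
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       q = NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a thin, validating wrapper around
#' [stats::p.adjust()] that errors on missing values and preserves the
#' input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("p-values contain NA/NaN")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Single-gene functional sets from all network nodes
#'
#' One singleton FGS per network node, with the gene id as set id. Network
#' density gives the edge-count model enough power to score individual
#' genes, which overlap-based enrichment cannot do.
#'
#' @param net an `nea_network`.
#' @return a `gene_set_collection` with role `"FGS"`.
#' @export
single_gene_fgs <- function(net) {
  sets <- as.list(net$nodes)
  names(sets) <- net$nodes
  gene_set_collection(sets, role = "FGS")
}

# internal: node x set logical membership matrix
.membership <- function(net, gsc) {
  M <- matrix(FALSE, length(net$nodes), length(gsc),
              dimnames = list(NULL, names(gsc)))
  for (i in seq_along(gsc)) {
    idx <- match(gsc[[i]], net$nodes)
    if (anyNA(idx))
      stop("set '", names(gsc)[i], "' contains genes absent from the network; restrict first")
    M[idx, i] <- TRUE
  }
  M
}

# internal: count matrix (|AGS sets| x |FGS sets|) of connecting edges for
# one edge list, with the within-set exclusion rule. Works off the
# bilinear expansion of the indicator product
#   1[u in A\F] 1[v in F\A] = a_u f_v (1 - f_u)(1 - a_v),
# which turns the per-pair sum over edges into four cross-products.
.count_between <- function(e1, e2, MA, MF) {
  XA <- MA[e1, , drop = FALSE] + 0; YA <- MA[e2, , drop = FALSE] + 0
  if (identical(dim(MA), dim(MF)) && identical(MA, MF)) {
    XF <- XA; YF <- YA
  } else {
    XF <- MF[e1, , drop = FALSE] + 0; YF <- MF[e2, , drop = FALSE] + 0
  }
  WA <- XA * YA; WF <- XF * YF
  h <- function(P, Q, R, S) {
    crossprod(P, S) - crossprod(P, R * S) - crossprod(P * Q, S) + crossprod(P * Q, R * S)
  }
  cnt <- h(XA, YA, XF, YF) + h(YA, XA, YF, XF)
  storage.mode(cnt) <- "integer"
  cnt
}

#' Render the full AGS x FGS matrix of network-enrichment scores
#'
#' Scores every pair of one altered and one functional gene set, then
#' adjusts p-values jointly over all cells by Benjamini-Hochberg. The
#' edge-counting step can be split across parallel jobs; partitioning
#' never changes any value or the row ordering.
#'
#' @param net an `nea_network`.
#' @param ags_coll,fgs_coll `gene_set_collection`s (or named lists),
#'   already restricted to the network.
#' @param variant chi-squared denominator convention, see
#'   [chi2_statistic()].
#' @param jobs number of parallel forked workers for edge counting.
#' @param strict_overlap see [expected_edges()].
#' @return a data.frame of class `nea_result` with columns `ags_id`,
#'   `fgs_id`, `n_edges`, `expected_edges`, `chi2`, `z`, `p`, `q` (one row
#'   per pair, AGS-major order) and a `metadata` attribute.
#' @export
nea_render <- function(net, ags_coll, fgs_coll, variant = c("pearson", "printed"),
                       jobs = 1L, strict_overlap = TRUE) {
  variant <- match.arg(variant)
  if (!length(ags_coll) || !length(fgs_coll)) stop("empty gene set collection")
  if (is.null(names(ags_coll)) || is.null(names(fgs_coll)))
    stop("gene set collections must be named")
  n_tests <- length(ags_coll) * length(fgs_coll)
  if (n_tests < 200)
    warning(sprintf("only %d AGS-FGS tests; q-values are poorly estimable below a few hundred tests",
                    n_tests))
  MA <- .membership(net, ags_coll)
  MF <- .membership(net, fgs_coll)
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  jobs <- max(1L, as.integer(jobs))
  if (jobs == 1L || length(ags_coll) == 1L) {
    cnt <- .count_between(e1, e2, MA, MF)
  } else {
    chunks <- split(seq_along(ags_coll),
                    ceiling(seq_along(ags_coll) / ceiling(length(ags_coll) / jobs)))
    parts <- parallel::mclapply(chunks, function(ix) {
      .count_between(e1, e2, MA[, ix, drop = FALSE], MF)
    }, mc.cores = jobs)
    cnt <- do.call(rbind, parts)
  }
  degA <- as.numeric(colSums(MA * net$degree))
  degF <- as.numeric(colSums(MF * net$degree))
  if (strict_overlap) {
    # per-pair degree sum of shared genes; subtracting it from each side's
    # total leaves the degree sums of AGS\FGS and FGS\AGS (never negative)
    ov <- crossprod(MA * net$degree, MF + 0)
    expd <- (outer(degA, rep(1, length(degF))) - ov) *
      (outer(rep(1, length(degA)), degF) - ov) / (2 * net$n_total_edges)
  } else {
    expd <- outer(degA, degF) / (2 * net$n_total_edges)
  }
  nvec <- as.vector(t(cnt))        # AGS-major: rows = AGS, inner loop FGS
  evec <- as.vector(t(expd))
  chi2 <- chi2_statistic(nvec, evec, net$n_total_edges, variant)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  z <- sign(nvec - evec) * sqrt(chi2)
  res <- data.frame(
    ags_id = rep(names(ags_coll), each = length(fgs_coll)),
    fgs_id = rep(names(fgs_coll), times = length(ags_coll)),
    n_edges = nvec,
    expected_edges = evec,
    chi2 = chi2,
    z = z,
    p = p,
    q = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  attr(res, "metadata") <- list(
    network = net$name,
    n_total_edges = net$n_total_edges,
    variant = variant,
    strict_overlap = strict_overlap,
    jobs = jobs,
    n_tests = n_tests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(res) <- c("nea_result", "data.frame")
  res
}
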