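## Network-quality benchmark: can the network "rediscover" known members
## of functional gene sets? Every FGS member, held out of its set, is a
## positive test case; degree-matched random outsiders tested against the
## same reduced set are the negatives. Sweeping the enrichment z threshold
## yields ROC curves and AUC, comparable across candidate networks.

#' ROC curve and AUC from scored test cases
#'
#' Threshold sweep over the distinct scores (ties grouped), counting
#' TP/FP/TN/FN at each threshold ("score >= threshold" predicts positive).
#' The trapezoidal AUC equals the Mann-Whitney pairwise-ordering
#' probability, counting ties as half.
#'
#' @param scores numeric vector.
#' @param truth logical (or "positive"/"negative") vector, same length.
#' @return a list with `roc` (data.frame `threshold, TP, FP, TN, FN, FPR,
#'   TPR`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) truth <- as.character(truth) == "positive"
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  P <- sum(truth); N <- sum(!truth)
  if (P == 0L || N == 0L) stop("need at least one positive and one negative case")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(-scores)
  sc <- scores[ord]; tr <- truth[ord]
  cum_tp <- cumsum(tr); cum_fp <- cumsum(!tr)
  last <- length(sc) - match(thr, rev(sc)) + 1L  # last index with score >= thr
  roc <- data.frame(
    threshold = c(Inf, thr),
    TP = c(0L, cum_tp[last]),
    FP = c(0L, cum_fp[last])
  )
  roc$TN <- N - roc$FP
  roc$FN <- P - roc$TP
  roc$FPR <- roc$FP / N
  roc$TPR <- roc$TP / P
  auc <- sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Leave-one-member ROC benchmark of a network
#'
#' One test case per FGS membership (a gene occurring in several FGS is
#' tested once per set). The positive case scores the singleton AGS
#' `{gene}` against its set with the gene removed; for each positive,
#' degree-matched genes outside the set are sampled (seeded) and scored
#' against the same reduced set as negatives. A good network ranks true
#' members above degree-matched impostors.
#'
#' @param net an `nea_network`.
#' @param fgs_coll a `gene_set_collection`, restricted to the network;
#'   sets need at least 2 members.
#' @param negatives_per_positive negatives sampled per positive case.
#' @param degree_tolerance relative degree window for matching (0.25 =
#'   within +/-25% of the held-out gene's degree); doubled with a warning
#'   up to 4 times when no candidate exists, then the case is skipped.
#' @param seed integer RNG seed.
#' @param variant chi-squared convention used for scoring.
#' @return a list of class `nea_benchmark`: `cases` (data.frame `gene,
#'   fgs_id, truth, score`), `roc`, `auc`, `skipped`, `metadata`.
#' @export
benchmark_network <- function(net, fgs_coll, negatives_per_positive = 1L,
                              degree_tolerance = 0.25, seed = 1L,
                              variant = c("pearson", "printed")) {
  variant <- match.arg(variant)
  if (any(lengths(fgs_coll) < 2L)) stop("every FGS needs at least 2 members for hold-one-out scoring")
  nn <- length(net$nodes)
  deg <- net$degree
  # adjacency as index list for fast single-gene counting
  adj <- vector("list", nn)
  ord_e <- c(net$edges[, 1], net$edges[, 2])
  other <- c(net$edges[, 2], net$edges[, 1])
  sp <- split(other, ord_e)
  adj[as.integer(names(sp))] <- sp
  two_E <- 2 * net$n_total_edges

  score_one <- function(g_idx, set_idx) {
    nbr <- adj[[g_idx]]
    n <- if (is.null(nbr)) 0L else sum(nbr %in% set_idx)
    n_hat <- deg[g_idx] * sum(deg[set_idx]) / two_E
    chi2 <- chi2_statistic(n, n_hat, net$n_total_edges, variant)
    sign(n - n_hat) * sqrt(chi2)
  }

  set.seed(seed)
  doubled <- 0L
  cases <- list(); skipped <- 0L
  for (si in seq_along(fgs_coll)) {
    set_idx_full <- match(fgs_coll[[si]], net$nodes)
    if (anyNA(set_idx_full))
      stop("set '", names(fgs_coll)[si], "' contains genes absent from the network; restrict first")
    in_set <- logical(nn); in_set[set_idx_full] <- TRUE
    for (g_idx in set_idx_full) {
      reduced <- setdiff(set_idx_full, g_idx)
      pos_score <- score_one(g_idx, reduced)
      d0 <- deg[g_idx]
      tol <- degree_tolerance
      cand <- integer(0)
      for (tries in 0:4) {
        cand <- which(!in_set & abs(deg - d0) <= tol * d0)
        if (length(cand) >= negatives_per_positive) break
        tol <- tol * 2
        doubled <- doubled + 1L
      }
      if (length(cand) < negatives_per_positive) { skipped <- skipped + 1L; next }
      negs <- if (length(cand) == 1L) cand else sample(cand, negatives_per_positive)
      neg_scores <- vapply(negs, score_one, 0, set_idx = reduced)
      cases[[length(cases) + 1L]] <- data.frame(
        gene = c(net$nodes[g_idx], net$nodes[negs]),
        fgs_id = names(fgs_coll)[si],
        truth = c("positive", rep("negative", length(negs))),
        score = c(pos_score, neg_scores),
        stringsAsFactors = FALSE
      )
    }
  }
  if (doubled > 0L)
    warning(sprintf("degree-matching window doubled %d time(s); %d case(s) skipped", doubled, skipped))
  cases <- do.call(rbind, cases)
  if (is.null(cases)) stop("no benchmark cases could be scored")
  ra <- roc_auc(cases$score, cases$truth)
  structure(list(
    cases = cases, roc = ra$roc, auc = ra$auc, skipped = skipped,
    metadata = list(network = net$name, negatives_per_positive = negatives_per_positive,
                    degree_tolerance = degree_tolerance, seed = seed, variant = variant)
  ), class = "nea_benchmark")
}

#' @export
print.nea_benchmark <- function(x, ...) {
  cat(sprintf("<nea_benchmark: %d cases (%d positive), AUC = %.3f>\n",
              nrow(x$cases), sum(x$cases$truth == "positive"), x$auc))
  invisible(x)
}
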