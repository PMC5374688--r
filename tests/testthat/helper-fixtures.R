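# Shared fixtures and independent brute-force oracles. The oracles never
# reuse package internals: they enumerate edges, set members and point
# masses directly, so agreement with the package is a real check.

toy_network <- function() {
  # A-B, B-C, C-A, C-D: degrees A2 B2 C3 D1, N_total = 4
  new_network(c("A", "B", "C", "C"), c("B", "C", "A", "D"))
}

# Erdos-Renyi-style random simple graph with at least one edge
random_graph <- function(n_nodes, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  new_network(ids[pairs[keep, 1]], ids[pairs[keep, 2]], nodes = ids)
}

random_subset <- function(net, k) sample(net$nodes, min(k, length(net$nodes)))

# brute force: double loop over edges with the within-set exclusion rule
bf_count_edges <- function(net, A, F_) {
  cnt <- 0L
  for (k in seq_len(net$n_total_edges)) {
    u <- net$nodes[net$edges[k, 1]]
    v <- net$nodes[net$edges[k, 2]]
    connects <- (u %in% A && v %in% F_) || (v %in% A && u %in% F_)
    within_A <- u %in% A && v %in% A
    within_F <- u %in% F_ && v %in% F_
    if (connects && !within_A && !within_F) cnt <- cnt + 1L
  }
  cnt
}

bf_degree_sum <- function(net, genes) {
  total <- 0L
  for (g in genes) {
    for (k in seq_len(net$n_total_edges)) {
      u <- net$nodes[net$edges[k, 1]]
      v <- net$nodes[net$edges[k, 2]]
      if (u == g || v == g) total <- total + 1L
    }
  }
  total
}

bf_expected_edges <- function(net, A, F_, strict = TRUE) {
  if (strict) {
    both <- intersect(A, F_)
    A <- setdiff(A, both)
    F_ <- setdiff(F_, both)
  }
  if (!length(A) || !length(F_)) return(0)
  bf_degree_sum(net, A) * bf_degree_sum(net, F_) / (2 * net$n_total_edges)
}

bf_chi2 <- function(n, n_hat, n_total, variant = "pearson") {
  xn <- n_total - n
  xnh <- n_total - n_hat
  piece <- function(num, den) if (den > 0) num^2 / den else if (num == 0) 0 else Inf
  if (variant == "pearson") {
    piece(n - n_hat, n_hat) + piece(xn - xnh, xnh)
  } else {
    piece(n - n_hat, n) + piece(xn - xnh, xn)
  }
}

# independent BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    cand <- vapply(r:m, function(j) p[ord[j]] * m / j, 0)
    q[i] <- min(1, cand)
  }
  q
}

# hypergeometric upper tail P(X >= a) by explicit point-mass summation
bf_hyper_tail <- function(U, sizeA, sizeF, a) {
  kmax <- min(sizeA, sizeF)
  if (a > kmax) return(0)
  sum(vapply(a:kmax, function(k) {
    choose(sizeA, k) * choose(U - sizeA, sizeF - k) / choose(U, sizeF)
  }, 0))
}

# AUC as the Mann-Whitney pairwise ordering probability (ties = 1/2)
bf_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (ps in pos) for (ns in neg) tot <- tot + (ps > ns) + 0.5 * (ps == ns)
  tot / (length(pos) * length(neg))
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
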