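## Topology diagnostics. The parametric enrichment model is unbiased only
## on scale-free networks (power-law degree distribution), so the package
## ships visual-inspection aids for degree structure: the degree histogram
## with a log-log power-law fit, and second-order structure (mean
## neighbor degree per degree class, degree-degree assortativity).

#' Degree distribution and scale-freeness diagnostic
#'
#' Tabulates the degree histogram and fits a least-squares line to
#' (log10 degree, log10 count) over degrees with nonzero count and
#' degree > 0. In a scale-free network the points fall on a line with
#' slope around -2 to -3. By default raw degree-count pairs enter the fit
#' (transparent, if noisy in the tail); `binned = TRUE` averages counts
#' within logarithmic (powers-of-2) degree bins first.
#'
#' @param net an `nea_network`.
#' @param binned use logarithmic binning for the fit.
#' @return a list of class `topology_summary` with `histogram`
#'   (data.frame `degree, count`), `loglog_slope`, `loglog_r2`, and
#'   `fitted` (FALSE when fewer than 3 distinct positive degrees exist;
#'   slope and R^2 are then `NA`).
#' @export
connectivity <- function(net, binned = FALSE) {
  tab <- table(net$degree)
  hist <- data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  pos <- hist[hist$degree > 0, , drop = FALSE]
  out <- list(histogram = hist, loglog_slope = NA_real_, loglog_r2 = NA_real_,
              fitted = FALSE)
  if (nrow(pos) >= 3L) {
    if (binned) {
      bin <- floor(log2(pos$degree))
      xd <- tapply(pos$degree, bin, function(d) exp(mean(log(d))))
      yc <- tapply(pos$count, bin, mean)
      x <- log10(as.numeric(xd)); y <- log10(as.numeric(yc))
    } else {
      x <- log10(pos$degree); y <- log10(pos$count)
    }
    if (length(unique(x)) >= 3L) {
      fit <- stats::lm(y ~ x)
      out$loglog_slope <- unname(stats::coef(fit)[2])
      out$loglog_r2 <- summary(fit)$r.squared
      out$fitted <- TRUE
    }
  }
  class(out) <- "topology_summary"
  out
}

#' Second-order degree structure
#'
#' For every degree class d, the mean over nodes of degree d of the mean
#' degree of their neighbors, plus the degree-degree Pearson correlation
#' across edge endpoints (both orientations) as the assortativity
#' coefficient. High-degree hubs avoiding each other (disassortativity,
#' common in biological networks) shows as a falling curve and a negative
#' coefficient; such second-order structure is exactly what simple
#' degree-preserving rewiring may not conserve.
#'
#' @param net an `nea_network` with at least one edge.
#' @return a list of class `topology_summary` with `neighbor_degree`
#'   (data.frame `degree, mean_neighbor_degree`), `assortativity`, and
#'   `assortativity_defined` (`FALSE` for degree-regular networks, where
#'   the correlation is undefined).
#' @export
topology2nd <- function(net) {
  if (net$n_total_edges == 0L) stop("network has no edges")
  deg <- as.numeric(net$degree)
  e1 <- net$edges[, 1]; e2 <- net$edges[, 2]
  # per-node mean neighbor degree, then averaged within degree classes
  nbr_deg_sum <- rep(0, length(net$nodes))
  tmp <- tapply(c(deg[e2], deg[e1]), c(e1, e2), sum)
  nbr_deg_sum[as.integer(names(tmp))] <- tmp
  has_edge <- deg > 0
  node_mnd <- nbr_deg_sum[has_edge] / deg[has_edge]
  cls <- tapply(node_mnd, deg[has_edge], mean)
  neighbor_degree <- data.frame(degree = as.integer(names(cls)),
                                mean_neighbor_degree = as.numeric(cls))
  x <- c(deg[e1], deg[e2]); y <- c(deg[e2], deg[e1])
  defined <- stats::sd(x) > 0
  assort <- if (defined) stats::cor(x, y) else NA_real_
  structure(list(neighbor_degree = neighbor_degree,
                 assortativity = assort,
                 assortativity_defined = defined),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  if (!is.null(x$histogram)) {
    cat(sprintf("<topology_summary: %d degree classes; log-log slope %s (R2 %s)>\n",
                nrow(x$histogram),
                if (isTRUE(x$fitted)) sprintf("%.2f", x$loglog_slope) else "not fitted",
                if (isTRUE(x$fitted)) sprintf("%.2f", x$loglog_r2) else "-"))
  } else {
    cat(sprintf("<topology_summary: assortativity %s>\n",
                if (isTRUE(x$assortativity_defined)) sprintf("%.3f", x$assortativity) else "undefined"))
  }
  invisible(x)
}
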