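## Seeded synthetic generators: scale-free networks, planted functional
## modules, null gene sets and expression-like matrices. These make every
## analysis in the package testable offline, with known ground truth.

#' Generate a scale-free network by preferential attachment
#'
#' Growth model: starting from m isolated seed nodes, each new node
#' attaches m edges to distinct existing nodes sampled with probability
#' proportional to degree + 1. The resulting degree distribution is heavy
#' tailed (power law in the large-n limit), matching the regime in which
#' the parametric enrichment model is unbiased. The edge count is exactly
#' `m * (n_nodes - m)`.
#'
#' @param n_nodes number of nodes (> m).
#' @param m edges attached per new node (>= 1).
#' @param seed integer RNG seed.
#' @return an `nea_network` with node ids `g000001`, `g000002`, ...
#' @export
make_scalefree_network <- function(n_nodes, m, seed = 1L) {
  n_nodes <- as.integer(n_nodes); m <- as.integer(m)
  if (m < 1L || n_nodes <= m) stop("need n_nodes > m >= 1")
  set.seed(seed)
  deg <- integer(n_nodes)
  n_edges <- m * (n_nodes - m)
  from <- integer(n_edges); to <- integer(n_edges)
  ptr <- 0L
  for (t in (m + 1L):n_nodes) {
    targets <- sample.int(t - 1L, m, prob = deg[seq_len(t - 1L)] + 1)
    idx <- ptr + seq_len(m)
    from[idx] <- t; to[idx] <- targets
    deg[targets] <- deg[targets] + 1L
    deg[t] <- m
    ptr <- ptr + m
  }
  ids <- sprintf("g%06d", seq_len(n_nodes))
  new_network(ids[from], ids[to], nodes = ids,
              name = sprintf("scalefree_n%d_m%d_s%d", n_nodes, m, seed))
}

#' Uniformly random gene sets from network nodes
#'
#' Null gene sets for calibration: each set samples its members uniformly
#' without replacement from the network's nodes.
#'
#' @param net an `nea_network`.
#' @param n_sets number of sets.
#' @param sizes integer vector of set sizes, recycled to `n_sets`.
#' @param seed integer RNG seed.
#' @return a `gene_set_collection` (role FGS) with ids `rs001`, ...
#' @export
make_random_gene_sets <- function(net, n_sets, sizes, seed = 1L) {
  sizes <- rep_len(as.integer(sizes), n_sets)
  if (any(sizes < 1L)) stop("set sizes must be positive")
  if (any(sizes > length(net$nodes))) stop("set size exceeds the number of network nodes")
  set.seed(seed)
  sets <- lapply(sizes, function(k) sample(net$nodes, k))
  names(sets) <- sprintf("rs%03d", seq_len(n_sets))
  gene_set_collection(sets, role = "FGS")
}

#' Plant functional modules into a network
#'
#' Samples pairwise-disjoint node sets and densifies each to a target
#' edge density of `boost` times the network's background density, both
#' among the set's members and from members to a per-set random shared
#' neighbor pool. This creates the two signals the package's analyses
#' look for: between/within-set edge enrichment for the network test and
#' member-versus-set connectivity for the benchmark. `boost = 1` leaves
#' the network untouched.
#'
#' @param net an `nea_network`.
#' @param n_sets number of planted modules.
#' @param size_range length-2 integer range of module sizes (sampled
#'   uniformly).
#' @param boost target within/incident edge density as a multiple of the
#'   background density (>= 1). Default 10, a typical enrichment level of
#'   curated pathways over the interactome background.
#' @param seed integer RNG seed.
#' @return a list with `network` (augmented `nea_network`) and `sets`
#'   (a `gene_set_collection`, role FGS, ids `mod01`, ...).
#' @export
make_planted_fgs <- function(net, n_sets, size_range = c(20L, 50L), boost = 10,
                             seed = 1L) {
  if (boost < 1) stop("boost must be >= 1")
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  n <- length(net$nodes)
  if (sum(sizes) + max(sizes) > n)
    stop("cannot place ", n_sets, " disjoint sets (plus neighbor pools) in a ", n, "-node network")
  perm <- sample.int(n, sum(sizes))
  members <- split(perm, rep(seq_len(n_sets), times = sizes))
  sets <- lapply(members, function(ix) net$nodes[ix])
  names(sets) <- sprintf("mod%02d", seq_len(n_sets))
  gsc <- gene_set_collection(sets, role = "FGS")
  if (boost == 1) return(list(network = net, sets = gsc))

  bg_density <- 2 * net$n_total_edges / (n * (n - 1))
  ekey <- paste(net$edges[, 1], net$edges[, 2])
  add_from <- integer(0); add_to <- integer(0)
  outside <- setdiff(seq_len(n), perm)
  for (si in seq_len(n_sets)) {
    ix <- members[[si]]; k <- length(ix)
    # candidate internal pairs not already edges
    cand <- t(utils::combn(sort(ix), 2L))
    cand <- cand[!paste(cand[, 1], cand[, 2]) %in% ekey, , drop = FALSE]
    target <- round(boost * bg_density * choose(k, 2))
    have <- choose(k, 2) - nrow(cand)
    need <- min(max(0L, target - have), nrow(cand))
    if (need > 0L) {
      pick <- cand[sample.int(nrow(cand), need), , drop = FALSE]
      add_from <- c(add_from, pick[, 1]); add_to <- c(add_to, pick[, 2])
    }
    # shared neighbor pool: extra member-to-pool edges at the same density
    pool <- sample(outside, min(k, length(outside)))
    pc <- expand.grid(a = ix, b = pool)
    pkey <- paste(pmin(pc$a, pc$b), pmax(pc$a, pc$b))
    pc <- pc[!pkey %in% ekey, , drop = FALSE]
    target_p <- round(boost * bg_density * k * length(pool))
    have_p <- k * length(pool) - nrow(pc)
    need_p <- min(max(0L, target_p - have_p), nrow(pc))
    if (need_p > 0L) {
      pick <- pc[sample.int(nrow(pc), need_p), , drop = FALSE]
      add_from <- c(add_from, pick$a); add_to <- c(add_to, pick$b)
    }
  }
  aug <- new_network(
    net$nodes[c(net$edges[, 1], add_from)],
    net$nodes[c(net$edges[, 2], add_to)],
    nodes = net$nodes,
    name = paste0(net$name, "_planted")
  )
  list(network = aug, sets = gsc)
}

#' Simulate an expression-like matrix with known differential genes
#'
#' Two-group (or multi-group) log2-scale expression: per-gene baseline
#' means, a fraction of genes shifted between the first and each later
#' group by +/- `effect` log2 units, and Gaussian replicate noise. The
#' returned truth table lets AGS builders be validated for recall against
#' the planted differential genes.
#'
#' @param n_genes number of gene rows.
#' @param groups integer vector (length >= 2) of replicate counts per
#'   group; names become group labels (defaults `A`, `B`, ...). Default
#'   `c(A = 3, B = 3)`, a typical small replicated design.
#' @param de_fraction fraction of genes differentially expressed.
#' @param effect absolute group shift for differential genes, log2 units.
#'   Default 4 (a 16-fold change, a strong, unambiguous signal).
#' @param noise_sd replicate noise standard deviation (log2 units).
#' @param seed integer RNG seed.
#' @return a list with `matrix` (genes x samples), `truth` (data.frame
#'   `gene, is_de, direction`), and `groups` (factor over columns).
#' @export
make_expression_matrix <- function(n_genes = 2000L, groups = c(A = 3L, B = 3L),
                                   de_fraction = 0.1, effect = 4, noise_sd = 0.5,
                                   seed = 1L) {
  if (length(groups) < 2L || any(groups < 1L)) stop("need >= 2 groups with >= 1 replicate each")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must lie in [0, 1]")
  if (de_fraction * n_genes < 1) warning("de_fraction * n_genes < 1: no differential gene will be planted")
  if (is.null(names(groups))) names(groups) <- LETTERS[seq_along(groups)]
  set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, mean = 6, sd = 2)
  n_de <- if (effect == 0) 0L else floor(de_fraction * n_genes)  # zero effect: all-null truth
  de_idx <- if (n_de >= 1L) sample.int(n_genes, n_de) else integer(0)
  direction <- integer(n_genes)
  direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  grp <- factor(rep(names(groups), times = groups), levels = names(groups))
  mat <- matrix(0, n_genes, length(grp),
                dimnames = list(genes, paste0(rep(names(groups), times = groups), "_r",
                                              unlist(lapply(groups, seq_len)))))
  for (j in seq_along(grp)) {
    shift <- if (grp[j] == names(groups)[1]) 0 else direction * effect
    mat[, j] <- base + shift + stats::rnorm(n_genes, sd = noise_sd)
  }
  truth <- data.frame(gene = genes, is_de = direction != 0L, direction = direction,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth, groups = grp)
}

#' Group-mean log fold changes from an expression matrix
#'
#' Convenience contrast builder: difference of group means (later groups
#' minus the first) per gene, one column per contrast - the score matrix
#' the AGS builders expect when samples carry replicates.
#'
#' @param mat genes x samples numeric matrix.
#' @param groups factor over the columns of `mat`.
#' @return genes x contrasts numeric matrix with columns like `B_vs_A`.
#' @export
group_fold_change <- function(mat, groups) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(mat)) stop("`groups` must have one entry per matrix column")
  lv <- levels(groups)
  means <- vapply(lv, function(g) rowMeans(mat[, groups == g, drop = FALSE]),
                  numeric(nrow(mat)))
  fc <- means[, -1, drop = FALSE] - means[, 1]
  colnames(fc) <- paste0(lv[-1], "_vs_", lv[1])
  fc
}
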