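#' Construct a network object from an edge list
#'
#' Builds the undirected simple graph used throughout the package from a
#' two-column character edge list. Self-loops are dropped and duplicate
#' (including reversed) pairs collapsed, so the result satisfies the
#' invariants of an unweighted simple graph: the sum of all node degrees
#' equals twice the edge count.
#'
#' @param from,to character vectors of equal length giving edge endpoints.
#' @param nodes optional character vector of node ids; nodes not appearing
#'   in any edge are kept as isolated vertices. Defaults to the endpoints
#'   in first-appearance order.
#' @param weights optional numeric vector of per-edge confidences. Parsed
#'   and carried along, but ignored by every statistic in the package.
#' @param name a label stored in result metadata.
#' @return an object of class `nea_network`: a list with elements
#'   `nodes` (character), `edges` (integer matrix, one row per edge,
#'   indices into `nodes`, smaller index first), `degree` (named integer),
#'   `n_total_edges` (the N_total of the enrichment model), `name`, and
#'   optionally `weights`.
#' @export
new_network <- function(from, to, nodes = NULL, weights = NULL, name = "network") {
  stopifnot(length(from) == length(to))
  from <- as.character(from); to <- as.character(to)
  if (is.null(nodes)) nodes <- unique(as.vector(rbind(from, to)))
  nodes <- as.character(nodes)
  i <- match(from, nodes); j <- match(to, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not present in `nodes`")
  loop <- i == j
  if (any(loop)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loop)))
    i <- i[!loop]; j <- j[!loop]
    if (!is.null(weights)) weights <- weights[!loop]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  edges <- cbind(lo[keep], hi[keep])
  if (!is.null(weights)) weights <- weights[keep]
  deg <- tabulate(as.vector(edges), nbins = length(nodes))
  names(deg) <- nodes
  structure(list(
    nodes = nodes,
    edges = edges,
    degree = deg,
    n_total_edges = nrow(edges),
    name = name,
    weights = weights
  ), class = "nea_network")
}

#' Read a network from a 2-3 column TSV file
#'
#' Expects one edge per line: two node ids and an optional numeric
#' confidence, separated by tabs (or any whitespace). Lines starting with
#' `#` are comments. Duplicate pairs, reversed duplicates and self-loops
#' are collapsed/dropped as in [new_network()].
#'
#' @param path path to the edge-list file.
#' @param keep_weights if `TRUE`, a third column is parsed and stored;
#'   weights never enter any score.
#' @param normalize_ids if `TRUE`, node ids are upper-cased before use.
#'   Off by default: ids are case-sensitive opaque strings.
#' @return an `nea_network`.
#' @export
read_network <- function(path, keep_weights = FALSE, normalize_ids = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("network file '", path, "' contains no edges")
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed network line %d in '%s': expected 2-3 fields, got %d",
                 lineno[bad[1]], path, nf[bad[1]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  if (normalize_ids) { from <- toupper(from); to <- toupper(to) }
  w <- NULL
  if (keep_weights && any(nf == 3L)) {
    w <- rep(NA_real_, length(fields))
    w[nf == 3L] <- as.numeric(vapply(fields[nf == 3L], `[[`, "", 3L))
  }
  new_network(from, to, weights = w, name = basename(path))
}

#' @export
print.nea_network <- function(x, ...) {
  cat(sprintf("<nea_network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), x$n_total_edges))
  invisible(x)
}

#' Sum of node degrees over a gene set
#'
#' The N_AGS / N_FGS quantity of the enrichment model: the sum of
#' connectivities of the set's members in the network.
#'
#' @param net an `nea_network`.
#' @param genes character vector of gene ids; every gene must be a network
#'   node (restrict the collection first, see [restrict_to_network()]).
#' @return a non-negative integer.
#' @export
degree_sum <- function(net, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) return(0L)
  idx <- match(genes, net$nodes)
  if (anyNA(idx)) {
    stop("gene(s) not in network: ", paste(utils::head(genes[is.na(idx)], 5), collapse = ", "),
         "; restrict the gene set to the network first")
  }
  sum(net$degree[idx])
}

# internal: edges of `net` as an igraph object over integer vertex ids
.net_to_igraph <- function(net) {
  igraph::make_empty_graph(n = length(net$nodes), directed = FALSE) +
    igraph::edges(as.vector(t(net$edges)))
}

.igraph_to_net <- function(g, net, name = net$name) {
  el <- igraph::as_edgelist(g, names = FALSE)
  new_network(net$nodes[el[, 1]], net$nodes[el[, 2]],
              nodes = net$nodes, name = name)
}
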