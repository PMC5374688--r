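#' Construct a gene set collection
#'
#' A collection is a named list of character vectors (one per set), with a
#' role tag saying whether it is used as altered gene sets (AGS) or
#' functional gene sets (FGS). Iteration order is insertion order and set
#' ids must be unique; members are deduplicated.
#'
#' @param sets named list of character vectors.
#' @param role `"AGS"` or `"FGS"`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, role = c("FGS", "AGS")) {
  role <- match.arg(role)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a non-empty id")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set id(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, class = "gene_set_collection", role = role)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection (%s): %d sets, sizes %s>\n",
              attr(x, "role"), length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read gene sets from GMT or long-format TSV
#'
#' GMT: one set per line, `set-id<TAB>description<TAB>member...`.
#' Long format: two tab-separated columns `gene, set-id`. Members are
#' deduplicated per set and set order is preserved. Sets that end up empty
#' are dropped with a warning; a duplicated set id is an error.
#'
#' @param path file path.
#' @param format `"gmt"` or `"long"`.
#' @param role role tag for the resulting collection.
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path, format = c("gmt", "long"), role = c("FGS", "AGS")) {
  format <- match.arg(format)
  role <- match.arg(role)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("gene set file '", path, "' is empty")
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
      stop("duplicate set id(s) in '", path, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- ids
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 2L))
      stop("long-format gene set file '", path, "' must have 2 tab-separated columns (gene, set-id)")
    gene <- vapply(fields, `[[`, "", 1L)
    set <- vapply(fields, `[[`, "", 2L)
    sets <- lapply(split(gene, factor(set, levels = unique(set))), unique)
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropped %d empty gene set(s): %s", sum(empty),
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no non-empty gene sets in '", path, "'")
  gene_set_collection(sets, role = role)
}

#' Write a gene set collection as GMT
#'
#' @param gsc a `gene_set_collection`.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the role tag).
#' @export
write_gene_sets <- function(gsc, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep(attr(gsc, "role") %||% "NA", length(gsc))
  lines <- vapply(seq_along(gsc), function(i) {
    paste(c(names(gsc)[i], descriptions[i], gsc[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a gene set collection to network nodes
#'
#' Intersects every set with the network's node list; AGS, FGS and NET
#' must share one id format, so genes absent from the network carry no
#' degree and cannot enter the model. Dropped genes are counted in a
#' warning; sets emptied by the restriction are removed.
#'
#' @param gsc a `gene_set_collection` (or named list).
#' @param net an `nea_network`.
#' @return the restricted `gene_set_collection`.
#' @export
restrict_to_network <- function(gsc, net) {
  role <- attr(gsc, "role") %||% "FGS"
  restricted <- lapply(gsc, function(s) intersect(as.character(s), net$nodes))
  dropped <- lengths(gsc) - lengths(restricted)
  if (any(dropped > 0L)) {
    warning(sprintf("dropped %d gene(s) absent from network '%s' across %d set(s)",
                    sum(dropped), net$name, sum(dropped > 0L)))
  }
  empty <- lengths(restricted) == 0L
  if (all(empty)) stop("all gene sets empty after restriction to network '", net$name, "'")
  if (any(empty)) {
    warning(sprintf("removed %d set(s) with no genes in network: %s", sum(empty),
                    paste(names(restricted)[empty], collapse = ", ")))
    restricted <- restricted[!empty]
  }
  gene_set_collection(restricted, role = role)
}
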