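## Builders for altered gene sets (AGS): the sample-specific input side of
## the enrichment analysis. Scores are used as given (typically log2 fold
## changes); no internal normalization is applied.

.check_score_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric genes x samples matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("score matrix needs unique row names (gene ids)")
  if (is.null(colnames(m))) stop("score matrix needs column names (sample ids)")
  invisible(m)
}

# NaN/NA scores never enter ranking or thresholding; counted per column
.drop_na_scores <- function(x, column) {
  bad <- is.na(x)
  if (any(bad)) message(sprintf("column '%s': excluded %d missing score(s)", column, sum(bad)))
  x[!bad]
}

#' Top-n altered gene sets by absolute score
#'
#' Per sample column, the n genes with the largest absolute scores (e.g.
#' the top 100/300/1000 genes by fold change regardless of significance).
#' Boundary ties are broken by gene id in lexicographic (C locale) order,
#' keeping the smaller id, so output is deterministic.
#'
#' @param m numeric genes x samples matrix with unique rownames.
#' @param n number of genes per set; must not exceed the gene count.
#' @return a `gene_set_collection` (role AGS), one set per column.
#' @export
ags_top <- function(m, n) {
  .check_score_matrix(m)
  if (n < 1L || n > nrow(m)) stop("n must be between 1 and the number of genes")
  sets <- lapply(colnames(m), function(cn) {
    x <- .drop_na_scores(stats::setNames(m[, cn], rownames(m)), cn)
    if (n > length(x)) stop("column '", cn, "': fewer than n non-missing scores")
    ord <- order(-abs(x), names(x), method = "radix")
    names(x)[ord[seq_len(n)]]
  })
  names(sets) <- colnames(m)
  gene_set_collection(sets, role = "AGS")
}

#' Significance-driven altered gene sets
#'
#' Per sample column, genes whose absolute score strictly exceeds
#' `cutoff` (e.g. |log2 fold change| > 1, 2 or 4), optionally intersected
#' with genes whose adjusted p-value does not exceed `alpha` in a
#' companion matrix of identical shape. Columns left empty are dropped
#' with a warning (set sizes are data-driven by design).
#'
#' @inheritParams ags_top
#' @param cutoff strict absolute-score threshold.
#' @param alpha optional adjusted-p threshold (non-strict, `<=`).
#' @param p_matrix companion matrix of adjusted p-values; required when
#'   `alpha` is given, and must share row and column names with `m`.
#' @return a `gene_set_collection` (role AGS).
#' @export
ags_significant <- function(m, cutoff, alpha = NULL, p_matrix = NULL) {
  .check_score_matrix(m)
  if (cutoff < 0) stop("cutoff must be non-negative")
  if (!is.null(alpha)) {
    if (is.null(p_matrix)) stop("alpha given but no companion p-value matrix")
    if (!identical(dimnames(p_matrix), dimnames(m)))
      stop("p-value matrix must share row and column names with the score matrix")
  }
  sets <- lapply(colnames(m), function(cn) {
    x <- .drop_na_scores(stats::setNames(m[, cn], rownames(m)), cn)
    keep <- names(x)[abs(x) > cutoff]
    if (!is.null(alpha)) {
      pv <- stats::setNames(p_matrix[, cn], rownames(p_matrix))[keep]
      keep <- keep[!is.na(pv) & pv <= alpha]
    }
    sort(keep, method = "radix")
  })
  names(sets) <- colnames(m)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sprintf("dropped %d column(s) with no gene passing the cutoff: %s",
                    sum(empty), paste(colnames(m)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no column yields a non-empty altered gene set")
  gene_set_collection(sets, role = "AGS")
}

#' Random altered gene sets of fixed size
#'
#' Per sample column, n genes sampled uniformly without replacement from
#' the matrix rows; the null counterpart of [ags_top()] for calibration
#' experiments. Seeded and reproducible.
#'
#' @inheritParams ags_top
#' @param seed integer RNG seed.
#' @return a `gene_set_collection` (role AGS).
#' @export
ags_toprandom <- function(m, n, seed = 1L) {
  .check_score_matrix(m)
  if (n < 1L || n > nrow(m)) stop("n must be between 1 and the number of genes")
  set.seed(seed)
  sets <- lapply(colnames(m), function(cn) sample(rownames(m), n))
  names(sets) <- colnames(m)
  gene_set_collection(sets, role = "AGS")
}

#' Altered gene sets from per-sample mutation lists
#'
#' Turns a two-column table (sample id, mutated gene) into one AGS per
#' sample holding its distinct mutated genes. Accepts a data.frame or a
#' 2-column TSV path; a header row is auto-detected when the first field
#' is "sample" (case-insensitive).
#'
#' @param x data.frame with columns (sample, gene) or a TSV file path.
#' @return a `gene_set_collection` (role AGS), one set per sample in
#'   first-appearance order.
#' @export
mutations2ags <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (!length(lines)) stop("mutation table '", x, "' is empty")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L))
      stop("mutation table '", x, "' must have 2 tab-separated columns (sample, gene)")
    x <- data.frame(sample = vapply(fields, `[[`, "", 1L),
                    gene = vapply(fields, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || ncol(x) < 2L) stop("expected a 2-column (sample, gene) table")
  if (nrow(x) && tolower(trimws(x[[1]][1])) == "sample") x <- x[-1, , drop = FALSE]
  if (!nrow(x)) stop("mutation table is empty")
  sets <- lapply(split(as.character(x[[2]]),
                       factor(x[[1]], levels = unique(x[[1]]))), unique)
  gene_set_collection(sets, role = "AGS")
}
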