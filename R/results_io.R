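.STAT_COLS <- c("n_edges", "expected_edges", "chi2", "z", "p", "q")

# '#'-prefixed self-describing header written atop output TSVs
.meta_header <- function(meta) {
  meta <- meta %||% list()
  c(sprintf("# netenrich %s", as.character(utils::packageVersion("netenrich"))),
    vapply(names(meta), function(k) sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), ""))
}

#' Write an enrichment result matrix to TSV
#'
#' Long layout writes exactly the columns `ags_id, fgs_id, n_edges,
#' expected_edges, chi2, z, p, q`; a wide layout `"wide:<statistic>"`
#' writes the AGS x FGS grid of one statistic. A `#`-prefixed metadata
#' header (tool version, network, parameters, timestamp) precedes the
#' table.
#'
#' @param rm an `nea_result` from [nea_render()].
#' @param path output file.
#' @param layout `"long"` or `"wide:<statistic>"`, e.g. `"wide:z"`.
#' @export
write_results <- function(rm, path, layout = "long") {
  meta <- attr(rm, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  if (identical(layout, "long")) {
    tab <- as.data.frame(rm)[, c("ags_id", "fgs_id", .STAT_COLS)]
  } else if (startsWith(layout, "wide:")) {
    stat <- sub("^wide:", "", layout)
    if (!stat %in% .STAT_COLS)
      stop("unknown statistic '", stat, "'; choose one of ",
           paste(.STAT_COLS, collapse = ", "))
    ags <- unique(rm$ags_id); fgs <- unique(rm$fgs_id)
    grid <- matrix(rm[[stat]][order(match(rm$ags_id, ags), match(rm$fgs_id, fgs))],
                   nrow = length(ags), byrow = TRUE, dimnames = list(ags, fgs))
    tab <- data.frame(ags_id = rownames(grid), grid, check.names = FALSE)
  } else {
    stop("unknown layout '", layout, "'")
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a long-format enrichment result TSV
#'
#' Inverse of [write_results()] for the long layout; `#` header lines are
#' skipped.
#'
#' @param path file written by [write_results()].
#' @return a data.frame with the eight long-layout columns.
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
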