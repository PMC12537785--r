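#' Read and write the pipeline's plain-text formats
#'
#' Expression matrices travel as TSV (rows = genes, columns = sample ids,
#' header row); metadata and titers as CSV; ortholog maps as two-column
#' TSV with a header; gene panels as one symbol per line; gene sets as
#' GMT (set name, description, then symbols, tab-separated).
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param expr genes x samples numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param meta sample metadata data.frame.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param group_levels number of adjuvant groups (fixes factor levels).
#' @export
read_metadata_csv <- function(path, group_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lev <- if (is.null(group_levels)) sort(unique(df$group)) else
    seq_len(group_levels)
  df$group <- factor(df$group, levels = lev)
  df$timepoint <- factor(df$timepoint,
                         levels = intersect(c("pre", "day1", "day7"),
                                            unique(df$timepoint)))
  df
}

#' @rdname io
#' @param titers titer table data.frame.
#' @export
write_titer_csv <- function(titers, path) {
  utils::write.csv(titers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_titer_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("source_id", "human_symbol")
  df
}

#' @rdname io
#' @param map ortholog map data.frame.
#' @export
write_ortholog_tsv <- function(map, path) {
  utils::write.table(map[, c("source_id", "human_symbol")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_panel <- function(path) {
  readLines(path)
}

#' @rdname io
#' @param panel character vector of gene symbols.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a simulated study to disk
#'
#' Emits the generator's outputs in the pipeline's input formats:
#' expression TSV, metadata CSV, titer CSV, ortholog-map TSV, panel text
#' file, and a ground-truth JSON (planted genes per group, common genes,
#' drivers, coefficients).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(study$expr, file.path(dir, "expression.tsv"))
  write_metadata_csv(study$meta, file.path(dir, "metadata.csv"))
  write_titer_csv(study$titers, file.path(dir, "titers.csv"))
  write_ortholog_tsv(study$truth$ortholog_map, file.path(dir, "orthologs.tsv"))
  write_panel(study$truth$panel, file.path(dir, "panel.txt"))
  jsonlite::write_json(
    list(planted = study$truth$planted,
         common = study$truth$common,
         drivers = study$titer_model$driver_genes,
         coefficients = study$titer_model$coefficients,
         dose_boost = study$titer_model$dose_boost),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  invisible(dir)
}
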