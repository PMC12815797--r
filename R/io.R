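#' Write an omics layer as TSV
#'
#' Samples in rows, header of feature ids, first column `sample_id`.
#'
#' @param layer an [omics_layer()].
#' @param path output file.
#' @export
write_layer_tsv <- function(layer, path) {
  df <- data.frame(sample_id = rownames(layer$values),
                   layer$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics layer from TSV/CSV
#'
#' @param path input matrix file; first column holds ids.
#' @param name layer label.
#' @param value_domain value domain to record (see [omics_layer()]).
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"`, in which case the matrix is transposed after
#'   reading.
#' @param sep field separator (default tab).
#' @return an [omics_layer()].
#' @export
read_layer_tsv <- function(path, name,
                           value_domain = "continuous",
                           orientation = c("samples_in_rows",
                                           "features_in_rows"),
                           sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (orientation == "features_in_rows") m <- t(m)
  omics_layer(name, m, value_domain)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then genes.
#'
#' @param path GMT file.
#' @return a named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(ln, 1, 60))
    gene_set(parts[1], parts[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets a [gene_set()] or list of them.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(genesets, path, description = "na") {
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  lines <- vapply(genesets, function(gs)
    paste(c(gs$name, description, gs$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tumor-growth study from long-format CSV
#'
#' Columns `animal`, `arm`, `day` and either `volume_mm3` or
#' `length_mm` + `width_mm`.
#'
#' @param path CSV file.
#' @return a [growth_study()].
#' @export
read_growth_csv <- function(path) {
  growth_study(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a tumor-growth study as long-format CSV
#'
#' @param study a [growth_study()].
#' @param path output file.
#' @export
write_growth_csv <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
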