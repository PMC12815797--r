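#' Construct a single omics layer
#'
#' An `omics_layer` holds one samples-by-features matrix together with its
#' value domain and a normalization flag. Row names are sample ids, column
#' names are feature ids; both must be unique. Missing entries are `NA`.
#'
#' @param name layer label, e.g. `"mRNA"`.
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique `rownames` (sample ids) and `colnames` (feature ids).
#' @param value_domain one of `"continuous"`, `"unit_interval"`,
#'   `"nonneg_continuous"`; describes the admissible value range.
#' @param normalized logical flag, `TRUE` after min-max scaling.
#' @return an object of class `omics_layer`.
#' @export
omics_layer <- function(name, values,
                        value_domain = c("continuous", "unit_interval",
                                         "nonneg_continuous"),
                        normalized = FALSE) {
  value_domain <- match.arg(value_domain)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("layer matrix needs rownames (samples) and colnames (features)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in layer '", name, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in layer '", name, "'")
  structure(
    list(name = name, values = values, value_domain = value_domain,
         normalized = isTRUE(normalized)),
    class = "omics_layer"
  )
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s'> %d samples x %d features (%s%s), %d missing\n",
              x$name, nrow(x$values), ncol(x$values), x$value_domain,
              if (x$normalized) ", normalized" else "",
              sum(is.na(x$values))))
  invisible(x)
}

sample_ids <- function(layer) rownames(layer$values)
feature_ids <- function(layer) colnames(layer$values)

#' Construct a multi-omics dataset
#'
#' Bundles several [omics_layer()] objects that share an identical, identically
#' ordered sample index, plus an append-only provenance log of the processing
#' steps applied so far.
#'
#' @param layers list of `omics_layer` objects with identical `rownames`.
#' @param provenance character vector of applied processing steps.
#' @return an object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(layers, provenance = character()) {
  stopifnot(length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == ""))
    names(layers) <- vapply(layers, `[[`, "", "name")
  ids <- sample_ids(layers[[1]])
  for (l in layers) {
    if (!identical(sample_ids(l), ids))
      stop("layers do not share an identical sample index; run intersect_samples() first")
  }
  structure(list(layers = layers, provenance = provenance),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d layers, %d common samples\n",
              length(x$layers), nrow(x$layers[[1]]$values)))
  for (l in x$layers)
    cat(sprintf("  %-12s %5d features (%s)\n", l$name, ncol(l$values),
                l$value_domain))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

log_step <- function(dataset, step) {
  dataset$provenance <- c(dataset$provenance, step)
  dataset
}

#' Construct a gene set
#'
#' @param name set label.
#' @param genes character vector of gene symbols; coerced to upper case,
#'   duplicates removed.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' The nine-gene Treg identity signature
#'
#' Core Treg identity markers (FOXP3, IL2RA, CCR8), immunosuppressive
#' cytokines (TGFB1, IL10) and Treg-recruiting chemokines (CCL1, CCL17,
#' CCL22, CXCL12).
#'
#' @return a [gene_set()] named `"TREG_SIGNATURE"`.
#' @export
treg_signature <- function() {
  gene_set("TREG_SIGNATURE",
           c("FOXP3", "CCR8", "IL2RA", "TGFB1", "IL10",
             "CCL1", "CCL22", "CCL17", "CXCL12"))
}

#' The T-cell exhaustion marker panel
#'
#' @return a [gene_set()] named `"EXHAUSTION_PANEL"` with PDCD1, CTLA4, LAG3,
#'   TIGIT, TOX and ENTPD1.
#' @export
exhaustion_markers <- function() {
  gene_set("EXHAUSTION_PANEL",
           c("PDCD1", "CTLA4", "LAG3", "TIGIT", "TOX", "ENTPD1"))
}
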