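#' Preprocessing configuration
#'
#' Defaults follow common multi-omics practice for a four-layer
#' mRNA/miRNA/methylation/protein design: drop features missing in more than
#' 20% of samples, impute the rest with sample-space KNN (k = 5), min-max
#' scale mRNA and miRNA (methylation stays on native beta values, protein is
#' assumed pre-normalized), and keep the most variable 2000/482/2000/217
#' features per layer.
#'
#' @param max_missing_frac maximum tolerated per-feature missing fraction.
#' @param knn_k neighbour count for [knn_impute()].
#' @param retain named integer vector, features to keep per layer.
#' @param normalize named character vector per layer, `"minmax"` or `"none"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(max_missing_frac = 0.2,
                              knn_k = 5,
                              retain = c(mRNA = 2000, miRNA = 482,
                                         methylation = 2000, protein = 217),
                              normalize = c(mRNA = "minmax", miRNA = "minmax",
                                            methylation = "none",
                                            protein = "none")) {
  stopifnot(knn_k >= 1, all(retain >= 1),
            max_missing_frac >= 0, max_missing_frac <= 1,
            all(normalize %in% c("minmax", "none")))
  structure(list(max_missing_frac = max_missing_frac, knn_k = knn_k,
                 retain = retain, normalize = normalize),
            class = "preprocess_config")
}

#' Restrict layers to their common samples
#'
#' Subsets and reorders every layer to the lexicographically sorted
#' intersection of sample ids, the canonical order used by all later stages.
#'
#' @param layers list of [omics_layer()] objects.
#' @return a [multiomics_dataset()] on the common samples.
#' @export
intersect_samples <- function(layers) {
  stopifnot(length(layers) >= 1)
  common <- sample_ids(layers[[1]])
  for (i in seq_along(layers)[-1]) {
    nxt <- intersect(common, sample_ids(layers[[i]]))
    if (length(nxt) == 0)
      stop(sprintf("no common samples between layer '%s' and layer '%s'",
                   layers[[1]]$name, layers[[i]]$name))
    common <- nxt
  }
  common <- sort(common)
  layers <- lapply(layers, function(l) {
    l$values <- l$values[common, , drop = FALSE]
    l
  })
  multiomics_dataset(layers,
                     provenance = sprintf("intersect_samples(n=%d)",
                                          length(common)))
}

#' Drop features with excessive missingness
#'
#' Keeps features whose missing fraction is at most `max_missing_frac`
#' (inclusive); feature order is preserved.
#'
#' @param layer an [omics_layer()].
#' @param max_missing_frac threshold in [0, 1].
#' @return the filtered layer.
#' @export
filter_features_by_missing <- function(layer, max_missing_frac = 0.2) {
  stopifnot(inherits(layer, "omics_layer"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- colMeans(is.na(layer$values))
  keep <- frac <= max_missing_frac
  if (!any(keep))
    stop("all features of layer '", layer$name,
         "' exceed the missingness threshold; raise max_missing_frac")
  layer$values <- layer$values[, keep, drop = FALSE]
  layer
}

#' KNN imputation over sample neighbours
#'
#' Each missing entry (sample s, feature f) is replaced by the mean of f over
#' the k nearest samples, using Euclidean distance on pairwise-complete
#' features (scaled by `sqrt(p / m)` for m shared features, the [stats::dist()]
#' convention) and skipping candidate neighbours that are themselves missing
#' f. Observed entries are never modified. With fewer than k usable
#' neighbours, all usable neighbours are averaged.
#'
#' @param layer an [omics_layer()].
#' @param k neighbour count (default 5).
#' @return the layer with no missing entries.
#' @export
knn_impute <- function(layer, k = 5) {
  stopifnot(inherits(layer, "omics_layer"), k >= 1)
  x <- layer$values
  if (!anyNA(x)) return(layer)
  obs_per_sample <- rowSums(!is.na(x))
  if (any(obs_per_sample == 0))
    stop("sample(s) with zero observed features: ",
         paste(rownames(x)[obs_per_sample == 0], collapse = ", "))
  obs_per_feature <- colSums(!is.na(x))
  if (any(obs_per_feature == 0))
    stop("feature(s) with zero observed values: ",
         paste(colnames(x)[obs_per_feature == 0], collapse = ", "))
  d <- as.matrix(stats::dist(x))    # pairwise-complete Euclidean, p/m scaled
  diag(d) <- Inf
  out <- x
  miss_idx <- which(is.na(x), arr.ind = TRUE)
  for (r in seq_len(nrow(miss_idx))) {
    s <- miss_idx[r, 1]; f <- miss_idx[r, 2]
    cand <- which(!is.na(x[, f]) & is.finite(d[s, ]))
    if (length(cand) == 0)
      stop("no usable neighbour for sample ", rownames(x)[s],
           ", feature ", colnames(x)[f])
    ord <- cand[order(d[s, cand], cand)]
    nn <- ord[seq_len(min(k, length(ord)))]
    out[s, f] <- mean(x[nn, f])
  }
  layer$values <- out
  layer
}

#' Per-feature min-max scaling to \[0, 1\]
#'
#' `x' = (x - min) / (max - min)` per feature; constant features map to 0.
#' Requires a complete matrix (impute first).
#'
#' @param layer an [omics_layer()].
#' @return the scaled layer with its `normalized` flag set.
#' @export
minmax_normalize <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  if (anyNA(x)) stop("layer '", layer$name,
                     "' has missing entries; impute before normalizing")
  mins <- apply(x, 2, min)
  rng <- apply(x, 2, max) - mins
  const <- rng == 0
  rng[const] <- 1
  x <- sweep(sweep(x, 2, mins), 2, rng, "/")
  x[, const] <- 0
  layer$values <- x
  layer$normalized <- TRUE
  layer
}

#' Keep the n most variable features
#'
#' Features are ranked by sample variance; ties are broken by original
#' feature order, and the survivors keep their original relative order.
#'
#' @param layer a complete [omics_layer()].
#' @param n number of features to retain.
#' @return the reduced layer.
#' @export
select_top_variance <- function(layer, n) {
  stopifnot(inherits(layer, "omics_layer"))
  x <- layer$values
  if (anyNA(x)) stop("impute before feature selection")
  if (n > ncol(x))
    stop("n (", n, ") exceeds the feature count (", ncol(x), ") of layer '",
         layer$name, "'")
  v <- apply(x, 2, stats::var)
  keep <- sort(order(-v, seq_along(v))[seq_len(n)])
  layer$values <- x[, keep, drop = FALSE]
  layer
}

#' Concatenate layers into one joint matrix
#'
#' Column-binds the layers in order; feature ids are prefixed with the layer
#' name (`layer.feature`) so provenance survives concatenation.
#'
#' @param dataset a [multiomics_dataset()] with complete layers.
#' @return a numeric samples-by-features matrix.
#' @export
concatenate_layers <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  ids <- sample_ids(dataset$layers[[1]])
  blocks <- lapply(dataset$layers, function(l) {
    if (anyNA(l$values)) stop("layer '", l$name, "' still has missing entries")
    if (!identical(sample_ids(l), ids)) stop("mismatched sample order")
    b <- l$values
    colnames(b) <- paste(l$name, colnames(b), sep = ".")
    b
  })
  do.call(cbind, blocks)
}

#' Run the full preprocessing chain
#'
#' filter (missingness) -> KNN impute -> min-max normalize (per-layer policy)
#' -> top-variance selection -> concatenation, after intersecting samples.
#' Retention counts are capped at the available feature count with a warning.
#'
#' @param layers list of [omics_layer()] objects (or a
#'   [multiomics_dataset()]).
#' @param config a [preprocess_config()].
#' @return a list with `dataset` (the processed [multiomics_dataset()]) and
#'   `joint` (the concatenated matrix).
#' @export
preprocess <- function(layers, config = preprocess_config()) {
  dataset <- if (inherits(layers, "multiomics_dataset")) layers
             else intersect_samples(layers)
  dataset$layers <- lapply(dataset$layers, function(l) {
    l <- filter_features_by_missing(l, config$max_missing_frac)
    l <- knn_impute(l, config$knn_k)
    pol <- config$normalize[l$name]
    if (!is.na(pol) && pol == "minmax") l <- minmax_normalize(l)
    n_keep <- config$retain[l$name]
    if (!is.na(n_keep)) {
      if (n_keep > ncol(l$values)) {
        warning("layer '", l$name, "': only ", ncol(l$values),
                " features available; keeping all")
        n_keep <- ncol(l$values)
      }
      l <- select_top_variance(l, n_keep)
    }
    l
  })
  dataset <- log_step(dataset, "preprocess")
  list(dataset = dataset, joint = concatenate_layers(dataset))
}
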