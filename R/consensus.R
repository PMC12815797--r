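#' Consensus clustering configuration
#'
#' Defaults follow the reference procedure: candidate K from 3 to 10, 1000
#' replicates of K-means on 80% subsamples, and the customary PAC window
#' (0.1, 0.9].
#'
#' @param k_range candidate cluster numbers, all >= 2.
#' @param n_reps number of subsampling replicates.
#' @param subsample_frac fraction of samples drawn (without replacement) per
#'   replicate.
#' @param pac_lower,pac_upper consensus-value window defining "ambiguous"
#'   pairs; the interval convention is open-left/closed-right.
#' @param seed RNG seed.
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(k_range = 3:10, n_reps = 1000,
                             subsample_frac = 0.8,
                             pac_lower = 0.1, pac_upper = 0.9,
                             seed = 1) {
  stopifnot(all(k_range >= 2), n_reps >= 1,
            subsample_frac > 0, subsample_frac <= 1,
            pac_lower >= 0, pac_lower < pac_upper, pac_upper <= 1)
  structure(list(k_range = as.integer(k_range), n_reps = as.integer(n_reps),
                 subsample_frac = subsample_frac, pac_lower = pac_lower,
                 pac_upper = pac_upper, seed = seed),
            class = "consensus_config")
}

# K-means++ seeding followed by Lloyd refinement via stats::kmeans
kmeans_pp <- function(x, k, iter_max = 300) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = prob)
      nd2 <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  init <- x[centers, , drop = FALSE]
  # duplicate seeds can arise in degenerate data; jitter to keep kmeans happy
  if (anyDuplicated(init))
    init <- init + stats::rnorm(length(init), sd = 1e-8)
  stats::kmeans(x, centers = init, iter.max = iter_max)$cluster
}

#' Subsampled consensus matrix for one K
#'
#' Runs `n_reps` replicates; each draws `floor(subsample_frac * n)` samples
#' without replacement and partitions them with K-means (K-means++
#' initialization, one start per replicate -- replicate diversity comes from
#' the subsampling). The consensus value for a pair is the fraction of
#' replicates in which it was co-clustered among those in which it was
#' co-sampled; never co-sampled pairs get 0 with a coverage warning, and the
#' diagonal is forced to 1.
#'
#' @param latent complete numeric matrix, samples in rows.
#' @param K number of clusters for this scan point.
#' @param config a [consensus_config()].
#' @param store_assignments keep the per-replicate subsample indices and
#'   labels (for auditing).
#' @return a `consensus_result` with the consensus `matrix`, the integer
#'   `copair_counts`/`cosample_counts`, and `pac` computed with the config
#'   window. Labels are added by [assign_clusters()].
#' @export
consensus_matrix <- function(latent, K, config = consensus_config(),
                             store_assignments = FALSE) {
  stopifnot(is.matrix(latent), K >= 2)
  n <- nrow(latent)
  m <- floor(config$subsample_frac * n)
  if (K >= m) stop("K must be smaller than the subsample size (", m, ")")
  copair <- matrix(0L, n, n)
  cosample <- matrix(0L, n, n)
  assignments <- if (store_assignments) vector("list", config$n_reps) else NULL
  withr::with_seed(stage_seed(config$seed, K), {
    for (r in seq_len(config$n_reps)) {
      idx <- sort(sample.int(n, m))
      lab <- kmeans_pp(latent[idx, , drop = FALSE], K)
      co <- outer(lab, lab, "==")
      cosample[idx, idx] <- cosample[idx, idx] + 1L
      copair[idx, idx] <- copair[idx, idx] + co
      if (store_assignments) assignments[[r]] <- list(idx = idx, labels = lab)
    }
  })
  cons <- copair / pmax(cosample, 1L)
  uncovered <- sum(cosample[upper.tri(cosample)] == 0)
  n_pairs <- n * (n - 1) / 2
  if (uncovered > 0)
    warning(sprintf(paste0("%d of %d sample pairs were never co-sampled ",
                           "(consensus set to 0); increase n_reps"),
                    uncovered, n_pairs))
  diag(cons) <- 1
  dimnames(cons) <- list(rownames(latent), rownames(latent))
  res <- structure(
    list(K = as.integer(K), matrix = cons, copair_counts = copair,
         cosample_counts = cosample, labels = NULL, pac = NA_real_,
         assignments = assignments,
         pac_lower = config$pac_lower, pac_upper = config$pac_upper),
    class = "consensus_result")
  res$pac <- pac(res, config$pac_lower, config$pac_upper)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> K=%d, n=%d, PAC=%.4f%s\n", x$K,
              nrow(x$matrix), x$pac,
              if (is.null(x$labels)) "" else ", labels assigned"))
  invisible(x)
}

#' Empirical CDF of off-diagonal consensus values
#'
#' @param result a `consensus_result`.
#' @return a [stats::ecdf()] over the upper-triangular consensus values.
#' @export
consensus_cdf <- function(result) {
  stats::ecdf(result$matrix[upper.tri(result$matrix)])
}

#' Proportion of ambiguously clustered pairs
#'
#' PAC = CDF(upper) - CDF(lower) over the upper-triangular off-diagonal
#' consensus values, i.e. the fraction of pairs whose consensus value falls
#' in the ambiguous window (lower, upper]. Lower PAC means more stable
#' clustering.
#'
#' @param result a `consensus_result`.
#' @param lower,upper window bounds (defaults 0.1 and 0.9).
#' @return a scalar in [0, 1].
#' @export
pac <- function(result, lower = 0.1, upper = 0.9) {
  x <- result$matrix[upper.tri(result$matrix)]
  mean(x > lower & x <= upper)
}

#' Select K by minimum PAC
#'
#' @param pac_by_k named numeric vector, names are candidate K values.
#' @return the K (integer) with the lowest PAC; ties go to the smallest K.
#' @export
select_k <- function(pac_by_k) {
  stopifnot(length(pac_by_k) >= 1, !is.null(names(pac_by_k)))
  ks <- as.integer(names(pac_by_k))
  ord <- order(pac_by_k, ks)
  ks[ord[1]]
}

#' Final labels from a consensus matrix
#'
#' Average-linkage agglomerative clustering on dissimilarity
#' `1 - consensus`, cut at K; clusters are renumbered by decreasing size
#' (cluster 1 is the largest; ties keep the lower dendrogram label first).
#'
#' @param result a `consensus_result`.
#' @param K number of clusters to cut (defaults to the result's K).
#' @return integer labels in `1..K`, named by sample id.
#' @export
assign_clusters <- function(result, K = result$K) {
  n <- nrow(result$matrix)
  if (K > n) stop("K exceeds the sample count")
  hc <- stats::hclust(stats::as.dist(1 - result$matrix), method = "average")
  raw <- stats::cutree(hc, k = K)
  sizes <- table(raw)
  remap <- integer(K)
  remap[as.integer(names(sizes))[order(-sizes, as.integer(names(sizes)))]] <-
    seq_len(K)
  labels <- remap[raw]
  names(labels) <- rownames(result$matrix)
  labels
}

#' Scan candidate K values and pick the most stable partition
#'
#' Runs [consensus_matrix()] for every K in the config's `k_range`, selects
#' the K with the lowest PAC, and assigns final labels at that K.
#'
#' @param latent complete numeric matrix, samples in rows.
#' @param config a [consensus_config()].
#' @return a list with `results` (per-K `consensus_result`s, names = K),
#'   `pac_by_k`, `best_k`, and `labels` at the selected K.
#' @export
consensus_cluster <- function(latent, config = consensus_config()) {
  results <- lapply(config$k_range, function(K)
    consensus_matrix(latent, K, config))
  names(results) <- config$k_range
  pac_by_k <- vapply(results, `[[`, numeric(1), "pac")
  best_k <- select_k(pac_by_k)
  best <- results[[as.character(best_k)]]
  labels <- assign_clusters(best, best_k)
  best$labels <- labels
  results[[as.character(best_k)]] <- best
  list(results = results, pac_by_k = pac_by_k, best_k = best_k,
       labels = labels)
}

#' Silhouette scores for a labelled embedding
#'
#' Standard silhouette with Euclidean distance; singleton clusters get
#' silhouette width 0 by convention.
#'
#' @param latent numeric matrix, samples in rows.
#' @param labels per-sample cluster labels (>= 2 distinct values).
#' @return a list with `overall` (mean width), `per_cluster` (named mean
#'   widths) and `widths` (per-sample).
#' @export
silhouette_score <- function(latent, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters")
  stopifnot(length(labels) == nrow(latent))
  sil <- cluster::silhouette(labels, stats::dist(latent))
  widths <- sil[, "sil_width"]
  per_cluster <- tapply(widths, labels, mean)
  list(overall = mean(widths),
       per_cluster = per_cluster,
       widths = widths)
}
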