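# Small in-code fixtures shared across test files.

# a tiny named matrix with sample/feature ids
toy_matrix <- function(n, p, seed = 1, prefix = "F") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("%s%03d", prefix, seq_len(p))))
    m
  })
}

toy_layer <- function(n = 6, p = 4, seed = 1, name = "toy",
                      value_domain = "continuous") {
  omics_layer(name, toy_matrix(n, p, seed), value_domain)
}

# small synthetic design used by pipeline-level tests: 4 layers, modest width
small_specs <- function() {
  default_layer_specs(n_mrna = 300, n_mirna = 100, n_meth = 200,
                      n_protein = 60)
}

small_retain <- function() {
  c(mRNA = 150, miRNA = 50, methylation = 100, protein = 30)
}

# map a recovered clustering onto the planted cluster id: the recovered
# cluster holding the plurality of the planted cluster's samples
recovered_cluster_for <- function(labels, truth_labels, planted) {
  tab <- table(labels[truth_labels == planted])
  names(tab)[which.max(tab)]
}

# brute-force KNN imputation: exhaustive neighbour search with the
# pairwise-complete (p/m scaled) Euclidean distance, written as plain loops
brute_knn_impute <- function(x, k) {
  p <- ncol(x)
  out <- x
  for (s in seq_len(nrow(x))) for (f in seq_len(p)) {
    if (!is.na(x[s, f])) next
    dists <- rep(Inf, nrow(x))
    for (t in seq_len(nrow(x))) {
      if (t == s || is.na(x[t, f])) next
      shared <- which(!is.na(x[s, ]) & !is.na(x[t, ]))
      if (length(shared) == 0) next
      dists[t] <- sqrt(p / length(shared) *
                         sum((x[s, shared] - x[t, shared])^2))
    }
    cand <- which(is.finite(dists))
    nn <- cand[order(dists[cand], cand)][seq_len(min(k, length(cand)))]
    out[s, f] <- mean(x[nn, f])
  }
  out
}

# independent GSEA running sum (direct transcription of the definition)
brute_gsea_es <- function(scores, hit_positions, weight) {
  N <- length(scores)
  hit <- seq_len(N) %in% hit_positions
  w <- abs(scores)^weight
  if (sum(w[hit]) == 0) w[hit] <- 1
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / sum(w[hit]) else -1 / (N - sum(hit))
    running[i] <- cur
  }
  running[which.max(abs(running))]
}
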