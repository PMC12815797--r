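# column z-scores with a degenerate-SD guard (constant gene -> z = 0)
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, mu)
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  z
}

#' Per-sample gene-set signature score
#'
#' Default `mean_z`: each gene is z-scored across samples (constant genes
#' score 0) and the signature score is the mean z over the set genes present
#' in the matrix. The `ssgsea_like` alternative computes, per sample, a
#' rank-weighted running-sum enrichment statistic of the set within that
#' sample's expression ranking. Genes absent from the matrix are logged in
#' the `"missing_genes"` attribute, not scored.
#'
#' @param expr complete numeric matrix, samples in rows, genes in columns.
#' @param geneset a [gene_set()].
#' @param method `"mean_z"` (default) or `"ssgsea_like"`.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, geneset,
                            method = c("mean_z", "ssgsea_like")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), inherits(geneset, "gene_set"))
  if (anyNA(expr)) stop("expression matrix has missing entries")
  ids <- toupper(colnames(expr))         # case-insensitive symbol matching
  present_idx <- which(ids %in% geneset$genes)
  if (length(present_idx) == 0)
    stop("no genes of set '", geneset$name, "' found in the expression matrix")
  missing <- setdiff(geneset$genes, ids)
  score <- if (method == "mean_z") {
    rowMeans(zscore_cols(expr)[, present_idx, drop = FALSE])
  } else {
    N <- ncol(expr)
    hit <- seq_len(N) %in% present_idx
    apply(expr, 1, function(x) {
      ord <- order(x, decreasing = TRUE)
      h <- hit[ord]
      w <- (N - seq_len(N) + 1)^0.25       # rank weight, top-heavy
      p_hit <- cumsum(w * h) / sum(w * h)
      p_miss <- cumsum(!h) / (N - sum(h))
      sum(p_hit - p_miss) / N
    })
  }
  names(score) <- rownames(expr)
  attr(score, "missing_genes") <- missing
  attr(score, "method") <- method
  score
}

#' Rank genes for one cluster versus the rest
#'
#' One-vs-rest per-gene statistic, sorted decreasing. `signal_to_noise` is
#' `(mu1 - mu0) / (sd1 + sd0)` with each SD floored at `0.2 * |mu|` of its
#' group and at 1e-8 absolute (the classic GSEA convention); `log2fc` is the
#' difference of group means (log-scale data assumed). Ties are broken by
#' lexicographic gene id, making the ranking deterministic.
#'
#' @param expr complete numeric matrix, samples in rows, genes in columns.
#' @param labels per-sample cluster labels aligned with `expr` rows.
#' @param cluster the label defining group 1.
#' @param metric `"signal_to_noise"` (default) or `"log2fc"`.
#' @return named numeric vector sorted decreasing, with a `"metric"`
#'   attribute.
#' @export
rank_genes <- function(expr, labels, cluster,
                       metric = c("signal_to_noise", "log2fc")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(expr), length(labels) == nrow(expr))
  in1 <- labels == cluster
  if (!any(in1)) stop("cluster '", cluster, "' not present in labels")
  if (sum(in1) < 2 || sum(!in1) < 2)
    stop("both groups need at least 2 samples")
  x1 <- expr[in1, , drop = FALSE]
  x0 <- expr[!in1, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  stat <- if (metric == "signal_to_noise") {
    s1 <- pmax(apply(x1, 2, stats::sd), 0.2 * abs(mu1), 1e-8)
    s0 <- pmax(apply(x0, 2, stats::sd), 0.2 * abs(mu0), 1e-8)
    (mu1 - mu0) / (s1 + s0)
  } else {
    mu1 - mu0
  }
  ord <- order(-stat, colnames(expr))
  out <- stat[ord]
  attr(out, "metric") <- metric
  out
}

# weighted KS running-sum enrichment score for hit positions `hit_idx`
# within a ranked score vector; returns ES and the peak position
gsea_es <- function(scores, hit_idx, weight) {
  N <- length(scores)
  Nh <- length(hit_idx)
  if (Nh >= N) stop("gene set covers the entire ranked list")
  inc <- numeric(N)
  w <- abs(scores[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, Nh)      # all-zero scores: equal increments
  inc[hit_idx] <- w / sum(w)
  inc[-hit_idx] <- -1 / (N - Nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak)
}

#' Gene set enrichment analysis on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: hits increment proportionally to
#' `|score|^weight` (normalized to sum 1), misses decrement `1/(N - Nh)`;
#' ES is the extremum of the running sum. The null distribution permutes set
#' membership (random gene labels), NES is ES divided by the mean |null ES|
#' of matching sign, and the permutation p-value is the matching-sign tail
#' `(1 + #{|null| >= |ES|, same sign}) / (1 + #{same sign})`. FDR is
#' Benjamini-Hochberg across the sets supplied in one call.
#'
#' @param ranked named numeric vector sorted decreasing (see
#'   [rank_genes()]).
#' @param genesets a [gene_set()] or list of them.
#' @param n_perm membership permutations; 0 gives ES only (NES/p `NA`),
#'   otherwise at least 100.
#' @param weight running-sum exponent (1 = classic weighted GSEA,
#'   0 = unweighted KS).
#' @param seed RNG seed for the permutations.
#' @return a data.frame with one row per set: `set`, `size`, `ES`, `NES`,
#'   `p`, `fdr_q`, `n_perm`, `leading_edge` (comma-separated genes).
#' @export
gsea <- function(ranked, genesets, n_perm = 1000, weight = 1, seed = 1) {
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  stopifnot(length(genesets) >= 1, !is.null(names(ranked)))
  if (n_perm != 0 && n_perm < 100)
    stop("n_perm must be 0 (ES only) or >= 100")
  N <- length(ranked)
  ranked_ids <- toupper(names(ranked))   # symbols are matched case-insensitively
  rows <- withr::with_seed(seed, lapply(genesets, function(gs) {
    hit_idx <- which(ranked_ids %in% gs$genes)
    if (length(hit_idx) == 0)
      stop("no genes of set '", gs$name, "' found in the ranked list")
    obs <- gsea_es(ranked, hit_idx, weight)
    hits_sorted <- hit_idx
    leading <- if (obs$es >= 0) {
      names(ranked)[hits_sorted[hits_sorted <= obs$peak]]
    } else {
      names(ranked)[hits_sorted[hits_sorted >= obs$peak]]
    }
    nes <- p <- NA_real_
    if (n_perm > 0) {
      null_es <- vapply(seq_len(n_perm), function(i) {
        gsea_es(ranked, sample.int(N, length(hit_idx)), weight)$es
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(obs$es)]
      if (length(same) > 0) {
        nes <- obs$es / mean(abs(same))
        p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      } else {
        nes <- Inf * sign(obs$es)
        p <- 1 / (1 + n_perm)
      }
    }
    data.frame(set = gs$name, size = length(hit_idx), ES = obs$es,
               NES = nes, p = p, n_perm = n_perm,
               leading_edge = paste(leading, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_q <- if (n_perm > 0) stats::p.adjust(out$p, "BH") else NA_real_
  out[, c("set", "size", "ES", "NES", "p", "fdr_q", "n_perm",
          "leading_edge")]
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric p-value for an overlap at least as large as
#' observed between a hit list and each gene set, restricted to the
#' universe; Benjamini-Hochberg adjustment across the sets supplied in one
#' call.
#'
#' @param hits character vector of hit genes, must be a subset of
#'   `universe`.
#' @param universe character vector of background genes.
#' @param genesets a [gene_set()] or list of them.
#' @return a data.frame with `set`, `set_size` (in-universe), `overlap`,
#'   `p`, `q`.
#' @export
ora <- function(hits, universe, genesets) {
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  hits <- unique(toupper(hits)); universe <- unique(toupper(universe))
  if (!all(hits %in% universe))
    stop("hits contain genes outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  N <- length(universe); n <- length(hits)
  rows <- lapply(genesets, function(gs) {
    set_in <- intersect(gs$genes, universe)
    if (length(set_in) == 0)
      stop("gene set '", gs$name, "' has no overlap with the universe")
    K <- length(set_in)
    k <- length(intersect(hits, set_in))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = gs$name, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Nonparametric group comparison with post-hoc tests
#'
#' Tie-corrected Kruskal-Wallis across all groups, Dunn's pairwise z-tests
#' on mean ranks (Bonferroni-adjusted by default, the classical Dunn
#' procedure), and pairwise Wilcoxon rank-sum tests (BH-adjusted;
#' [stats::wilcox.test()] semantics, exact for small tie-free samples). If
#' every value is identical, H is defined as 0 with p = 1.
#'
#' @param values numeric vector.
#' @param labels group labels aligned with `values`, >= 2 groups of >= 2.
#' @param dunn_adjust p-adjustment for the Dunn table (default
#'   `"bonferroni"`).
#' @return a `group_test_result` list: `kruskal` (statistic, p), `dunn` and
#'   `wilcoxon` pairwise data.frames.
#' @export
group_tests <- function(values, labels, dunn_adjust = "bonferroni") {
  stopifnot(length(values) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 samples")
  groups <- levels(labels)
  pairs <- utils::combn(groups, 2)

  if (length(unique(values)) == 1) {
    kw <- list(statistic = 0, p = 1)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     stringsAsFactors = FALSE)
    dunn <- cbind(pw, z = 0, p = 1, p_adj = 1)
    wil <- cbind(pw, p = 1, p_adj = 1)
    return(structure(list(kruskal = kw, dunn = dunn, wilcoxon = wil),
                     class = "group_test_result"))
  }

  kt <- stats::kruskal.test(values, labels)
  kw <- list(statistic = unname(kt$statistic), p = kt$p.value)

  # Dunn: z-tests on mean ranks with tie correction
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, labels, mean)
  n_i <- table(labels)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_corr
  dunn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(sigma2_base * (1 / n_i[[g1]] + 1 / n_i[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  dunn$p_adj <- stats::p.adjust(dunn$p, dunn_adjust)

  wil <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    wt <- suppressWarnings(stats::wilcox.test(values[labels == g1],
                                              values[labels == g2],
                                              correct = TRUE))
    data.frame(group1 = g1, group2 = g2, p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  wil$p_adj <- stats::p.adjust(wil$p, "BH")

  structure(list(kruskal = kw, dunn = dunn, wilcoxon = wil),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> Kruskal-Wallis H=%.3f, p=%.3g; %d pairs\n",
              x$kruskal$statistic, x$kruskal$p, nrow(x$dunn)))
  invisible(x)
}

#' Exhaustion-marker panel per cluster
#'
#' Computes a per-sample exhaustion score (mean z over the marker panel) and
#' reports, per cluster, the Spearman correlation between the Treg signature
#' score and the exhaustion score, plus per-marker cluster mean expression.
#' Constant vectors within a cluster yield correlation 0 with a
#' `degenerate` flag.
#'
#' @param expr complete numeric matrix, samples in rows, genes in columns.
#' @param treg_scores per-sample Treg signature scores aligned with `expr`.
#' @param labels per-sample cluster labels.
#' @param markers a [gene_set()] of exhaustion markers (default
#'   [exhaustion_markers()]).
#' @return a list with `correlations` (data.frame cluster, rho, degenerate)
#'   and `marker_means` (clusters x markers matrix).
#' @export
exhaustion_panel <- function(expr, treg_scores, labels,
                             markers = exhaustion_markers()) {
  stopifnot(nrow(expr) == length(treg_scores),
            nrow(expr) == length(labels))
  exh <- signature_score(expr, markers)
  clusters <- sort(unique(labels))
  cor_rows <- lapply(clusters, function(cl) {
    sel <- labels == cl
    a <- treg_scores[sel]; b <- exh[sel]
    degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
    rho <- if (degenerate) 0 else
      stats::cor(a, b, method = "spearman")
    data.frame(cluster = cl, rho = rho, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  present <- which(toupper(colnames(expr)) %in% markers$genes)
  means <- t(vapply(clusters, function(cl)
    colMeans(expr[labels == cl, present, drop = FALSE]),
    numeric(length(present))))
  rownames(means) <- clusters
  list(correlations = do.call(rbind, cor_rows), marker_means = means)
}
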