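test_that("signature scores reduce to gene z-scores and guard degeneracy", {
  x <- toy_matrix(20, 6, seed = 1, prefix = "G")
  one <- gene_set("ONE", colnames(x)[3])
  got <- signature_score(x, one)
  expect_equal(as.numeric(got), as.numeric(scale(x[, 3])[, 1]))

  flat <- matrix(5, 4, 3, dimnames = list(letters[1:4], c("A", "B", "C")))
  expect_equal(as.numeric(signature_score(flat, gene_set("S", c("A", "B")))),
               rep(0, 4))
})

test_that("signature scores ignore gene order and log absent genes", {
  x <- toy_matrix(15, 5, seed = 2, prefix = "G")
  s1 <- signature_score(x, gene_set("S", c("G001", "G003")))
  s2 <- signature_score(x, gene_set("S", c("G003", "G001")))
  expect_equal(as.numeric(s1), as.numeric(s2))
  s3 <- signature_score(x, gene_set("S", c("G001", "G003", "NOPE")))
  expect_equal(as.numeric(s3), as.numeric(s1))
  expect_identical(attr(s3, "missing_genes"), "NOPE")
  expect_error(signature_score(x, gene_set("S", "ABSENT")), "ABSENT|S")
})

test_that("a planted Treg spike separates the spiked cluster's scores", {
  cfg <- synthetic_omics_config(n_samples = 300, n_clusters = 3,
                                layer_specs = small_specs(),
                                treg_cluster = 2, treg_effect = 2, seed = 3)
  g <- generate_multiomics(cfg)
  expr <- g$dataset$layers$mRNA$values
  sc <- signature_score(expr, treg_signature())
  lab <- g$truth$labels
  means <- tapply(sc, lab, mean)
  expect_identical(unname(which.max(means)), 2L)
  p <- stats::wilcox.test(sc[lab == 2], sc[lab != 2])$p.value
  expect_lt(p, 0.001)
})

test_that("gene ranking matches the statistic definitions", {
  lab <- rep(c(1, 2), each = 5)
  x <- toy_matrix(10, 4, seed = 4, prefix = "G")
  x[, 1] <- 1                     # identical in both groups -> statistic 0
  ranked <- rank_genes(x, lab, 1)
  expect_equal(unname(ranked["G001"]), 0)

  # mu1 - mu0 = sd1 + sd0 exactly (unit-SD groups shifted by 2)
  # -> signal-to-noise 1; the SD floors do not bind here
  v <- as.numeric(scale(1:5))
  y <- cbind(GENE = c(v + 2, v),
             NOISE = withr::with_seed(1, rnorm(10)))
  rownames(y) <- sprintf("s%d", 1:10)
  got <- rank_genes(y, lab, 1)
  expect_equal(unname(got["GENE"]), 1, tolerance = 1e-10)
})

test_that("gene ranking equals an independent recomputation on a toy matrix", {
  lab <- rep(c("a", "b"), c(6, 8))
  x <- toy_matrix(14, 20, seed = 5, prefix = "G")
  ranked <- rank_genes(x, lab, "a")
  manual <- vapply(colnames(x), function(g) {
    m1 <- mean(x[lab == "a", g]); m0 <- mean(x[lab == "b", g])
    s1 <- max(sd(x[lab == "a", g]), 0.2 * abs(m1), 1e-8)
    s0 <- max(sd(x[lab == "b", g]), 0.2 * abs(m0), 1e-8)
    (m1 - m0) / (s1 + s0)
  }, numeric(1))
  manual <- manual[order(-manual, names(manual))]
  expect_equal(ranked, manual, ignore_attr = TRUE)
  expect_identical(names(ranked), names(manual))
  expect_error(rank_genes(x, lab, "zzz"), "not present")
  expect_error(rank_genes(x, c("a", rep("b", 13)), "a"), "2 samples")

  # log2fc metric is the difference of group means
  lfc <- rank_genes(x, lab, "a", metric = "log2fc")
  expect_equal(unname(lfc["G004"]),
               mean(x[lab == "a", "G004"]) - mean(x[lab == "b", "G004"]))
})

test_that("the GSEA running sum matches a hand computation (N=10, |S|=3)", {
  scores <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.25, 0.1)
  names(scores) <- sprintf("g%02d", 1:10)
  set <- gene_set("TOP3", names(scores)[1:3])
  got <- gsea(scores, set, n_perm = 0, weight = 1)
  # manual running sum: hits at 1,2,3 with weights 5,4,3 (sum 12),
  # misses decrement 1/7
  running <- cumsum(c(5 / 12, 4 / 12, 3 / 12, rep(-1 / 7, 7)))
  expect_equal(got$ES, running[which.max(abs(running))])
  expect_equal(got$ES, 1)  # the set occupies the top 3 ranks exactly
  expect_identical(got$leading_edge, paste(names(scores)[1:3], collapse = ","))

  # generic positions, checked against the independent transcription
  set2 <- gene_set("MIX", names(scores)[c(2, 5, 9)])
  got2 <- gsea(scores, set2, n_perm = 0, weight = 1)
  expect_equal(got2$ES, brute_gsea_es(scores, c(2, 5, 9), 1))
})

test_that("GSEA ES is bounded, sign-symmetric, and errors on a full-list set", {
  r <- make_ranked_expression(50, 8, "random", seed = 6)
  es <- gsea(r$ranked, r$geneset, n_perm = 0)$ES
  expect_true(abs(es) <= 1)
  neg <- sort(-r$ranked, decreasing = TRUE)
  es_neg <- gsea(neg, r$geneset, n_perm = 0)$ES
  expect_equal(sign(es_neg), -sign(es))
  all_set <- gene_set("ALL", names(r$ranked))
  expect_error(gsea(r$ranked, all_set, n_perm = 0), "entire")
})

test_that("permutation p converges to the exhaustive membership null (N=6, |S|=2, weight 0)", {
  scores <- c(3, 2, 1, -1, -2, -3)
  names(scores) <- sprintf("g%d", 1:6)
  obs_set <- c(1, 2)
  # exhaustive null over all C(6,2)=15 memberships
  all_es <- apply(utils::combn(6, 2), 2, function(pos)
    brute_gsea_es(scores, pos, 0))
  obs_es <- brute_gsea_es(scores, obs_set, 0)
  same <- all_es[sign(all_es) == sign(obs_es)]
  exact_p <- sum(abs(same) >= abs(obs_es)) / length(same)
  got <- gsea(scores, gene_set("S", c("g1", "g2")), n_perm = 20000,
              weight = 0, seed = 7)
  expect_lt(abs(got$p - exact_p), 0.02)
})

test_that("GSEA agrees with an independent implementation at weight 1", {
  skip_if_not_installed("fgsea")
  r <- make_ranked_expression(200, 15, "random", seed = 8)
  es_mine <- gsea(r$ranked, r$geneset, n_perm = 0, weight = 1)$ES
  es_ref <- fgsea::calcGseaStat(r$ranked,
                                which(names(r$ranked) %in% r$geneset$genes))
  expect_equal(es_mine, es_ref, tolerance = 1e-8)
})

test_that("ORA reproduces exact hypergeometric combinatorics", {
  u <- sprintf("g%02d", 1:10)
  s5 <- gene_set("S5", u[1:5])
  # overlap 5 of 5 hits in universe 10: p = 1/C(10,5)
  expect_equal(ora(u[1:5], u, s5)$p, 1 / choose(10, 5))
  # zero overlap -> upper tail includes >= 0 -> p = 1
  expect_equal(ora(u[6:10], u, s5)$p, 1)
  # hits = universe -> overlap forced to the whole set
  full <- ora(u, u, s5)
  expect_identical(full$overlap, 5L)
  expect_equal(full$p, 1)
  expect_error(ora(c(u[1], "zz"), u, s5), "outside")
})

test_that("ORA p equals exhaustive enumeration for small universes", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      N <- sample(8:12, 1)
      u <- sprintf("g%02d", seq_len(N))
      set <- sample(u, sample(2:4, 1))
      hits <- sample(u, sample(3:5, 1))
    })
    got <- ora(hits, u, gene_set("S", set))
    k_obs <- got$overlap
    combos <- utils::combn(N, length(hits))
    overlaps <- apply(combos, 2, function(idx)
      length(intersect(toupper(u[idx]), toupper(set))))
    expect_equal(got$p, mean(overlaps >= k_obs), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("BH adjustment is monotone and capped at 1", {
  p <- c(0.001, 0.04, 0.2, 0.8, 0.9)
  sets <- lapply(1:5, function(i) gene_set(paste0("S", i), sprintf("g%d", i)))
  # property is about p.adjust usage inside ora/gsea outputs
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q <= 1))
  got <- ora(sprintf("g%d", 1:2), sprintf("g%d", 1:8), sets)
  expect_true(all(got$q >= got$p - 1e-12))
  expect_true(all(got$q <= 1))
})

test_that("Kruskal-Wallis H matches the hand formula on a constructed case", {
  vals <- 1:12
  lab <- rep(c("a", "b", "c"), each = 4)
  got <- group_tests(vals, lab)
  r <- rank(vals); N <- 12
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, lab, function(x) length(x) * (mean(x) - mean(r))^2))
  expect_equal(got$kruskal$statistic, H)
  expect_equal(got$kruskal$p, stats::kruskal.test(vals, factor(lab))$p.value)
})

test_that("group tests flag only truly shifted pairs", {
  withr::with_seed(9, {
    base <- rnorm(20)
    vals <- c(base, rnorm(20), rnorm(20) + 10)
    lab <- rep(c("a", "b", "c"), each = 20)
  })
  got <- group_tests(vals, lab)
  shifted <- got$dunn$p_adj[got$dunn$group1 == "a" & got$dunn$group2 == "c" |
                            got$dunn$group1 == "b" & got$dunn$group2 == "c"]
  unshifted <- got$dunn$p_adj[got$dunn$group1 == "a" & got$dunn$group2 == "b"]
  expect_true(all(shifted < 0.001))
  expect_gt(unshifted, 0.05)
  wil_c <- got$wilcoxon$p[got$wilcoxon$group2 == "c" |
                          got$wilcoxon$group1 == "c"]
  expect_true(all(wil_c < 1e-6))
})

test_that("identical groups and identical values degrade gracefully", {
  same <- withr::with_seed(10, rnorm(15))
  got <- group_tests(c(same, same), rep(c("x", "y"), each = 15))
  expect_lt(got$kruskal$statistic, 1)
  const <- group_tests(rep(2, 12), rep(c("x", "y", "z"), each = 4))
  expect_equal(const$kruskal$statistic, 0)
  expect_equal(const$kruskal$p, 1)
  expect_error(group_tests(1:5, c(1, 1, 1, 1, 2)), "2 samples")
})

test_that("exhaustion panel correlations behave at the extremes", {
  x <- toy_matrix(60, 12, seed = 11, prefix = "G")
  colnames(x)[1:6] <- exhaustion_markers()$genes
  lab <- rep(1:2, each = 30)
  exh <- signature_score(x, exhaustion_markers())
  got <- exhaustion_panel(x, exh, lab)   # treg score == exhaustion score
  expect_equal(got$correlations$rho, c(1, 1))

  # independent scores (n = 200 per cluster) stay near zero in 19/20 seeds
  hits <- 0
  for (s in 1:20) {
    y <- toy_matrix(400, 8, seed = 100 + s, prefix = "G")
    colnames(y)[1:6] <- exhaustion_markers()$genes
    ind <- withr::with_seed(300 + s, rnorm(400))
    rho <- exhaustion_panel(y, ind, rep(1:2, each = 200))$correlations$rho
    if (all(abs(rho) < 0.2)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("markers spiked with the Treg genes give that cluster the top correlation", {
  cfg <- synthetic_omics_config(n_samples = 150, n_clusters = 3,
                                layer_specs = small_specs(),
                                treg_cluster = 2, treg_effect = 2, seed = 12)
  g <- generate_multiomics(cfg)
  expr <- g$dataset$layers$mRNA$values
  sc <- signature_score(expr, treg_signature())
  got <- exhaustion_panel(expr, sc, g$truth$labels)
  best <- got$correlations$cluster[which.max(got$correlations$rho)]
  expect_identical(as.integer(best), 2L)
})

test_that("GMT round-trips through read and write", {
  sets <- list(gene_set("A", c("X1", "X2", "X3")),
               gene_set("B", c("Y1", "Y2")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), c("A", "B"))
  expect_identical(back$A$genes, c("X1", "X2", "X3"))
  expect_error(read_gmt(withr::local_tempfile(lines = "JUSTNAME")),
               "malformed")
})
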