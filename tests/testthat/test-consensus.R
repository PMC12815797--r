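two_clouds <- function(n_per = 10, sep = 100, d = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
    rownames(x) <- sprintf("s%02d", seq_len(2 * n_per))
    colnames(x) <- sprintf("d%d", seq_len(d))
    x
  })
}

test_that("a single full-sample replicate reproduces one K-means partition", {
  x <- two_clouds(seed = 2)
  cm <- consensus_matrix(x, 2, consensus_config(n_reps = 1,
                                                subsample_frac = 1, seed = 3),
                         store_assignments = TRUE)
  expect_true(all(cm$matrix %in% c(0, 1)))
  lab <- cm$assignments[[1]]$labels
  same <- outer(lab, lab, "==") * 1
  expect_equal(unname(cm$matrix), unname(same))
})

test_that("perfectly separated clouds give an all-or-nothing consensus", {
  x <- two_clouds(seed = 4)
  cm <- consensus_matrix(x, 2, consensus_config(n_reps = 60, seed = 5))
  truth <- rep(1:2, each = 10)
  within <- cm$matrix[outer(truth, truth, "==") & upper.tri(cm$matrix)]
  between <- cm$matrix[outer(truth, truth, "!=")]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_equal(cm$pac, 0)
})

test_that("consensus values equal a recount from the stored partitions", {
  withr::with_seed(6, {
    x <- matrix(rnorm(24), 12, 2,
                dimnames = list(sprintf("s%d", 1:12), c("a", "b")))
  })
  cm <- consensus_matrix(x, 3, consensus_config(n_reps = 50, seed = 7),
                         store_assignments = TRUE)
  n <- 12
  copair <- matrix(0, n, n); cosample <- matrix(0, n, n)
  for (rep in cm$assignments) {
    for (i in seq_along(rep$idx)) for (j in seq_along(rep$idx)) {
      a <- rep$idx[i]; b <- rep$idx[j]
      cosample[a, b] <- cosample[a, b] + 1
      if (rep$labels[i] == rep$labels[j]) copair[a, b] <- copair[a, b] + 1
    }
  }
  manual <- ifelse(cosample > 0, copair / pmax(cosample, 1), 0)
  diag(manual) <- 1
  expect_equal(unname(cm$matrix), manual)
  expect_identical(cm$copair_counts, matrix(as.integer(copair), n, n))
})

test_that("PAC follows the open-left closed-right window convention", {
  n <- 6
  make_result <- function(vals) {
    m <- matrix(0, n, n); m[upper.tri(m)] <- vals
    m <- m + t(m); diag(m) <- 1
    structure(list(matrix = m), class = "consensus_result")
  }
  # perfect 0/1 consensus
  expect_equal(pac(make_result(rep(c(0, 1), length.out = 15))), 0)
  # everything ambiguous
  expect_equal(pac(make_result(rep(0.5, 15))), 1)
  # random symmetric matrix vs direct counting
  vals <- withr::with_seed(8, runif(15))
  expect_equal(pac(make_result(vals)), mean(vals > 0.1 & vals <= 0.9))
  # boundary: a value exactly at the lower bound is NOT ambiguous,
  # at the upper bound it IS
  expect_equal(pac(make_result(c(0.1, 0.9, rep(0, 13)))), 1 / 15)
})

test_that("PAC is invariant under sample reordering", {
  x <- two_clouds(n_per = 8, sep = 3, seed = 9)
  cm1 <- consensus_matrix(x, 2, consensus_config(n_reps = 40, seed = 10))
  perm <- withr::with_seed(11, sample(nrow(x)))
  res <- structure(list(matrix = cm1$matrix[perm, perm]),
                   class = "consensus_result")
  expect_equal(pac(res), cm1$pac)
})

test_that("K selection takes the PAC argmin with ties to the smallest K", {
  expect_identical(select_k(c(`3` = 0.04, `4` = 0.2, `5` = 0.3)), 3L)
  expect_identical(select_k(c(`4` = 0.1, `3` = 0.1)), 3L)
  expect_identical(select_k(c(`5` = 0.02)), 5L)
})

test_that("labels recover a block-diagonal consensus exactly", {
  blocks <- rep(1:3, times = c(5, 4, 3))
  m <- outer(blocks, blocks, "==") * 1
  dimnames(m) <- list(sprintf("s%d", 1:12), sprintf("s%d", 1:12))
  res <- structure(list(K = 3L, matrix = m), class = "consensus_result")
  lab <- assign_clusters(res)
  expect_equal(as.numeric(tapply(lab, blocks, function(v) length(unique(v)))),
               c(1, 1, 1))
  # renumbering: largest block is cluster 1, smallest is cluster 3
  expect_identical(unname(lab[1]), 1L)
  expect_identical(unname(lab[12]), 3L)
  expect_error(assign_clusters(res, K = 20), "exceeds")
})

test_that("consensus clustering recovers planted labels on separated data", {
  withr::with_seed(12, {
    centers <- matrix(rnorm(3 * 5, sd = 6), 3, 5)
    truth <- rep(1:3, each = 15)
    x <- centers[truth, ] + matrix(rnorm(45 * 5), 45, 5)
    dimnames(x) <- list(sprintf("s%d", 1:45), sprintf("d%d", 1:5))
  })
  cm <- consensus_matrix(x, 3, consensus_config(n_reps = 60, seed = 13))
  expect_gte(adjusted_rand_index(assign_clusters(cm, 3), truth), 0.9)
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(20, {
    for (i in 1:5) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b))
    }
  })
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("identical seeds give identical consensus output", {
  x <- two_clouds(n_per = 8, sep = 2, seed = 14)
  cfg <- consensus_config(n_reps = 30, seed = 15)
  a <- consensus_matrix(x, 2, cfg)
  b <- consensus_matrix(x, 2, cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$pac, b$pac)
  expect_identical(assign_clusters(a, 2), assign_clusters(b, 2))
})

test_that("consensus matrices are symmetric with unit diagonal in [0,1]", {
  x <- two_clouds(n_per = 7, sep = 1, seed = 16)
  cm <- consensus_matrix(x, 2, consensus_config(n_reps = 25, seed = 17))
  expect_equal(cm$matrix, t(cm$matrix))
  expect_true(all(diag(cm$matrix) == 1))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
})

test_that("silhouette matches the brute-force definition on a toy set", {
  withr::with_seed(18, {
    x <- matrix(rnorm(20), 10, 2,
                dimnames = list(sprintf("s%d", 1:10), c("a", "b")))
  })
  lab <- rep(1:2, each = 5)
  got <- silhouette_score(x, lab)
  d <- as.matrix(dist(x))
  manual <- vapply(1:10, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(10) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(d[i, lab == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(unname(got$widths), manual)
  expect_equal(got$overall, mean(manual))
})

test_that("silhouette reflects geometry and rejects degenerate labelings", {
  x <- two_clouds(n_per = 10, sep = 100, seed = 19)
  expect_gt(silhouette_score(x, rep(1:2, each = 10))$overall, 0.9)
  # one cloud split arbitrarily into two labels: near zero or negative
  one <- x[1:10, ]
  expect_lt(silhouette_score(one, rep(1:2, 5))$overall, 0.25)
  expect_error(silhouette_score(x, rep(1, 20)), "2 clusters")
})
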