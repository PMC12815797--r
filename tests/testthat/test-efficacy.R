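noise_free_study <- function(effects = c(control = 1, treated = 0.5),
                             rate = 0.2, v0 = 100,
                             days = c(0, 2, 4, 7, 9, 11, 14)) {
  generate_growth_study(growth_sim_config(arms = effects, n_per_arm = 3,
                                          v0_mean = v0, v0_sd = 0,
                                          growth_rate = rate, noise_cv = 0,
                                          days = days, seed = 1))
}

test_that("caliper volume follows L*W^2/2 with the swap convention", {
  expect_equal(tumor_volume(10, 10), 500)
  expect_equal(tumor_volume(8, 6), 144)
  expect_warning(v <- tumor_volume(6, 8), "swapped")
  expect_equal(v, 144)
  expect_error(tumor_volume(0, 5), "positive")
})

test_that("growth-study construction validates its records", {
  df <- data.frame(animal = c("a1", "a1"), arm = "control",
                   day = c(0, 14), length_mm = c(6, 10), width_mm = c(5, 8))
  st <- growth_study(df)
  expect_equal(st$volume_mm3, c(75, 320))
  bad <- data.frame(animal = "a1", arm = c("x", "y"), day = c(0, 2),
                    volume_mm3 = c(50, 60))
  expect_error(growth_study(bad), "more than one arm")
  expect_error(growth_study(data.frame(animal = "a", arm = "b", day = 0,
                                       volume_mm3 = -2)), "positive")
})

test_that("growth studies round-trip through long-format CSV", {
  st <- noise_free_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(st, path)
  back <- read_growth_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(st), tolerance = 1e-12)
})

test_that("TGI matches the closed form on noise-free exponentials", {
  st <- noise_free_study()
  # delta method: 100 * (1 - (T14 - T0)/(C14 - C0))
  expected <- 100 * (1 - (100 * exp(0.2 * 0.5 * 14) - 100) /
                           (100 * exp(0.2 * 14) - 100))
  expect_equal(as.numeric(tgi(st, "treated", 14, "delta")), expected)
  expect_equal(as.numeric(tgi(st, "treated", 14, "ratio")),
               100 * (1 - exp(0.2 * 0.5 * 14) / exp(0.2 * 14)))
  expect_identical(attr(tgi(st, "treated", 14), "method"), "delta")
})

test_that("TGI limits: flat arm gives 100%, shrinking control errors", {
  st <- noise_free_study(effects = c(control = 1, flat = 0))
  expect_equal(as.numeric(tgi(st, "flat", 14, "delta")), 100)
  shrink <- noise_free_study(effects = c(control = 1, t = 0.5), rate = 0)
  expect_error(tgi(shrink, "t", 14, "delta"), "did not grow")
})

test_that("delta-TGI is the gap to the best monotherapy", {
  expect_equal(delta_tgi(25.4, c(-17.3, 0.7)), 24.7)
  expect_equal(delta_tgi(10, c(10, 3)), 0)
  expect_equal(delta_tgi(0, c(-5, -8)), 5)
})

test_that("normalized AUC is a control ratio with the expected direction", {
  st <- noise_free_study(effects = c(control = 1, same = 1, fast = 1.3,
                                     slow = 0.5))
  expect_equal(normalized_auc(st, "control"), 1)
  expect_equal(normalized_auc(st, "same"), 1)
  expect_gt(normalized_auc(st, "fast"), 1)
  # hand trapezoid on the 7-point schedule
  days <- c(0, 2, 4, 7, 9, 11, 14)
  trap <- function(eff) {
    y <- exp(0.2 * eff * days)
    sum(diff(days) * (head(y, -1) + tail(y, -1)) / 2)
  }
  expect_equal(normalized_auc(st, "slow"), trap(0.5) / trap(1))
  no0 <- st[st$day > 0 | st$arm != "slow", ]
  expect_error(normalized_auc(growth_study(no0), "slow"), "day-0")
})

test_that("Bliss and HSA indices follow their definitions", {
  s0 <- synergy_indices(0, 0, 30)
  expect_equal(s0$bliss_expected, 0)
  expect_equal(s0$bliss_exceedance, 0.3)
  # pure Bliss additivity
  s1 <- synergy_indices(50, 50, 75)
  expect_equal(s1$bliss_expected, 0.75)
  expect_equal(s1$bliss_exceedance, 0)
  # negative monotherapy fractions are legal and unclipped
  s2 <- synergy_indices(-20, 10, 40, 900, 1100, 500, day = 14)
  expect_equal(s2$bliss_expected, -0.2 + 0.1 - (-0.2 * 0.1))
  expect_equal(s2$hsa_excess, 900 - 500)
  expect_identical(s2$day, 14)
})

test_that("Bliss exceedance of the expected effect is identically zero", {
  grid <- expand.grid(fa = seq(-0.5, 1, by = 0.25),
                      fb = seq(-0.5, 1, by = 0.25))
  for (i in seq_len(nrow(grid))) {
    fa <- grid$fa[i]; fb <- grid$fb[i]
    expected <- fa + fb - fa * fb
    s <- synergy_indices(100 * fa, 100 * fb, 100 * expected)
    expect_equal(s$bliss_exceedance, 0)
  }
})

test_that("two-way ANOVA matches textbook cell-mean arithmetic", {
  # balanced 2x2 with integers
  vals <- c(10, 12, 14, 16, 20, 22, 28, 30)
  a <- rep(c(FALSE, TRUE), each = 4)
  b <- rep(c(FALSE, FALSE, TRUE, TRUE), 2)
  tab <- two_way_anova(vals, a, b)
  n <- 2
  cell <- tapply(vals, list(a, b), mean)
  grand <- mean(vals)
  ssa <- 4 * sum((tapply(vals, a, mean) - grand)^2)
  ssb <- 4 * sum((tapply(vals, b, mean) - grand)^2)
  ssab <- n * sum((cell - outer(rowMeans(cell) - grand,
                                colMeans(cell) - grand, "+") - grand)^2)
  expect_equal(tab$sum_sq[1], ssa)
  expect_equal(tab$sum_sq[2], ssb)
  expect_equal(tab$sum_sq[3], ssab)
  # conservation: components add to the total SS
  expect_equal(sum(tab$sum_sq), sum((vals - grand)^2))
  # row order invariance
  perm <- withr::with_seed(2, sample(8))
  expect_equal(two_way_anova(vals[perm], a[perm], b[perm])$sum_sq,
               tab$sum_sq)
})

test_that("additive responses give zero interaction and empty cells error", {
  a <- rep(c(FALSE, TRUE), each = 6)
  b <- rep(c(FALSE, TRUE), 6)
  vals <- 5 + 2 * a + 3 * b
  tab <- two_way_anova(vals, a, b)
  expect_equal(tab$sum_sq[3], 0, tolerance = 1e-20)
  expect_error(two_way_anova(vals[1:6], a[1:6], rep(FALSE, 6)),
               "at least 2")
})

test_that("randomization check summarizes and flags baseline imbalance", {
  same <- randomization_check(rep(100, 12), rep(c("a", "b", "c"), 4))
  expect_equal(same$pooled$sd, 0)
  expect_false(any(same$per_arm$flagged))

  v <- c(96.2, 95.1, 102.3, 88.7, 99.4, 91.8)
  got <- randomization_check(v, rep("x", 6))
  expect_equal(got$pooled$mean, mean(v))
  expect_equal(got$pooled$sd, sd(v))

  withr::with_seed(3, {
    base <- c(rnorm(10, 100, 3), rnorm(10, 100, 3), rnorm(10, 130, 3))
  })
  flag <- randomization_check(base, rep(c("a", "b", "shifted"), each = 10))
  expect_true(flag$per_arm$flagged[flag$per_arm$arm == "shifted"])
  expect_false(any(flag$per_arm$flagged[flag$per_arm$arm != "shifted"]))
})

test_that("the synergy report assembles all metrics consistently", {
  st <- generate_growth_study(growth_sim_config(seed = 4))
  rep <- synergy_report(st)
  expect_equal(rep$normalized_auc[["control"]], 1)
  expect_equal(rep$delta_tgi,
               rep$tgi[["combo"]] - max(rep$tgi[c("mono_a", "mono_b")]))
  expect_equal(rep$bliss_exceedance,
               rep$tgi[["combo"]] / 100 - rep$bliss_expected)
  expect_identical(rep$day, 14)
  expect_identical(nrow(rep$anova), 4L)
  # row-order invariance of the whole report
  perm <- withr::with_seed(5, sample(nrow(st)))
  rep2 <- synergy_report(growth_study(as.data.frame(st)[perm, ]))
  expect_equal(rep2$tgi, rep$tgi)
  expect_equal(rep2$bliss_exceedance, rep$bliss_exceedance)
  expect_error(synergy_report(st, roles = c(control = "nope", mono_a = "IPG7236",
                                            mono_b = "antiPDL1", combo = "combo")),
               "not in study")
})
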