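#' Caliper tumor volume
#'
#' `V = L * W^2 / 2` (mm3). If a width exceeds its length the two are
#' swapped with a warning, so the formula always squares the smaller
#' dimension.
#'
#' @param length,width caliper measurements in mm, vectorized.
#' @return volumes in mm3.
#' @export
tumor_volume <- function(length, width) {
  stopifnot(length(length) == length(width))
  if (any(length <= 0) || any(width <= 0))
    stop("caliper dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length; swapped")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Construct a tumor-growth study
#'
#' Long-format records of per-animal volume trajectories. Either a
#' `volume_mm3` column or the caliper pair `length_mm`/`width_mm` (converted
#' via [tumor_volume()]) must be present.
#'
#' @param records data.frame with columns `animal`, `arm`, `day`, and
#'   `volume_mm3` or `length_mm` + `width_mm`.
#' @return a `growth_study` (a validated data.frame).
#' @export
growth_study <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("animal", "arm", "day") %in% names(records)))
  if (!"volume_mm3" %in% names(records)) {
    if (!all(c("length_mm", "width_mm") %in% names(records)))
      stop("need a volume_mm3 column or length_mm + width_mm")
    records$volume_mm3 <- tumor_volume(records$length_mm, records$width_mm)
  }
  if (any(records$volume_mm3 <= 0)) stop("volumes must be positive")
  if (any(records$day < 0)) stop("days must be nonnegative")
  arm_per_animal <- tapply(records$arm, records$animal,
                           function(a) length(unique(a)))
  if (any(arm_per_animal > 1))
    stop("animal(s) assigned to more than one arm")
  rownames(records) <- NULL
  structure(records[, c("animal", "arm", "day", "volume_mm3")],
            class = c("growth_study", "data.frame"))
}

#' @export
print.growth_study <- function(x, ...) {
  cat(sprintf("<growth_study> %d arms, %d animals, days %s\n",
              length(unique(x$arm)), length(unique(x$animal)),
              paste(sort(unique(x$day)), collapse = ",")))
  invisible(as.data.frame(x))
}

#' Arm-wise mean volume curve
#'
#' @param study a [growth_study()].
#' @param arm arm name.
#' @return data.frame with `day` and mean `volume_mm3`, sorted by day.
#' @export
arm_mean_curve <- function(study, arm) {
  sub <- study[study$arm == arm, ]
  if (nrow(sub) == 0) stop("arm '", arm, "' not found")
  agg <- stats::aggregate(volume_mm3 ~ day, data = sub, FUN = mean)
  agg[order(agg$day), ]
}

curve_at <- function(curve, day) {
  i <- match(day, curve$day)
  if (is.na(i)) stop("no measurement on day ", day)
  curve$volume_mm3[i]
}

#' Tumor growth inhibition at a fixed day
#'
#' Delta method (default): `100 * (1 - (T_d - T_0) / (C_d - C_0))`, growth
#' of the treated arm relative to control growth. Ratio method:
#' `100 * (1 - T_d / C_d)`. The method used is recorded in the
#' `"method"` attribute.
#'
#' @param study a [growth_study()].
#' @param arm treated arm name.
#' @param day endpoint day (default: the last day measured in both arms).
#' @param method `"delta"` or `"ratio"`.
#' @param control control arm name (default `"control"`).
#' @return TGI in percent.
#' @export
tgi <- function(study, arm, day = NULL, method = c("delta", "ratio"),
                control = "control") {
  method <- match.arg(method)
  tc <- arm_mean_curve(study, arm)
  cc <- arm_mean_curve(study, control)
  if (is.null(day)) day <- max(intersect(tc$day, cc$day))
  t0 <- curve_at(tc, 0); td <- curve_at(tc, day)
  c0 <- curve_at(cc, 0); cd <- curve_at(cc, day)
  value <- if (method == "delta") {
    if (cd - c0 <= 0)
      stop("control arm did not grow over [0, ", day,
           "]; delta-method TGI undefined")
    100 * (1 - (td - t0) / (cd - c0))
  } else {
    100 * (1 - td / cd)
  }
  structure(value, method = method, day = day)
}

#' Improvement of the combination over the best monotherapy
#'
#' @param tgi_combo combination-arm TGI (percent).
#' @param tgi_monos numeric vector of monotherapy TGIs (percent).
#' @return `tgi_combo - max(tgi_monos)` in percentage points.
#' @export
delta_tgi <- function(tgi_combo, tgi_monos) {
  stopifnot(length(tgi_monos) >= 1)
  as.numeric(tgi_combo) - max(as.numeric(tgi_monos))
}

#' Baseline-normalized AUC ratio versus control
#'
#' Per animal, the trapezoidal AUC of `V(t) / V(interval start)` over the
#' interval; the arm value is the mean over animals and the returned
#' quantity is the ratio of the arm mean to the control-arm mean, so the
#' control maps to 1 by construction.
#'
#' @param study a [growth_study()].
#' @param arm arm name.
#' @param interval two days, default `c(0, 14)`.
#' @param control control arm name.
#' @return the AUC ratio (scalar).
#' @export
normalized_auc <- function(study, arm, interval = c(0, 14),
                           control = "control") {
  animal_auc <- function(a) {
    sub <- study[study$animal == a, ]
    sub <- sub[sub$day >= interval[1] & sub$day <= interval[2], ]
    sub <- sub[order(sub$day), ]
    if (sub$day[1] != interval[1])
      stop("animal ", a, " lacks a day-", interval[1], " measurement")
    trapz_auc(sub$day, sub$volume_mm3 / sub$volume_mm3[1])
  }
  arm_mean <- function(nm) {
    animals <- unique(study$animal[study$arm == nm])
    if (length(animals) == 0) stop("arm '", nm, "' not found")
    mean(vapply(animals, animal_auc, numeric(1)))
  }
  arm_mean(arm) / arm_mean(control)
}

#' HSA and Bliss independence synergy indices
#'
#' TGIs are converted to effect fractions `f = TGI / 100` (negative values
#' retained, no clipping). Bliss expected effect is
#' `f_a + f_b - f_a * f_b`; the exceedance is the observed combination
#' fraction minus the expectation (positive = synergy beyond independence).
#' HSA excess is the endpoint mean-volume reduction of the combination
#' below the best (smallest-volume) single agent, in mm3, when endpoint
#' volumes are supplied.
#'
#' @param tgi_a,tgi_b,tgi_ab monotherapy and combination TGIs in percent.
#' @param mean_vol_a,mean_vol_b,mean_vol_ab optional endpoint mean volumes
#'   (mm3) for the HSA index.
#' @param day optional endpoint day, echoed in the output.
#' @return a list with `bliss_expected`, `bliss_exceedance`, `hsa_excess`
#'   (`NA` without volumes) and `day`.
#' @export
synergy_indices <- function(tgi_a, tgi_b, tgi_ab,
                            mean_vol_a = NA_real_, mean_vol_b = NA_real_,
                            mean_vol_ab = NA_real_, day = NA) {
  f_a <- tgi_a / 100; f_b <- tgi_b / 100; f_ab <- tgi_ab / 100
  bliss_expected <- f_a + f_b - f_a * f_b
  list(bliss_expected = bliss_expected,
       bliss_exceedance = f_ab - bliss_expected,
       hsa_excess = min(mean_vol_a, mean_vol_b) - mean_vol_ab,
       day = day)
}

#' Two-way factorial ANOVA on endpoint values
#'
#' 2x2 design with factors A and B (treatment on/off) and their
#' interaction; sums of squares are computed on the (balanced) design via
#' [stats::aov()], where type I, II and III coincide.
#'
#' @param endpoint_values numeric vector (e.g. day-14 volumes, one per
#'   animal).
#' @param factor_a_on,factor_b_on logical vectors aligned with
#'   `endpoint_values`.
#' @return a data.frame with `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`
#'   for A, B, A:B and residuals.
#' @export
two_way_anova <- function(endpoint_values, factor_a_on, factor_b_on) {
  stopifnot(length(endpoint_values) == length(factor_a_on),
            length(endpoint_values) == length(factor_b_on))
  A <- factor(factor_a_on, levels = c(FALSE, TRUE))
  B <- factor(factor_b_on, levels = c(FALSE, TRUE))
  cells <- table(A, B)
  if (any(cells < 2))
    stop("every cell of the 2x2 design needs at least 2 observations")
  fit <- stats::aov(endpoint_values ~ A * B)
  tab <- summary(fit)[[1]]
  data.frame(term = c("A", "B", "A:B", "residuals"),
             df = tab[["Df"]],
             sum_sq = tab[["Sum Sq"]],
             mean_sq = tab[["Mean Sq"]],
             F = tab[["F value"]],
             p = tab[["Pr(>F)"]],
             stringsAsFactors = FALSE)
}

#' Baseline randomization check
#'
#' Per-arm and pooled mean +/- SD of baseline tumor volumes; an arm is
#' flagged when its mean deviates from the pooled mean by more than one
#' pooled SD.
#'
#' @param baselines positive numeric vector of baseline volumes.
#' @param arms arm labels aligned with `baselines`.
#' @return a list with `per_arm` (data.frame arm, n, mean, sd, flagged) and
#'   `pooled` (mean, sd).
#' @export
randomization_check <- function(baselines, arms) {
  stopifnot(all(baselines > 0), length(baselines) == length(arms))
  pooled_mean <- mean(baselines)
  pooled_sd <- stats::sd(baselines)
  per_arm <- do.call(rbind, lapply(unique(arms), function(a) {
    v <- baselines[arms == a]
    data.frame(arm = a, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  dev <- abs(per_arm$mean - pooled_mean)
  per_arm$flagged <- if (is.na(pooled_sd) || pooled_sd == 0) dev > 0
                     else dev > pooled_sd
  list(per_arm = per_arm,
       pooled = list(mean = pooled_mean, sd = pooled_sd))
}

#' Full efficacy and synergy report for a four-arm study
#'
#' Computes per-arm TGI at the endpoint day, the improvement over the best
#' monotherapy, per-arm normalized AUC ratios, HSA and Bliss synergy
#' indices, a two-way ANOVA on endpoint volumes, and a baseline
#' randomization check.
#'
#' @param study a [growth_study()].
#' @param roles named character vector mapping `control`, `mono_a`,
#'   `mono_b`, `combo` to arm names in the study.
#' @param day endpoint day; default is the last day measured in every arm.
#' @param tgi_method `"delta"` (default) or `"ratio"`.
#' @return a `synergy_report` list.
#' @export
synergy_report <- function(study,
                           roles = c(control = "control", mono_a = "IPG7236",
                                     mono_b = "antiPDL1", combo = "combo"),
                           day = NULL, tgi_method = "delta") {
  stopifnot(all(c("control", "mono_a", "mono_b", "combo") %in% names(roles)))
  missing_arms <- setdiff(roles, unique(study$arm))
  if (length(missing_arms))
    stop("arms not in study: ", paste(missing_arms, collapse = ", "))
  if (is.null(day)) {
    day <- max(Reduce(intersect,
                      lapply(roles, function(a) study$day[study$arm == a])))
  }
  treated <- roles[c("mono_a", "mono_b", "combo")]
  tgis <- vapply(treated, function(a)
    as.numeric(tgi(study, a, day, tgi_method, control = roles[["control"]])),
    numeric(1))
  auc <- vapply(roles, function(a)
    normalized_auc(study, a, c(0, day), control = roles[["control"]]),
    numeric(1))
  end_mean <- function(a)
    mean(study$volume_mm3[study$arm == a & study$day == day])
  syn <- synergy_indices(tgis[["mono_a"]], tgis[["mono_b"]], tgis[["combo"]],
                         end_mean(roles[["mono_a"]]),
                         end_mean(roles[["mono_b"]]),
                         end_mean(roles[["combo"]]), day = day)
  endpoint <- study[study$day == day & study$arm %in% roles, ]
  anova_tab <- two_way_anova(
    endpoint$volume_mm3,
    endpoint$arm %in% roles[c("mono_a", "combo")],
    endpoint$arm %in% roles[c("mono_b", "combo")])
  base <- study[study$day == min(study$day) & study$arm %in% roles, ]
  rand <- randomization_check(base$volume_mm3, base$arm)
  structure(list(day = day, tgi_method = tgi_method, roles = roles,
                 tgi = tgis,
                 delta_tgi = delta_tgi(tgis[["combo"]],
                                       tgis[c("mono_a", "mono_b")]),
                 normalized_auc = auc,
                 bliss_expected = syn$bliss_expected,
                 bliss_exceedance = syn$bliss_exceedance,
                 hsa_excess = syn$hsa_excess,
                 anova = anova_tab,
                 randomization = rand),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf("<synergy_report> day %s (%s TGI)\n", x$day, x$tgi_method))
  cat(sprintf("  TGI %%: mono_a %.1f, mono_b %.1f, combo %.1f (dTGI %.1f pp)\n",
              x$tgi[["mono_a"]], x$tgi[["mono_b"]], x$tgi[["combo"]],
              x$delta_tgi))
  cat(sprintf("  Bliss expected %.3f, exceedance %.3f; HSA excess %.1f mm3\n",
              x$bliss_expected, x$bliss_exceedance, x$hsa_excess))
  cat(sprintf("  ANOVA interaction p = %.3g\n", x$anova$p[3]))
  invisible(x)
}
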