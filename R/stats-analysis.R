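#' Pattern correlation with a one-sample t-test
#'
#' Quantifies how consistently a set of individual speed-fluctuation
#' sequences follows a reference pattern: each individual's mean-removed
#' sequence is correlated (Pearson) with the reference over their common
#' step indices, and the per-subject correlations are tested against zero
#' with a two-sided one-sample t-test. Correlation compares shape only, so
#' it is invariant to each sequence's amplitude and mean.
#'
#' @param individuals list of [speed_trajectory()] objects (one per
#'   subject, typically each subject's within-condition average).
#' @param reference a [speed_trajectory()] (e.g. the grand average, or the
#'   model prediction).
#' @param min_overlap smallest usable common index range.
#' @return a `pattern_correlation` list: `rho` (per subject), `mean_rho`,
#'   `sd_rho`, `t`, `df`, `p_value`, `n`.
#' @export
pattern_correlation <- function(individuals, reference, min_overlap = 5) {
  stopifnot(length(individuals) >= 2)
  rho <- vapply(individuals, function(tr) {
    idx <- intersect(tr$step_index, reference$step_index)
    if (length(idx) < min_overlap)
      stop_curbwalk("alignment", "common index range shorter than min_overlap")
    a <- fluctuations(tr)[match(idx, tr$step_index)]
    b <- fluctuations(reference)[match(idx, reference$step_index)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance sequence: correlation undefined, subject excluded")
      return(NA_real_)
    }
    stats::cor(a, b)
  }, numeric(1))
  ok <- !is.na(rho)
  if (stats::sd(rho[ok]) == 0) {
    # degenerate case (e.g. every sequence identical to the reference):
    # the one-sample t statistic is unbounded
    warning("per-subject correlations are constant: t-test degenerate")
    tt <- list(statistic = sign(mean(rho[ok])) * Inf,
               parameter = sum(ok) - 1,
               p.value = if (mean(rho[ok]) == 0) 1 else .Machine$double.xmin)
  } else tt <- stats::t.test(rho[ok], mu = 0)
  structure(list(rho = rho, mean_rho = mean(rho[ok]),
                 sd_rho = stats::sd(rho[ok]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = unname(tt$p.value), n = sum(ok)),
            class = "pattern_correlation")
}

#' @export
print.pattern_correlation <- function(x, ...) {
  cat(sprintf("Pattern correlation: rho = %.3f +/- %.3f (n = %d), t(%g) = %.2f, p = %.3g\n",
              x$mean_rho, x$sd_rho, x$n, x$df, x$t, x$p_value))
  invisible(x)
}

# pooled regression backbone shared by the two scaling fits:
# dv_ijk ~ (coef * ratio_jk + offset) * dv_i^ref, estimated as OLS on the
# two regressors ratio*dv_ref and dv_ref with no intercept.
scaling_fit <- function(trials, ratios, reference, coef_name) {
  y <- x1 <- x2 <- numeric(0)
  for (j in seq_along(trials)) {
    tr <- trials[[j]]
    idx <- intersect(tr$step_index, reference$step_index)
    dv <- fluctuations(tr)[match(idx, tr$step_index)]
    dvr <- fluctuations(reference)[match(idx, reference$step_index)]
    y <- c(y, dv)
    x1 <- c(x1, ratios[j] * dvr)
    x2 <- c(x2, dvr)
  }
  if (stats::sd(x2) == 0 && stats::sd(x1) == 0)
    stop_curbwalk("fit", "singular design: flat reference pattern")
  fit <- stats::lm(y ~ 0 + x1 + x2)
  if (any(!is.finite(stats::coef(fit))) || stats::sd(x1 - mean(ratios) * x2) == 0)
    stop_curbwalk("fit", "singular design: no spread in the scaling ratio")
  # noise-free recovery yields a perfect fit; its summary warning is benign
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  sm <- suppressWarnings(summary(fit))
  structure(list(coefficient = unname(stats::coef(fit)["x1"]),
                 offset = unname(stats::coef(fit)["x2"]),
                 ci_halfwidth = unname((ci[, 2] - ci[, 1]) / 2),
                 p_value = unname(sm$coefficients["x1", "Pr(>|t|)"]),
                 coef_name = coef_name,
                 n_trials = length(trials), n_points = length(y),
                 fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit (%s): coefficient = %.3f +/- %.3f (95%% CI), offset = %.3f, p = %.3g (%d trials, %d points)\n",
              x$coef_name, x$coefficient, x$ci_halfwidth[1], x$offset,
              x$p_value, x$n_trials, x$n_points))
  invisible(x)
}

#' Step-height scaling of the compensation pattern
#'
#' Tests whether each trial's fluctuation waveform scales in proportion to
#' its step height: `dv_ijk ~ (c_b * b_jk / b_up + d_b) * dv_i^up`, pooled
#' over all steps and trials by ordinary least squares. A coefficient `c_b`
#' near 1 means the Up-step pattern, sign-flipped, predicts Down-step
#' responses (twofold symmetry), with level trials intermediate.
#'
#' @param trials list of [speed_trajectory()] objects.
#' @param step_heights signed step height of each trial (same units as
#'   `b_up`).
#' @param reference_up the average Up-step fluctuation pattern.
#' @param b_up the reference Up-step height.
#' @return a `scaling_fit`: `coefficient` (`c_b`), `offset` (`d_b`), 95%
#'   CI half-widths, p-value for `c_b != 0`.
#' @export
fit_height_scaling <- function(trials, step_heights, reference_up,
                               b_up = max(step_heights)) {
  stopifnot(length(trials) == length(step_heights))
  if (length(unique(step_heights)) < 2)
    stop_curbwalk("fit", "need trials at two or more distinct step heights")
  scaling_fit(trials, step_heights / b_up, reference_up, "c_b")
}

#' Speed scaling of the compensation pattern
#'
#' Tests whether fluctuation amplitude decreases with overall walking
#' speed: `dv_ijk ~ (c_v * v_jk / v_up + d_v) * dv_i^up` over Up-step
#' trials. The model predicts `c_v < 0`: a fixed curb perturbs faster
#' (higher kinetic energy) walking relatively less.
#'
#' @param trials list of Up-step [speed_trajectory()] objects.
#' @param speeds each trial's overall speed (m/s).
#' @param reference_up the average Up-step fluctuation pattern.
#' @param v_up reference speed (defaults to the mean of `speeds`).
#' @return a `scaling_fit`: `coefficient` (`c_v`), `offset` (`d_v`), CI,
#'   p-value.
#' @export
fit_speed_scaling <- function(trials, speeds, reference_up,
                              v_up = mean(speeds)) {
  stopifnot(length(trials) == length(speeds))
  if (stats::sd(speeds) / mean(speeds) < 0.005)
    warning("speed range below 0.5% c.v.: the speed-scaling test is underpowered")
  scaling_fit(trials, speeds / v_up, reference_up, "c_v")
}

#' Overall speed and variability summary by condition
#'
#' Reports, per condition: the mean and SD (across subjects) of overall
#' trial speeds, the within-trial RMS speed fluctuation and its c.v., and
#' the between-trial speed c.v. per subject.
#'
#' @param trials list of [speed_trajectory()] objects.
#' @param subjects subject id per trial.
#' @param conditions condition label per trial.
#' @return a data frame with one row per condition.
#' @export
variability_summary <- function(trials, subjects, conditions) {
  stopifnot(length(trials) == length(subjects),
            length(trials) == length(conditions))
  tm <- vapply(trials, function(tr) mean(tr$speed_mps), numeric(1))
  rms <- vapply(trials, function(tr)
    sqrt(mean(fluctuations(tr)^2)), numeric(1))
  out <- lapply(unique(conditions), function(cc) {
    sel <- conditions == cc
    subj_mean <- tapply(tm[sel], subjects[sel], mean)
    subj_btcv <- tapply(tm[sel], subjects[sel], function(v)
      if (length(v) > 1) stats::sd(v) / mean(v) else NA_real_)
    data.frame(condition = cc,
               mean_speed = mean(subj_mean),
               sd_speed = if (length(subj_mean) > 1) stats::sd(subj_mean)
                          else NA_real_,
               within_trial_rms = mean(rms[sel]),
               within_trial_cv = mean(rms[sel] / tm[sel]),
               between_trial_cv = mean(subj_btcv, na.rm = TRUE),
               n_trials = sum(sel))
  })
  do.call(rbind, out)
}

#' Permutation check of the one-sample correlation test
#'
#' Recomputes the [pattern_correlation()] p-value under a sign-flipping
#' permutation null: the per-subject correlations have their signs flipped
#' at random and the mean recompared. With exchangeable, symmetric nulls
#' the permutation p agrees with the t-test p up to Monte-Carlo error.
#'
#' @param pc a `pattern_correlation`.
#' @param n_perm number of random sign assignments.
#' @param seed RNG seed.
#' @return the two-sided permutation p-value.
#' @export
permutation_p_value <- function(pc, n_perm = 2000, seed = 1L) {
  rho <- pc$rho[!is.na(pc$rho)]
  obs <- abs(mean(rho))
  with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(k) {
      s <- sample(c(-1, 1), length(rho), replace = TRUE)
      abs(mean(s * rho)) >= obs
    }, logical(1)))
    (hits + 1) / (n_perm + 1)
  })
}
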