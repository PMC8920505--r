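# shared clean and drifty trials for the pipeline tests
fx_clean_trial <- function() fixture("clean_trial", {
  cfg <- cohort_config(drift_rms = 0, cv_step_noise = 0, rng_seed = 31)
  tr <- generate_trial(1.38, "up", fx_pattern(), cfg, seed = 31)
  list(cfg = cfg, truth = tr,
       traces = synthesize_foot_traces(tr, cfg, seed = 31))
})
fx_drift_trial <- function() fixture("drift_trial", {
  cfg <- cohort_config(rng_seed = 32)
  tr <- generate_trial(1.38, "up", fx_pattern(), cfg, seed = 32)
  list(cfg = cfg, truth = tr,
       traces = synthesize_foot_traces(tr, cfg, seed = 32))
})
perturb_time <- function(truth) truth$footfalls$time_s[truth$perturbation_step + 1]

test_that("footfall detection finds the true dwells", {
  tt <- fx_clean_trial()
  for (foot in c("left", "right")) {
    ev <- detect_footfalls(tt$traces[[foot]])
    truth <- attr(tt$traces[[foot]], "true_dwell_times")
    expect_equal(nrow(ev), length(truth))
    # interior events within 20 ms of the true dwell midpoints (the first
    # and last dwell merge into the standing periods at the walkway ends)
    mid <- 2:(nrow(ev) - 1)
    expect_lt(max(abs(ev$time_s[mid] - truth[mid])), 0.020)
  }

  # a foot that never moves yields no strides, not spurious ones
  still <- tt$traces$left
  still$x_m <- rep(still$x_m[1], nrow(still))
  expect_error(detect_footfalls(still), class = "curbwalk_detection_error")

  # a threshold above swing speed labels everything stationary: error
  expect_error(detect_footfalls(tt$traces$left, speed_threshold = 50),
               class = "curbwalk_detection_error")

  # non-uniform sampling is a format error
  bad <- tt$traces$left
  bad$time_s[10] <- bad$time_s[10] + 0.004
  expect_error(detect_footfalls(bad), class = "curbwalk_format_error")
})

test_that("zero-velocity correction is exact where it should be", {
  tt <- fx_clean_trial()
  tr <- tt$traces$left
  ev <- detect_footfalls(tr)
  # correcting an uncorrupted signal leaves footfall positions untouched
  pos <- zupt_integrate(tr, ev)
  expect_lt(max(abs(pos$x_m[ev$index] - tr$x_m[ev$index])), 1e-6)

  # a constant velocity bias is cancelled exactly by the linear correction
  # (up to a common position offset from the biased integration anchor)
  biased <- tr
  biased$x_m <- tr$x_m + 0.02 * (biased$time_s - biased$time_s[1])
  posb <- zupt_integrate(biased, ev)
  rel <- function(x) x[ev$index] - x[ev$index[1]]
  expect_lt(max(abs(rel(posb$x_m) - rel(pos$x_m))), 1e-9)

  expect_error(zupt_integrate(tr, ev[1, , drop = FALSE]),
               class = "curbwalk_detection_error")
})

test_that("stride tables reproduce the true stride speeds", {
  tt <- fx_clean_trial()
  tr <- tt$traces$left
  ev <- detect_footfalls(tr)
  tab <- build_stride_table(zupt_integrate(tr, ev), ev)
  # defining identities
  expect_equal(tab$stride_length[-nrow(tab)],
               diff(tab$footfall_position), tolerance = 1e-12)
  expect_equal(tab$stride_speed, tab$stride_length / tab$stride_time)
  expect_true(all(diff(tab$footfall_time) > 0))
  # interior strides within 0.5% of ground truth
  truth <- tt$truth$footfalls[tt$truth$footfalls$foot == "left", ]
  true_speed <- diff(truth$x_m) / diff(truth$time_s)
  mid <- 2:(nrow(tab) - 2)
  expect_lt(max(abs(tab$stride_speed[mid] - true_speed[mid]) / true_speed[mid]),
            0.005)

  # two events give exactly one stride
  two <- build_stride_table(zupt_integrate(tr, ev), ev[3:4, ])
  expect_equal(sum(!is.na(two$stride_speed)), 1)
  expect_error(build_stride_table(zupt_integrate(tr, ev), ev[1, , drop = FALSE]),
               class = "curbwalk_detection_error")

  # equally spaced events with equal distances: identical speeds
  fake_pos <- structure(data.frame(time_s = seq(0, 10, 0.01),
                                   x_m = seq(0, 10, 0.01) * 1.3),
                        foot = "left")
  fake_ev <- data.frame(time_s = 1:8, index = 1 + 100 * (1:8),
                        x_m = 1.3 * (1:8))
  ft <- build_stride_table(fake_pos, fake_ev)
  expect_equal(unique(round(stats::na.omit(ft$stride_speed), 12)), 1.3)
})

test_that("detrending reconciles the feet without touching agreeing data", {
  tt <- fx_clean_trial()
  tabs <- lapply(tt$traces[c("left", "right")], function(tr) {
    ev <- detect_footfalls(tr)
    build_stride_table(zupt_integrate(tr, ev), ev)
  })
  tot <- function(s) s$footfall_position[nrow(s)] - s$footfall_position[1]

  # clean feet already agree: correction is (numerically) the identity
  d0 <- detrend_feet(tabs$left, tabs$right)
  expect_equal(d0$left$footfall_position, tabs$left$footfall_position,
               tolerance = 1e-6)
  expect_equal(tot(d0$left), tot(d0$right), tolerance = 1e-9)

  # one foot stretched by 2%: totals equalized exactly
  stretch <- tabs$left
  stretch$footfall_position <- stretch$footfall_position * 1.02
  d2 <- detrend_feet(stretch, tabs$right)
  expect_equal(tot(d2$left), tot(d2$right), tolerance = 1e-9)

  # grossly inconsistent feet are a quality failure
  broken <- tabs$left
  broken$footfall_position <- broken$footfall_position * 1.2
  expect_error(detrend_feet(broken, tabs$right),
               class = "curbwalk_quality_error")
})

test_that("the interleaved body-speed sequence aligns and crops correctly", {
  tt <- fx_clean_trial()
  rec <- reconstruct_trial(tt$traces, perturb_time(tt$truth), condition = "up")
  expect_s3_class(rec, "speed_trajectory")
  expect_true(all(diff(rec$time_s) > 0))
  expect_true(0 %in% rec$step_index)
  expect_equal(rec$time_s[rec$step_index == 0], 0, tolerance = 0.02)
  # 8.5 m of ~0.72 m steps retains on the order of a dozen samples
  expect_gte(nrow(rec), 10)
  expect_lte(nrow(rec), 15)

  # constant-speed control trial gives a flat sequence
  ctl <- generate_trial(1.38, "control", fx_pattern(), tt$cfg, seed = 41)
  ctr <- synthesize_foot_traces(ctl, tt$cfg, seed = 41)
  crec <- reconstruct_trial(ctr, perturb_time(ctl), condition = "control")
  expect_lt(stats::sd(crec$speed_mps) / mean(crec$speed_mps), 0.005)

  # alignment fails cleanly when the stated perturbation time is nonsense
  expect_error(reconstruct_trial(tt$traces, 1e4),
               class = "curbwalk_alignment_error")

  # re-running on the same trial is bit-identical
  rec2 <- reconstruct_trial(tt$traces, perturb_time(tt$truth), condition = "up")
  expect_identical(rec, rec2)
})

test_that("end-to-end recovery meets the error budget", {
  # drift disabled: within 0.5% of the stride-based ground truth
  tt <- fx_clean_trial()
  rec <- reconstruct_trial(tt$traces, perturb_time(tt$truth), condition = "up")
  ts <- true_body_speed(tt$truth, "stride")
  idx <- intersect(rec$step_index, ts$step_index)
  err <- rec$speed_mps[match(idx, rec$step_index)] -
    ts$speed_mps[match(idx, ts$step_index)]
  expect_lt(max(abs(err)) / mean(ts$speed_mps), 0.005)

  # default drift and noise: RMS error within 1.5% of mean speed
  dd <- fx_drift_trial()
  recd <- reconstruct_trial(dd$traces, perturb_time(dd$truth), condition = "up")
  tsd <- true_body_speed(dd$truth, "stride")
  idx <- intersect(recd$step_index, tsd$step_index)
  errd <- recd$speed_mps[match(idx, recd$step_index)] -
    tsd$speed_mps[match(idx, tsd$step_index)]
  expect_lt(sqrt(mean(errd^2)) / mean(tsd$speed_mps), 0.015)

  # the recovered fluctuations track the injected pattern
  pstr <- fx_pattern_stride()
  i2 <- intersect(recd$step_index, pstr$step_index)
  rho <- stats::cor(fluctuations(recd)[match(i2, recd$step_index)],
                    fluctuations(pstr)[match(i2, pstr$step_index)])
  expect_gt(rho, 0.8)
  # and essentially perfectly so without noise or drift
  i3 <- intersect(rec$step_index, pstr$step_index)
  rho0 <- stats::cor(fluctuations(rec)[match(i3, rec$step_index)],
                     fluctuations(pstr)[match(i3, pstr$step_index)])
  expect_gt(rho0, 0.99)
})

test_that("condition averaging behaves on identities, symmetry, and noise", {
  t1 <- toy_trajectory(c(0, 0.05, 0.1, -0.05, 0, 0.02, -0.02))
  expect_equal(average_condition(list(t1))$speed_mps, t1$speed_mps)

  # two trajectories mirrored about the mean average to a flat line
  t2 <- toy_trajectory(-c(0, 0.05, 0.1, -0.05, 0, 0.02, -0.02))
  avg <- average_condition(list(t1, t2))
  expect_equal(stats::sd(avg$speed_mps), 0, tolerance = 1e-12)
  expect_true(all(!is.na(avg$sd_mps)))

  # averaging noisy copies shrinks the error toward the clean pattern
  set.seed(5)
  base <- c(0, 0.02, 0.06, 0.12, -0.01, -0.09, -0.05, -0.02, 0)
  noisy <- replicate(8, toy_trajectory(base + rnorm(9, 0, 0.03)),
                     simplify = FALSE)
  avg_err <- sqrt(mean((fluctuations(average_condition(noisy)) - base)^2))
  one_err <- sqrt(mean((fluctuations(noisy[[1]]) - base)^2))
  expect_lt(avg_err, one_err)

  # disjoint index ranges cannot be averaged
  t3 <- speed_trajectory(step_index = 20:26, time_s = (20:26) * 0.5,
                         speed_mps = rep(1.4, 7))
  expect_error(average_condition(list(t1, t3)),
               class = "curbwalk_alignment_error")
})
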