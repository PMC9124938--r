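test_that("exactly linear alpha-vs-HR input is interpolated exactly", {
  fit <- hrvt(make_linear_alpha(1.0, 0.4, 120, 180))
  expect_equal(unname(coef(fit)), c(145, 170), tolerance = 1e-9)
  e <- fit$estimates
  expect_equal(e$method, c("regression", "regression"))
  expect_equal(e$r2, c(1, 1), tolerance = 1e-9)
  expect_equal(e$hr, (e$target - e$intercept) / e$slope, tolerance = 1e-9)
  expect_false(any(nzchar(e$qc)))
})

test_that("a trace that never reaches the target carries a no-crossing flag", {
  a <- make_linear_alpha(0.9, 0.9, 120, 180)    # constant at 0.9
  fit <- hrvt(a)
  expect_true(all(grepl("no_crossing", fit$estimates$qc)))
  expect_true(all(is.na(fit$estimates$hr)))
})

test_that("a series ending above 0.5 yields HRVT but flags HRVT2", {
  a <- make_linear_alpha(1.0, 0.55, 120, 180)
  fit <- hrvt(a)
  expect_false(grepl("no_crossing", fit$estimates$qc[1]))
  expect_true(is.finite(fit$estimates$hr[1]))
  expect_true(grepl("no_crossing", fit$estimates$qc[2]))
  expect_true(is.na(fit$estimates$hr[2]))
})

test_that("HRVT estimates shift by exactly c when HR shifts by c", {
  a <- make_linear_alpha(1.05, 0.38, 115, 185, n = 140)
  set.seed(31)
  a$alpha1 <- a$alpha1 + rnorm(nrow(a), 0, 0.03)
  base <- coef(hrvt(a))
  shifted <- a; shifted$hr_bpm <- shifted$hr_bpm + 12.5
  expect_equal(unname(coef(hrvt(shifted)) - base), c(12.5, 12.5),
               tolerance = 1e-9)
})

test_that("threshold estimation needs at least five usable windows", {
  a <- make_linear_alpha(n = 4)
  expect_error(hrvt(a), "at least 5")
})

test_that("noisy but monotone traces fall back to first-crossing with QC", {
  # strongly curved profile: poor linear fit, crossing still well-defined
  hr <- seq(120, 180, length.out = 100)
  al <- 1.0 - 0.6 * ((hr - 120) / 60)^6
  a <- make_linear_alpha(n = 100)
  a$alpha1 <- al; a$hr_bpm <- hr
  fit <- hrvt(a, targets = c(hrvt = 0.75))
  e <- fit$estimates
  if (e$method == "first_crossing") expect_match(e$qc, "poor_fit")
  truth <- 120 + 60 * (0.25 / 0.6)^(1 / 6)
  expect_equal(e$hr, truth, tolerance = 2)
})

test_that("planted ramp thresholds are recovered within field accuracy", {
  spec <- hrv_scenarios()$clean_ramp
  res <- t(sapply(1:8, function(s) {
    ramp <- generate_exercise_ramp(spec, seed = s)
    fit <- hrvt(ramp$series)
    c(fit$estimates$hr - c(ramp$truth$hrvt_hr, ramp$truth$hrvt2_hr),
      ordered = fit$estimates$hr[2] >= fit$estimates$hr[1])
  }))
  expect_lte(median(abs(res[, 1])), 3)
  expect_lte(median(abs(res[, 2])), 5)
  # ordering holds: HRVT2 at or above HRVT heart rate in nearly every seed
  expect_gte(mean(res[, 3]), 0.95)
})

test_that("HRVT/HRVT2 ordering is enforced with a QC flag when violated", {
  a <- make_linear_alpha(1.0, 0.4, 120, 180)
  up <- a; up$alpha1 <- rev(up$alpha1)          # alpha rising with HR
  fit <- suppressWarnings(hrvt(up))
  expect_true(all(grepl("poor_fit|no_crossing|inconsistent", fit$estimates$qc)))
})

test_that("load drift is zero on constant alpha and recovers programmed decline", {
  a <- make_linear_alpha(n = 60)
  a$alpha1 <- 0.8
  d <- load_drift(a)
  expect_equal(d$slope_per_h, 0, tolerance = 1e-12)
  expect_equal(d$mean_alpha1, 0.8)

  # programmed decline of 0.2 per hour with window noise
  set.seed(77)
  tt <- seq(120, 3600, by = 5)
  b <- data.frame(window_end_s = tt,
                  alpha1 = 0.95 - 0.2 * tt / 3600 + rnorm(length(tt), 0, 0.04),
                  hr_bpm = 120, power_w = 200, artifact_pct = 0, valid = TRUE)
  class(b) <- c("alpha_series", "data.frame")
  d <- load_drift(b)
  expect_equal(d$slope_per_h, -0.2, tolerance = 0.05)
  expect_error(load_drift(b[1:5, ]), "at least 10")
})

test_that("drift recovery holds through the full pipeline", {
  # one-hour constant-load session with exponent drifting 0.95 -> 0.75:
  # a 0.2-per-hour programmed decline, the magnitude seen in fading athletes
  seg <- data.frame(length_s = rep(300, 12),
                    H = seq(0.95, 0.75, length.out = 12),
                    mean_rr_ms = rep(700, 12), rr_sd_ms = rep(30, 12))
  spec <- ramp_spec(seg, seed = 3, name = "drift")
  slopes <- sapply(1:4, function(s) {
    ramp <- generate_exercise_ramp(spec, seed = s)
    load_drift(alpha1_rolling(ramp$series))$slope_per_h
  })
  expect_lt(abs(mean(slopes) - (-0.2)), 0.05)

  # stationary control at the same length: no spurious drift
  flat <- ramp_spec(data.frame(length_s = 3600, H = 0.85, mean_rr_ms = 700,
                               rr_sd_ms = 30), seed = 4, name = "flat")
  slopes0 <- sapply(1:4, function(s) {
    ramp <- generate_exercise_ramp(flat, seed = s)
    load_drift(alpha1_rolling(ramp$series))$slope_per_h
  })
  expect_lt(abs(mean(slopes0)), 0.05)
})

test_that("fit methods expose the regression consistently", {
  a <- make_linear_alpha(1.0, 0.4, 120, 180)
  set.seed(5)
  a$alpha1 <- a$alpha1 + rnorm(nrow(a), 0, 0.02)
  fit <- hrvt(a)
  expect_equal(length(residuals(fit)), length(predict(fit)))
  expect_equal(predict(fit, c(150)),
               fit$estimates$intercept[1] + fit$estimates$slope[1] * 150,
               tolerance = 1e-9)
  expect_output(print(fit), "HRVT")
  expect_output(print(summary(fit)), "regression")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
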