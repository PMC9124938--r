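test_that("threshold detector follows the absolute-deviation rule", {
  x <- rr_series(rep(1000, 50))
  expect_length(detect_artifacts(x, "threshold", "medium")$flagged, 0)

  rr <- rep(1000, 50); rr[25] <- 2000          # merged beat: |2000-1000| > 250
  x <- suppressWarnings(rr_series(rr))
  r <- detect_artifacts(x, "threshold", "medium")
  expect_equal(r$flagged, 25L)
  expect_equal(r$pct, 100 / 50)

  rr <- rep(1000, 50); rr[25] <- 1200          # 200 ms: > 150 but < 250
  x <- rr_series(rr)
  expect_length(detect_artifacts(x, "threshold", "medium")$flagged, 0)
  expect_equal(detect_artifacts(x, "threshold", "strong")$flagged, 25L)

  expect_error(detect_artifacts(rr_series(rep(1000, 5)), "threshold"), "11 beats")
  expect_error(detect_artifacts(rr_series(rep(1000, 50)), "threshold", "huge"),
               "unknown threshold level")
})

test_that("stricter threshold levels flag supersets of looser levels", {
  for (seed in 1:5) {
    set.seed(seed)
    rr <- rnorm(400, 800, 40)
    rr[sample(20:380, 12)] <- rr[sample(20:380, 12)] +
      sample(c(-1, 1), 12, TRUE) * runif(12, 100, 900)
    x <- suppressWarnings(rr_series(pmax(rr, 300)))
    levels <- c("very_low", "low", "medium", "strong", "very_strong")
    flags <- lapply(levels, function(l) detect_artifacts(x, "threshold", l)$flagged)
    for (i in seq_len(length(levels) - 1L)) {
      expect_true(all(flags[[i]] %in% flags[[i + 1L]]),
                  info = paste("level nesting at seed", seed, levels[i]))
    }
  }
})

test_that("automatic detector isolates aberrant beats", {
  x <- rr_series(rep(1000, 100))
  expect_length(detect_artifacts(x, "automatic")$flagged, 0)

  set.seed(2)
  rr <- rnorm(200, 800, 30); rr[100] <- rr[100] * 2
  x <- suppressWarnings(rr_series(rr))
  expect_true(100L %in% detect_artifacts(x, "automatic")$flagged)

  expect_error(detect_artifacts(rr_series(rep(1000, 20)), "automatic"),
               "30 beats")
})

test_that("detectors recover injected missed beats with high recall and low FPR", {
  recalls_auto <- recalls_med <- fprs_med <- numeric(0)
  for (seed in 1:50) {
    x <- make_iid_series(1000, 800, 30, seed = seed)
    inj <- inject_missed_beats(x, 6, seed = seed + 500)
    truth <- inj$log - seq_along(inj$log) + 1L   # positions after deletions
    n_deg <- length(inj$series$rr)
    ra <- detect_artifacts(inj$series, "automatic")
    rm <- detect_artifacts(inj$series, "threshold", "medium")
    recalls_auto <- c(recalls_auto, mean(truth %in% ra$flagged))
    recalls_med <- c(recalls_med, mean(truth %in% rm$flagged))
    fprs_med <- c(fprs_med, length(setdiff(rm$flagged, truth)) /
                    (n_deg - length(truth)))
  }
  expect_gte(mean(recalls_auto), 0.9)
  expect_gte(mean(recalls_med), 0.9)
  expect_lte(mean(fprs_med), 0.01)
})

test_that("correction is the identity on clean series", {
  x <- make_iid_series(300, seed = 9)
  r <- detect_artifacts(x, "threshold", "medium")
  expect_length(r$flagged, 0)
  expect_identical(correct_artifacts(x, r), x)
})

test_that("merged beats are split with exact duration conservation", {
  rr <- rep(1000, 50); rr[25] <- 2000
  x <- suppressWarnings(rr_series(rr))
  r <- detect_artifacts(x, "threshold", "medium")
  xc <- correct_artifacts(x, r)
  expect_length(xc$rr, 51)                      # beat count restored
  expect_equal(duration(xc), duration(x))       # duration conserved
  expect_equal(xc$rr[25:26], c(1000, 1000), tolerance = 1e-6)
  expect_true(all(xc$corrected[25:26]))
  r_all <- r; r_all$flagged <- seq_along(x$rr)
  expect_error(correct_artifacts(x, r_all), "every beat")
})

test_that("corrected series re-detect below the original artifact level", {
  for (seed in 1:5) {
    x <- make_iid_series(800, 800, 30, seed = seed)
    inj <- inject_missed_beats(x, 5, seed = seed)
    before <- detect_artifacts(inj$series, "threshold", "medium")
    xc <- correct_artifacts(inj$series, before)
    after <- detect_artifacts(xc, "threshold", "medium")
    expect_lt(after$pct, before$pct)
  }
})

test_that("missed-beat injection deletes non-adjacent interior beats and conserves time", {
  x <- make_iid_series(1000, seed = 21)
  inj <- inject_missed_beats(x, 6, seed = 3)
  expect_length(inj$log, 60)
  expect_length(inj$series$rr, 940)
  expect_identical(duration(inj$series), duration(x))
  expect_true(all(diff(inj$log) >= 2))          # no two adjacent
  expect_true(all(inj$log > 1 & inj$log < 1000))

  inj2 <- inject_missed_beats(x, 6, seed = 3)
  expect_identical(inj2$log, inj$log)           # determinism
  expect_identical(inj2$series$rr, inj$series$rr)

  small <- rr_series(rep(1000, 10))
  expect_warning(out <- inject_missed_beats(small, 1, seed = 1), "0 deletions")
  expect_identical(out$series$rr, small$rr)
  expect_error(inject_missed_beats(x, 0), "pct")
  expect_error(inject_missed_beats(x, 25), "pct")
})

test_that("smoothness-priors detrending removes trend and mean", {
  z <- rnorm(100, 900, 20)
  expect_equal(sp_detrend(z, lambda = 0), rep(0, 100))

  ramp <- seq(600, 1000, length.out = 200)      # pure linear trend
  out <- sp_detrend(ramp, lambda = 500)
  expect_lt(max(abs(out)), 0.01 * diff(range(ramp)))

  for (seed in 1:5) {
    set.seed(seed)
    z <- cumsum(rnorm(150)) + rnorm(150, 800, 30)
    d <- sp_detrend(z)
    expect_lt(abs(mean(d)), 1e-6 * sd(d))
  }
  expect_error(sp_detrend(c(1, 2)), "at least 3")
})
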