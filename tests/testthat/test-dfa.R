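test_that("alpha1 separates the correlation regimes", {
  white <- sapply(1:30, function(s) {
    set.seed(s); dfa_alpha1(rnorm(1000, 800, 30))
  })
  expect_equal(mean(white), 0.5, tolerance = 0.05)

  onef <- sapply(1:30, function(s) dfa_alpha1(generate_fgn(1000, 1.0, seed = s)))
  expect_equal(mean(onef), 1.0, tolerance = 0.1)

  anti <- sapply(1:30, function(s) dfa_alpha1(generate_fgn(1000, 0.3, seed = s)))
  expect_lt(mean(anti), 0.5)
  expect_equal(mean(anti), 0.3, tolerance = 0.1)
})

test_that("degenerate windows yield invalid results", {
  expect_true(is.na(dfa_alpha1(rep(1000, 500))))   # zero fluctuation
  expect_true(is.na(dfa_alpha1(rnorm(20))))        # too short for the box range
})

test_that("alpha1 is exactly invariant under affine rescaling", {
  set.seed(44)
  rr <- rnorm(500, 800, 30)
  a <- dfa_alpha1(rr)
  expect_equal(dfa_alpha1(3.7 * rr + 250), a, tolerance = 1e-12)
  expect_equal(dfa_alpha1(0.01 * rr - 5), a, tolerance = 1e-12)
})

test_that("mean alpha1 rises monotonically with the programmed exponent", {
  hs <- c(0.3, 0.5, 0.75, 1.0)
  means <- sapply(hs, function(H) {
    mean(sapply(1:40, function(s) dfa_alpha1(generate_fgn(1000, H, seed = s * 31))))
  })
  expect_true(all(diff(means) > 0))
  expect_true(all(abs(means - hs) <= 0.1))
})

test_that("rolling windows follow the (T - window)/grid + 1 count", {
  x <- rr_series(rep(600, 1000))               # exactly 600 s
  a <- suppressWarnings(alpha1_rolling(x))
  expect_equal(nrow(a), (600 - 120) / 5 + 1)   # 97 windows
  expect_equal(a$window_end_s, seq(120, 600, by = 5))
  expect_false(any(a$valid))                   # constant input: invalid

  short <- rr_series(rep(1000, 119))
  expect_warning(empty <- alpha1_rolling(short), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("stationary series give flat alpha traces near 0.5", {
  x <- make_iid_series(1200, 600, 25, seed = 5)
  a <- alpha1_rolling(x)
  expect_true(all(a$valid))
  expect_equal(mean(a$alpha1), 0.5, tolerance = 0.06)
  trend <- coef(lm(alpha1 ~ window_end_s, a))[2]
  expect_lt(abs(trend), 1e-3)
  expect_true(all(abs(a$hr_bpm - 100) < 2))    # 600 ms beats = 100 bpm
})

test_that("windows beyond the artifact QC limit are invalid", {
  x <- make_iid_series(900, 600, 25, seed = 8)
  inj <- inject_missed_beats(x, 8, seed = 1)
  xc <- correct_artifacts(inj$series, detect_artifacts(inj$series, "threshold",
                                                       "medium"))
  a <- alpha1_rolling(xc)
  high <- a$artifact_pct > 5
  expect_true(any(high))
  expect_false(any(a$valid[high]))
})

test_that("streaming mode emits per beat and matches batch on the same window", {
  x <- make_iid_series(200, seed = 13)
  a <- alpha1_realtime(x)
  expect_equal(nrow(a), 1L)
  expect_equal(a$window_end_s, x$t[200])
  # exact agreement with a hand-built batch computation on beats 1..200
  expect_equal(a$alpha1, dfa_alpha1(sp_detrend(x$rr)))

  expect_equal(nrow(alpha1_realtime(make_iid_series(199, seed = 13))), 0L)

  y <- make_iid_series(260, seed = 14)
  b <- alpha1_realtime(y)
  expect_equal(nrow(b), 61L)
  expect_equal(b$alpha1[32],
               dfa_alpha1(sp_detrend(y$rr[32:231])))
})

test_that("trailing moving average smooths valid windows only", {
  a <- make_linear_alpha(n = 20)
  expect_equal(alpha_moving_average(a, 1)$alpha1, a$alpha1)

  const <- a; const$alpha1 <- 0.8
  expect_equal(alpha_moving_average(const, 4)$alpha1, rep(0.8, 20))

  b <- a[1:4, ]; b$alpha1 <- c(1.0, 0.8, 0.6, 0.4)
  sm <- alpha_moving_average(b, 4)
  expect_equal(sm$alpha1[4], 0.7)
  expect_equal(sm$partial, c(TRUE, TRUE, TRUE, FALSE))

  # invalid windows are passed over, not averaged in
  c3 <- a[1:6, ]; c3$alpha1 <- c(1, NA, 1, 1, 1, 1); c3$valid[2] <- FALSE
  sm <- alpha_moving_average(c3, 2)
  expect_true(is.na(sm$alpha1[2]))
  expect_equal(sm$alpha1[3], 1)
})
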