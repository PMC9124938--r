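#' Configuration for short-term DFA and its rolling computation
#'
#' @param n_min smallest box size in beats (default 4).
#' @param n_max largest box size in beats (default 16). Boxes 4--16 are the
#'   universal short-term convention for alpha1.
#' @param window_s rolling window width in seconds (default 120).
#' @param grid_s recalculation interval in seconds (default 5).
#' @param min_beats minimum beats a window must hold to be valid (default 100).
#' @param realtime_beats window length in beat-count (streaming) mode
#'   (default 200).
#' @param detrend_lambda smoothness-priors smoothing parameter applied per
#'   window before DFA (default 500); `NA` disables detrending.
#' @param max_artifact_pct windows with more than this percentage of corrected
#'   beats are marked invalid (default 5).
#' @return a `dfa_config` list.
#' @export
dfa_config <- function(n_min = 4L, n_max = 16L, window_s = 120, grid_s = 5,
                       min_beats = 100L, realtime_beats = 200L,
                       detrend_lambda = 500, max_artifact_pct = 5) {
  stopifnot(n_min >= 4L, n_min < n_max, window_s > 0, grid_s > 0,
            min_beats >= n_max, realtime_beats >= min_beats)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 window_s = window_s, grid_s = grid_s,
                 min_beats = as.integer(min_beats),
                 realtime_beats = as.integer(realtime_beats),
                 detrend_lambda = detrend_lambda,
                 max_artifact_pct = max_artifact_pct),
            class = "dfa_config")
}

#' Short-term DFA scaling exponent alpha1
#'
#' Computes the short-term scaling exponent of detrended fluctuation analysis
#' on one window of RR intervals: (1) subtract the window mean; (2) integrate
#' by cumulative sum; (3) for each box size `n` from `n_min` to `n_max`,
#' partition the profile into non-overlapping boxes of `n` points (trailing
#' partial box discarded), fit a least-squares line in each box, and take the
#' root-mean-square residual `F(n)` over all covered points; (4) alpha1 is the
#' least-squares slope of `log F(n)` against `log n`.
#'
#' Values near 1 indicate fractal, well-correlated beat patterns; 0.5 is
#' uncorrelated (white) behaviour; below 0.5 is anticorrelated.
#'
#' At the short box sizes used for alpha1 the raw fluctuation function carries
#' a finite-size bias: for exact fractional Gaussian noise the expectation
#' \eqn{E[F^2(n)] = tr(M \Sigma_H)/n} (with \eqn{M} the in-box linear
#' residual-maker and \eqn{\Sigma_H} the fGn profile covariance) is not
#' proportional to \eqn{n^{2H}} at boxes 4--16 — for uncorrelated data it is
#' \eqn{\sigma^2 (n^2-4)/(15n)}, inflating the naive slope by about 0.08. The
#' estimator therefore runs two passes: a provisional slope from the
#' white-noise-corrected fit, then a refit of
#' \eqn{\log F(n) - \log\sqrt{E[F^2(n; H_0)]}} against \eqn{\log n} around the
#' provisional exponent, which cancels the finite-size curvature to first
#' order across the whole anticorrelated-to-correlated range.
#'
#' @param rr numeric vector of RR intervals (ms or any affine rescaling:
#'   alpha1 is invariant under `a * rr + b`, `a > 0`).
#' @param config a [dfa_config()] (only the box-size range is used here).
#' @return the scaling exponent, or `NA` for degenerate input (fewer than
#'   `min_beats` points handled by callers; constant input has `F(n) = 0` and
#'   an undefined slope).
#' @export
dfa_alpha1 <- function(rr, config = dfa_config()) {
  x <- as.numeric(rr)
  N <- length(x)
  scales <- config$n_min:config$n_max
  if (N < 2L * config$n_max) return(NA_real_)
  if (stats::sd(x) == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(n) {
    nb <- N %/% n
    m <- matrix(y[seq_len(nb * n)], nrow = n)
    tt <- seq_len(n)
    res <- stats::lsfit(tt, m)$residuals
    sqrt(mean(res^2))
  }, numeric(1))
  if (any(Fn <= 0)) return(NA_real_)
  logn <- log(scales)
  logF <- log(Fn)
  # pass 1: white-noise finite-size correction (exact at H = 0.5)
  a <- unname(stats::lsfit(logn, logF + log(scales / sqrt(scales^2 - 4)))$coefficients[2L])
  # pass 2/3: rescale by the exact fGn expectation at the provisional exponent
  for (it in 1:2) {
    H0 <- min(max(a, 0.05), 0.98)
    a <- H0 + unname(stats::lsfit(logn, logF - .dfa_expected_logF(scales, H0))$coefficients[2L])
  }
  a
}

# log sqrt(E[F^2(n)]) for unit-variance fGn with Hurst H: per-box expected
# residual variance tr(M Sigma_H)/n, M the linear-detrend residual maker.
# Offsets between boxes and the global profile-mean drift are absorbed by the
# per-box intercept and slope, so this is exact for any series length.
.dfa_expected_logF <- local({
  cache <- new.env(parent = emptyenv())
  function(scales, H) {
    key <- paste0(format(round(H, 5)), ":", paste(scales, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- vapply(scales, function(n) {
      i <- seq_len(n)
      S <- 0.5 * (outer(i^(2 * H), rep(1, n)) + outer(rep(1, n), i^(2 * H)) -
                    abs(outer(i, i, "-"))^(2 * H))
      X <- cbind(1, i)
      M <- diag(n) - X %*% solve(crossprod(X), t(X))
      0.5 * log(sum(M * S) / n)
    }, numeric(1))
    cache[[key]] <- out
    out
  }
})

#' Rolling time-varying alpha1
#'
#' Recomputes alpha1 on a fixed-width rolling window over the whole recording:
#' windows end at `t = window_s, window_s + grid_s, ...` up to the recording
#' duration, each taking the beats whose end times fall in
#' `(t - window_s, t]`. Per window the chain is smoothness-priors detrending
#' followed by [dfa_alpha1()]; the window's mean heart rate, mean aligned
#' power (when a power channel is attached) and percentage of corrected beats
#' are recorded alongside. Windows with fewer than `min_beats` beats or with
#' artifact percentage above `max_artifact_pct` are marked invalid.
#'
#' @param x an [rr_series()].
#' @param config a [dfa_config()].
#' @return an `alpha_series`: a data frame with columns `window_end_s`,
#'   `alpha1`, `hr_bpm`, `power_w`, `artifact_pct`, `valid`, one row per
#'   window end on the grid. Empty (with a warning) when the recording is
#'   shorter than one window.
#' @export
alpha1_rolling <- function(x, config = dfa_config()) {
  stopifnot(inherits(x, "rr_series"))
  T_end <- duration(x)
  empty <- data.frame(window_end_s = numeric(0), alpha1 = numeric(0),
                      hr_bpm = numeric(0), power_w = numeric(0),
                      artifact_pct = numeric(0), valid = logical(0))
  class(empty) <- c("alpha_series", "data.frame")
  if (T_end < config$window_s) {
    warning(sprintf("recording (%.1f s) shorter than one %g-s window", T_end,
                    config$window_s))
    return(empty)
  }
  ends <- seq(config$window_s, T_end, by = config$grid_s)
  rows <- lapply(ends, function(te) {
    sel <- x$t > te - config$window_s & x$t <= te
    nb <- sum(sel)
    art <- if (nb > 0L) 100 * mean(x$corrected[sel]) else 0
    hr <- if (nb > 0L) 60000 / mean(x$rr[sel]) else NA_real_
    if (nb < config$min_beats) {
      return(data.frame(window_end_s = te, alpha1 = NA_real_, hr_bpm = hr,
                        power_w = NA_real_, artifact_pct = art, valid = FALSE))
    }
    w <- x$rr[sel]
    if (!is.na(config$detrend_lambda)) w <- sp_detrend(w, config$detrend_lambda)
    a1 <- dfa_alpha1(w, config)
    pw <- mean(channel_at(x$channels, "power_w",
                          seq(te - config$window_s + 1, te, by = 1)))
    data.frame(window_end_s = te, alpha1 = a1, hr_bpm = hr, power_w = pw,
               artifact_pct = art,
               valid = !is.na(a1) && art <= config$max_artifact_pct)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("alpha_series", "data.frame")
  out
}

#' Streaming (beat-count) alpha1
#'
#' Real-time variant: for every beat `k >= realtime_beats`, alpha1 over the
#' prior `realtime_beats` beats (`k - realtime_beats + 1` to `k`), emitted per
#' beat — the semantics of head-unit data fields that report alpha1 each
#' second from the prior 200 beats. The per-window chain (detrend then DFA)
#' matches [alpha1_rolling()], so the two modes agree exactly when configured
#' to identical beat windows.
#'
#' @param x an [rr_series()].
#' @param config a [dfa_config()] (`realtime_beats` sets the window).
#' @return an `alpha_series` with one row per emitting beat (empty when the
#'   series is shorter than one window).
#' @export
alpha1_realtime <- function(x, config = dfa_config()) {
  stopifnot(inherits(x, "rr_series"))
  n <- length(x$rr)
  w <- config$realtime_beats
  empty <- data.frame(window_end_s = numeric(0), alpha1 = numeric(0),
                      hr_bpm = numeric(0), power_w = numeric(0),
                      artifact_pct = numeric(0), valid = logical(0))
  class(empty) <- c("alpha_series", "data.frame")
  if (n < w) return(empty)
  rows <- lapply(w:n, function(k) {
    sel <- (k - w + 1L):k
    rrw <- x$rr[sel]
    dw <- if (!is.na(config$detrend_lambda)) sp_detrend(rrw, config$detrend_lambda) else rrw
    a1 <- dfa_alpha1(dw, config)
    art <- 100 * mean(x$corrected[sel])
    data.frame(window_end_s = x$t[k], alpha1 = a1, hr_bpm = 60000 / mean(rrw),
               power_w = NA_real_, artifact_pct = art,
               valid = !is.na(a1) && art <= config$max_artifact_pct)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("alpha_series", "data.frame")
  out
}

#' Trailing moving average of an alpha series
#'
#' Smooths the alpha1 trace with a trailing `k`-point mean over valid windows,
#' the smoothing drawn as "N-point moving average" lines in time-varying HRV
#' plots (4 points is customary). The first `k - 1` smoothed values average
#' fewer than `k` points and are marked `partial`.
#'
#' @param alpha an `alpha_series`.
#' @param k window length in points, `>= 1`; `k = 1` is the identity.
#' @return the alpha series with `alpha1` replaced by its trailing mean over
#'   valid rows (invalid rows keep `NA`) and a logical `partial` column added.
#' @export
alpha_moving_average <- function(alpha, k = 4L) {
  stopifnot(is.data.frame(alpha), k >= 1L)
  k <- as.integer(k)
  out <- alpha
  v <- which(out$valid)
  a <- out$alpha1[v]
  sm <- vapply(seq_along(a), function(i) mean(a[max(1L, i - k + 1L):i]), numeric(1))
  out$alpha1[v] <- sm
  out$partial <- FALSE
  if (length(v)) out$partial[v[seq_len(min(k - 1L, length(v)))]] <- TRUE
  class(out) <- c("alpha_series", "data.frame")
  out
}

#' @export
print.alpha_series <- function(x, ...) {
  cat(sprintf("alpha_series: %d windows (%d valid)", nrow(x), sum(x$valid)))
  if (nrow(x)) {
    cat(sprintf(", t = %.0f..%.0f s, alpha1 %.2f..%.2f", min(x$window_end_s),
                max(x$window_end_s), min(x$alpha1, na.rm = TRUE),
                max(x$alpha1, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
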