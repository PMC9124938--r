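#' Generate fractional Gaussian noise
#'
#' Exact synthesis of stationary fractional Gaussian noise (fGn) with Hurst
#' exponent `H` by circulant embedding of the autocovariance (Davies-Harte):
#' the fGn autocovariance \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})/2} is embedded in a circulant matrix whose eigenvalues are
#' non-negative for fGn, and a sample path is drawn in the Fourier domain. For
#' `H >= 1`, where stationary fGn is not defined, a 1/f-type surrogate is
#' synthesised by inverse-spectrum shaping with spectral exponent
#' \eqn{\beta = 2H - 1} (so `H = 1` gives an exact 1/f spectrum). The DFA
#' scaling exponent of the output approximates `H` in both regimes.
#'
#' The returned series is standardised to zero sample mean and unit sample
#' variance; its lag-1 autocorrelation matches the closed form
#' \eqn{\rho(1) = 2^{2H-1} - 1} within sampling error.
#'
#' @param n series length, at least 16.
#' @param H target scaling exponent, in (0, 1.5); exact fGn for `H < 1`.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `n`.
#' @export
generate_fgn <- function(n, H, seed = NULL) {
  stopifnot(n >= 16L)
  if (!(H > 0 && H < 1.5)) stop("H must be in (0, 1.5), got ", H)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- if (H < 1) .fgn_circulant(n, H) else .fgn_spectral(n, 2 * H - 1)
  as.numeric(scale(x))
}

# Davies-Harte circulant embedding, exact for 0 < H < 1
.fgn_circulant <- function(n, H) {
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  c_row <- c(g, g[n:2])                     # length 2n, circulant first row
  ev <- Re(stats::fft(c_row))
  ev[ev < 0] <- 0                           # clip fp noise; fGn embedding is PSD
  m <- 2L * n
  z1 <- stats::rnorm(n + 1L)
  z2 <- stats::rnorm(n - 1L)
  w <- complex(length.out = m)
  w[1L] <- sqrt(ev[1L]) * z1[1L]
  w[n + 1L] <- sqrt(ev[n + 1L]) * z1[n + 1L]
  idx <- 2:n
  w[idx] <- sqrt(ev[idx] / 2) * complex(real = z1[idx], imaginary = z2[idx - 1L])
  w[m + 2L - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w, inverse = TRUE)) / sqrt(m)
  x[seq_len(n)]
}

# 1/f^beta surrogate via inverse-spectrum shaping of white noise
.fgn_spectral <- function(n, beta) {
  zf <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1L)
  freq <- pmin(k, n - k) / n
  amp <- ifelse(freq > 0, freq^(-beta / 2), 0)
  Re(stats::fft(zf * amp, inverse = TRUE)) / n
}

#' Specify a synthetic incremental-exercise ramp
#'
#' A ramp is a sequence of piecewise-stationary segments, each with a target
#' scaling exponent `H`, a mean RR interval and an RR standard deviation;
#' neighbouring segments are joined by 30-second linear cross-fades of mean
#' and sd (the exponent switches at the boundary, so each analysis window has
#' a well-defined approximate true exponent). Mean RR must be non-increasing
#' across segments, emulating the rise in heart rate over a ramp; sd shrinking
#' with intensity mimics vagal withdrawal.
#'
#' @param segments data frame with columns `length_s`, `H`, `mean_rr_ms`,
#'   `rr_sd_ms`, one row per segment in order.
#' @param seed default seed used by [generate_exercise_ramp()].
#' @param fade_s cross-fade length at interior boundaries, seconds.
#' @param jitter_ms sd of additional white measurement jitter added to every
#'   interval (default 0).
#' @param power_w optional length-2 numeric: external power ramped linearly
#'   from `power_w[1]` to `power_w[2]` over the recording, attached as a 1-Hz
#'   channel.
#' @param name scenario label.
#' @return a `ramp_spec` list; `duration_s` is the sum of segment lengths.
#' @export
ramp_spec <- function(segments, seed = 1L, fade_s = 30, jitter_ms = 0,
                      power_w = NULL, name = "ramp") {
  stopifnot(is.data.frame(segments),
            all(c("length_s", "H", "mean_rr_ms", "rr_sd_ms") %in% names(segments)),
            nrow(segments) >= 1L, all(segments$length_s > 0),
            all(segments$H > 0 & segments$H < 1.5),
            all(diff(segments$mean_rr_ms) <= 0),
            all(segments$rr_sd_ms > 0))
  structure(list(segments = segments, duration_s = sum(segments$length_s),
                 seed = as.integer(seed), fade_s = fade_s,
                 jitter_ms = jitter_ms, power_w = power_w, name = name),
            class = "ramp_spec")
}

# piecewise-constant segment parameter with linear cross-fades at interior
# boundaries; vectorised over t
.ramp_param <- function(spec, values, t) {
  b <- cumsum(spec$segments$length_s)       # interior boundaries b[1..k-1]
  k <- length(values)
  out <- values[pmin(findInterval(t, c(0, b[-k]), rightmost.closed = FALSE), k)]
  if (k > 1L && spec$fade_s > 0) {
    half <- spec$fade_s / 2
    for (j in seq_len(k - 1L)) {
      sel <- t > b[j] - half & t < b[j] + half
      if (any(sel)) {
        frac <- (t[sel] - (b[j] - half)) / spec$fade_s
        out[sel] <- values[j] + frac * (values[j + 1L] - values[j])
      }
    }
  }
  out
}

# first time the (descending) trajectory crosses `target`, by fine sampling +
# linear interpolation; NA when never reached
.first_crossing_time <- function(spec, values, target) {
  tt <- seq(0, spec$duration_s, by = 0.1)
  v <- .ramp_param(spec, values, tt)
  below <- which(v <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(tt[1L])
  tt[i - 1L] + 0.1 * (v[i - 1L] - target) / (v[i - 1L] - v[i])
}

#' Generate a synthetic exercise ramp with planted thresholds
#'
#' Realises a [ramp_spec()] as an RR series: per segment an fGn stream with the
#' segment's target exponent is drawn, scaled to the local sd and shifted to
#' the local mean (both cross-faded at boundaries), and beats are laid down
#' sequentially until the specified duration is covered. The truth log records
#' the programmed exponent and mean-RR trajectories and the heart rates at
#' which the exponent trajectory first crosses 0.75 and 0.5 — the planted
#' HRVT and HRVT2 an estimator should recover.
#'
#' @param spec a [ramp_spec()].
#' @param seed integer seed; defaults to the spec's own.
#' @return list with `series` (an [rr_series()]) and `truth` (list:
#'   `trajectory` data frame sampled at 1 s with `time_s`, `alpha_true`,
#'   `mean_rr_ms`, `hr_bpm`; `hrvt_hr`, `hrvt2_hr`, `hrvt_time_s`,
#'   `hrvt2_time_s`; the spec).
#' @export
generate_exercise_ramp <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ramp_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(as.integer(seed))
  seg <- spec$segments
  k <- nrow(seg)
  b <- cumsum(seg$length_s)
  # one fGn stream per segment, sized generously for its fastest beat rate
  streams <- lapply(seq_len(k), function(j) {
    n_j <- ceiling(1.6 * seg$length_s[j] / (min(seg$mean_rr_ms) / 1000)) + 64L
    generate_fgn(max(n_j, 16L), seg$H[j])
  })
  used <- integer(k)
  rr <- numeric(0)
  t <- 0
  while (t < spec$duration_s) {
    j <- min(findInterval(t, c(0, b[-k]), rightmost.closed = FALSE), k)
    used[j] <- used[j] + 1L
    if (used[j] > length(streams[[j]])) {    # exceedingly slow beats; extend
      streams[[j]] <- c(streams[[j]], generate_fgn(256L, seg$H[j]))
    }
    x <- streams[[j]][used[j]]
    m <- .ramp_param(spec, seg$mean_rr_ms, t)
    s <- .ramp_param(spec, seg$rr_sd_ms, t)
    r <- m + s * x
    if (spec$jitter_ms > 0) r <- r + stats::rnorm(1L, sd = spec$jitter_ms)
    r <- min(max(r, 250), 2500)
    rr <- c(rr, r)
    t <- t + r / 1000
  }
  channels <- NULL
  if (!is.null(spec$power_w)) {
    ts <- seq(0, spec$duration_s, by = 1)
    channels <- data.frame(
      time_s = ts,
      power_w = spec$power_w[1L] + (spec$power_w[2L] - spec$power_w[1L]) *
        ts / spec$duration_s)
  }
  series <- suppressWarnings(
    rr_series(rr, channels = channels,
              meta = sprintf("synthetic ramp '%s' (seed %d)", spec$name, seed)))
  ts <- seq(0, spec$duration_s, by = 1)
  mrr <- .ramp_param(spec, seg$mean_rr_ms, ts)
  trajectory <- data.frame(time_s = ts,
                           alpha_true = .ramp_param(spec, seg$H, ts),
                           mean_rr_ms = mrr, hr_bpm = 60000 / mrr)
  t075 <- .first_crossing_time(spec, seg$H, 0.75)
  t05 <- .first_crossing_time(spec, seg$H, 0.5)
  hr_at <- function(tc) if (is.na(tc)) NA_real_ else
    60000 / .ramp_param(spec, seg$mean_rr_ms, tc)
  list(series = series,
       truth = list(trajectory = trajectory,
                    hrvt_hr = hr_at(t075), hrvt2_hr = hr_at(t05),
                    hrvt_time_s = t075, hrvt2_time_s = t05, spec = spec))
}

#' Built-in synthetic scenarios
#'
#' A catalogue of named [ramp_spec()]s covering the qualitative regimes of
#' alpha1 during exercise:
#' \describe{
#'   \item{clean_ramp}{20-min incremental ramp, exponent 1.1 at rest falling
#'     to 0.3 at peak (through the correlated, transition and anticorrelated
#'     zones), mean RR 850 to 330 ms, RR sd shrinking 40 to 3 ms; linear
#'     power 50 to 350 W attached.}
#'   \item{noisy_ramp}{the same trajectories with 1.75-fold RR variability and
#'     3 ms white measurement jitter.}
#'   \item{steady_low}{10 min of constant low-intensity exercise with high,
#'     well-correlated alpha (H = 1.05) — no threshold crossing.}
#'   \item{anticorrelated_floor}{10 min of severe-intensity anticorrelated
#'     beats (H = 0.3) at high heart rate.}
#' }
#'
#' @return named list of `ramp_spec` objects.
#' @export
hrv_scenarios <- function() {
  # heart rate rises linearly over an incremental ramp, so mean RR follows the
  # harmonic spacing 60000/HR; with the exponent also linear per stage this
  # reproduces the near-straight alpha1-vs-HR drop seen in ramp tests.
  # 30-s stages with 30-s fades make the programmed trajectory continuous
  # piecewise-linear, so the planted level crossings are unambiguous.
  ramp_segments <- data.frame(
    length_s = rep(30, 40),
    H = seq(1.1, 0.3, length.out = 40),
    mean_rr_ms = 60000 / seq(60000 / 850, 60000 / 330, length.out = 40),
    rr_sd_ms = exp(seq(log(40), log(3), length.out = 40)))
  noisy <- ramp_segments
  noisy$rr_sd_ms <- noisy$rr_sd_ms * 1.75
  list(
    clean_ramp = ramp_spec(ramp_segments, seed = 101L, power_w = c(50, 350),
                           name = "clean_ramp"),
    noisy_ramp = ramp_spec(noisy, seed = 202L, jitter_ms = 3,
                           power_w = c(50, 350), name = "noisy_ramp"),
    steady_low = ramp_spec(
      data.frame(length_s = 600, H = 1.05, mean_rr_ms = 850, rr_sd_ms = 40),
      seed = 303L, name = "steady_low"),
    anticorrelated_floor = ramp_spec(
      data.frame(length_s = 600, H = 0.3, mean_rr_ms = 400, rr_sd_ms = 8),
      seed = 404L, name = "anticorrelated_floor"))
}
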