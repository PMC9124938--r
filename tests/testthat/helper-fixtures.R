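# fixtures are built in code; no data files

# iid Gaussian RR series (uncorrelated beats)
make_iid_series <- function(n = 1000, mean_ms = 800, sd_ms = 30, seed = 1) {
  set.seed(seed)
  suppressWarnings(rr_series(stats::rnorm(n, mean_ms, sd_ms)))
}

# alpha series lying exactly on a line in HR: alpha a0 at hr0 declining to a1
# at hr1, on a 5-s grid
make_linear_alpha <- function(a0 = 1.0, a1 = 0.4, hr0 = 120, hr1 = 180,
                              n = 121, t0 = 120, grid = 5) {
  hr <- seq(hr0, hr1, length.out = n)
  df <- data.frame(window_end_s = t0 + grid * (seq_len(n) - 1L),
                   alpha1 = a0 + (hr - hr0) * (a1 - a0) / (hr1 - hr0),
                   hr_bpm = hr, power_w = NA_real_, artifact_pct = 0,
                   valid = TRUE)
  class(df) <- c("alpha_series", "data.frame")
  df
}

# a short incremental ramp for experiment-level tests (cheap to analyse)
short_ramp_spec <- function(seed = 11L) {
  seg <- data.frame(length_s = rep(30, 16),
                    H = seq(1.05, 0.35, length.out = 16),
                    mean_rr_ms = 60000 / seq(60000 / 800, 60000 / 360,
                                             length.out = 16),
                    rr_sd_ms = exp(seq(log(35), log(4), length.out = 16)))
  ramp_spec(seg, seed = seed, name = "short_ramp")
}
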