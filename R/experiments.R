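#' Artifact-injection bias experiment
#'
#' Quantifies the bias that missed-beat artifact plus correction induces in
#' the rolling alpha1 series. For each seed a clean synthetic ramp is
#' generated and analysed (control arm); missed beats are then injected at
#' each requested level, detected and corrected with each requested method,
#' and the degraded series is re-analysed. Windows are matched between arms by
#' window end time on the shared grid (windows invalid in either arm are
#' dropped pairwise); per-window bias is degraded minus control alpha1 and
#' proportional bias is bias over control.
#'
#' @param spec a [ramp_spec()] (e.g. from [hrv_scenarios()]).
#' @param levels artifact percentages to inject, each in (0, 20].
#' @param methods subset of `c("threshold_medium", "automatic")`.
#' @param seeds integer vector of seeds (one clean/degraded pair per seed).
#' @param config [dfa_config()] for the rolling analysis; by default the
#'   5\% artifact QC screen is lifted (`max_artifact_pct = 100`), since the
#'   experiment deliberately pushes windows past the field-quality limit.
#' @return a `bias_table` data frame, one row per level x method:
#'   `level_pct`, `method`, `mean_bias` (mean alpha1 bias over windows and
#'   seeds), `mean_abs_bias`, `max_prop_bias_pct` (largest \eqn{|bias/control|}
#'   in percent, median over seeds of each seed's maximum),
#'   `prop_bias_low_alpha` / `prop_bias_high_alpha` (mean proportional bias on
#'   windows with control alpha1 < 0.5 and > 1.0), `n_windows`, `n_seeds`.
#'   The per-window records are attached as attribute `"windows"`.
#' @export
artifact_bias_experiment <- function(spec,
                                     levels = c(1, 3, 6),
                                     methods = c("threshold_medium", "automatic"),
                                     seeds = 1:10,
                                     config = dfa_config(max_artifact_pct = 100)) {
  stopifnot(inherits(spec, "ramp_spec"), all(levels > 0 & levels <= 20))
  methods <- match.arg(methods, c("threshold_medium", "automatic"),
                       several.ok = TRUE)
  recs <- list()
  for (s in seeds) {
    ramp <- generate_exercise_ramp(spec, seed = s)
    control <- alpha1_rolling(ramp$series, config)
    for (lv in levels) {
      inj <- inject_missed_beats(ramp$series, lv, seed = s * 1000L + round(lv))
      for (me in methods) {
        rep_ <- if (me == "threshold_medium") {
          detect_artifacts(inj$series, "threshold", level = "medium")
        } else {
          detect_artifacts(inj$series, "automatic")
        }
        corr <- correct_artifacts(inj$series, rep_)
        degraded <- alpha1_rolling(corr, config)
        m <- merge(control[control$valid, c("window_end_s", "alpha1")],
                   degraded[degraded$valid, c("window_end_s", "alpha1")],
                   by = "window_end_s", suffixes = c("_ctl", "_deg"))
        if (nrow(m) == 0L) next
        recs[[length(recs) + 1L]] <- data.frame(
          seed = s, level_pct = lv, method = me,
          window_end_s = m$window_end_s, control = m$alpha1_ctl,
          bias = m$alpha1_deg - m$alpha1_ctl,
          prop = (m$alpha1_deg - m$alpha1_ctl) / m$alpha1_ctl)
      }
    }
  }
  win <- do.call(rbind, recs)
  rows <- lapply(split(win, list(win$level_pct, win$method), drop = TRUE),
                 function(d) {
    max_by_seed <- tapply(abs(d$prop), d$seed, max)
    data.frame(
      level_pct = d$level_pct[1L], method = d$method[1L],
      mean_bias = mean(d$bias), mean_abs_bias = mean(abs(d$bias)),
      max_prop_bias_pct = 100 * stats::median(max_by_seed),
      prop_bias_low_alpha = mean(d$prop[d$control < 0.5]),
      prop_bias_high_alpha = mean(d$prop[d$control > 1.0]),
      n_windows = nrow(d), n_seeds = length(unique(d$seed)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$level_pct), ]
  rownames(out) <- NULL
  attr(out, "windows") <- win
  class(out) <- c("bias_table", "data.frame")
  out
}

#' HRVT robustness to missed-beat artifact
#'
#' Measures how far the estimated HRVT heart rate moves when a synthetic ramp
#' with a planted threshold is degraded by missed-beat injection and then
#' corrected: per seed, level and method the shift is HRVT HR on the
#' degraded-corrected series minus HRVT HR on the control series. Seeds in
#' which either arm fails to cross the target are excluded and counted.
#'
#' @inheritParams artifact_bias_experiment
#' @param target alpha1 threshold value (default 0.75, the HRVT).
#' @return data frame, one row per level x method: `level_pct`, `method`,
#'   `median_shift`, `median_abs_shift`, `iqr_shift`, `max_abs_shift` (bpm),
#'   `n_seeds`, `n_excluded`. Per-seed shifts attached as attribute
#'   `"shifts"`.
#' @export
hrvt_robustness <- function(spec, levels = c(1, 3, 6),
                            methods = c("threshold_medium", "automatic"),
                            seeds = 1:10, target = 0.75,
                            config = dfa_config(max_artifact_pct = 100)) {
  stopifnot(inherits(spec, "ramp_spec"))
  methods <- match.arg(methods, c("threshold_medium", "automatic"),
                       several.ok = TRUE)
  shifts <- list()
  for (s in seeds) {
    ramp <- generate_exercise_ramp(spec, seed = s)
    control <- alpha1_rolling(ramp$series, config)
    hr_ctl <- tryCatch(
      estimate_threshold(control, "hr", target)$row$hr, error = function(e) NA)
    for (lv in levels) {
      inj <- inject_missed_beats(ramp$series, lv, seed = s * 1000L + round(lv))
      for (me in methods) {
        rep_ <- if (me == "threshold_medium") {
          detect_artifacts(inj$series, "threshold", level = "medium")
        } else {
          detect_artifacts(inj$series, "automatic")
        }
        corr <- correct_artifacts(inj$series, rep_)
        degraded <- alpha1_rolling(corr, config)
        hr_deg <- tryCatch(
          estimate_threshold(degraded, "hr", target)$row$hr,
          error = function(e) NA)
        shifts[[length(shifts) + 1L]] <- data.frame(
          seed = s, level_pct = lv, method = me,
          shift = hr_deg - hr_ctl, excluded = is.na(hr_deg) || is.na(hr_ctl))
      }
    }
  }
  sh <- do.call(rbind, shifts)
  rows <- lapply(split(sh, list(sh$level_pct, sh$method), drop = TRUE),
                 function(d) {
    v <- d$shift[!d$excluded]
    data.frame(level_pct = d$level_pct[1L], method = d$method[1L],
               median_shift = stats::median(v),
               median_abs_shift = stats::median(abs(v)),
               iqr_shift = stats::IQR(v), max_abs_shift = max(abs(v)),
               n_seeds = length(v), n_excluded = sum(d$excluded))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$level_pct), ]
  rownames(out) <- NULL
  attr(out, "shifts") <- sh
  out
}
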