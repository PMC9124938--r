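#' Construct an RR-interval series
#'
#' An `rr_series` holds an ordered sequence of beat-to-beat RR intervals in
#' milliseconds together with the derived beat times. The time base follows the
#' causal convention used by real-time analysis tools: each interval is stamped
#' at its END, so the series starts at `t = rr[1]/1000` seconds and the total
#' recording duration equals `sum(rr)/1000` exactly.
#'
#' @param rr numeric vector of RR intervals in milliseconds; all positive,
#'   length at least 2.
#' @param channels optional `data.frame` with a `time_s` column and aligned
#'   external-load columns (`power_w`, `speed_ms`), nominally sampled at 1 Hz.
#'   Channel values at beat or window times are looked up by nearest neighbour.
#' @param meta free-form character description of the source.
#' @param corrected optional logical vector marking intervals produced by
#'   artifact correction (used for per-window artifact percentages).
#'
#' @return An object of class `rr_series`: a list with elements `rr` (ms),
#'   `t` (beat times, s), `channels`, `meta` and `corrected`.
#'
#' @details Intervals outside the broadly physiological range 200--2500 ms are
#'   accepted with a warning; gating and correction are the job of
#'   [detect_artifacts()] and [correct_artifacts()], not the constructor.
#'
#' @examples
#' x <- rr_series(c(1000, 990, 1010, 1000))
#' x$t                # 1.00 1.99 3.00 4.00
#' duration(x)        # 4 s
#' @export
rr_series <- function(rr, channels = NULL, meta = "", corrected = NULL) {
  rr <- as.numeric(rr)
  if (length(rr) < 2L) {
    stop("an rr_series needs at least 2 intervals, got ", length(rr))
  }
  if (anyNA(rr) || any(rr <= 0)) {
    stop("all RR intervals must be positive and non-missing")
  }
  n_out <- sum(rr < 200 | rr > 2500)
  if (n_out > 0L) {
    warning(n_out, " interval(s) outside 200-2500 ms; kept (see detect_artifacts)")
  }
  if (!is.null(channels)) {
    if (!is.data.frame(channels) || !"time_s" %in% names(channels)) {
      stop("channels must be a data.frame with a 'time_s' column")
    }
  }
  if (is.null(corrected)) corrected <- rep(FALSE, length(rr))
  stopifnot(length(corrected) == length(rr))
  structure(
    list(rr = rr, t = cumsum(rr) / 1000, channels = channels,
         meta = as.character(meta)[1L], corrected = as.logical(corrected)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("rr_series: %d beats, %.1f s, mean RR %.0f ms (mean HR %.1f bpm)\n",
              length(x$rr), duration(x), mean(x$rr), 60000 / mean(x$rr)))
  if (!is.null(x$channels)) {
    cat("  channels:", paste(setdiff(names(x$channels), "time_s"), collapse = ", "), "\n")
  }
  if (any(x$corrected)) {
    cat(sprintf("  corrected beats: %d (%.1f%%)\n", sum(x$corrected),
                100 * mean(x$corrected)))
  }
  if (nzchar(x$meta)) cat("  source:", x$meta, "\n")
  invisible(x)
}

#' Total recording duration of an RR series
#'
#' @param x an [rr_series()].
#' @return duration in seconds, equal to `sum(x$rr)/1000`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  sum(x$rr) / 1000
}

#' Read RR intervals from a plain-text export
#'
#' Parses the one-interval-per-line dialect used by consumer heart-rate-monitor
#' exports (e.g. chest-strap logger apps): UTF-8 text, one numeric interval per
#' line, blank lines ignored, comment lines starting with `#` ignored.
#'
#' @param path file to read.
#' @param unit `"ms"` (default) or `"s"`; seconds are converted to ms.
#' @return an [rr_series()] with beat times rebuilt from zero.
#' @export
read_rr_text <- function(path, unit = c("ms", "s")) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("non-numeric RR value at line ", bad, " of '", path, "'")
  }
  if (any(vals <= 0)) {
    bad <- which(keep)[which(vals <= 0)[1L]]
    stop("non-positive RR interval at line ", bad, " of '", path, "'")
  }
  if (unit == "s") vals <- vals * 1000
  rr_series(vals, meta = path)
}

#' Read an RR recording from CSV
#'
#' Reads a header-rowed CSV holding an RR column in milliseconds and optional
#' timestamp and power columns. When a timestamp column is present it is
#' checked against the cumulative-RR time base; if total durations disagree by
#' more than 1\% a warning is issued and cumulative RR wins (beat times are
#' always rebuilt from the intervals).
#'
#' @param path file to read.
#' @param columns named character vector mapping roles to CSV header names;
#'   roles are `rr` (mandatory), `time` and `power` (optional). Default
#'   `c(rr = "rr_ms", time = "time_s", power = "power_w")`.
#' @return an [rr_series()]; if a power column is present it is attached as a
#'   1-Hz aligned channel.
#' @export
read_rr_csv <- function(path,
                        columns = c(rr = "rr_ms", time = "time_s", power = "power_w")) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"rr" %in% names(columns) || !columns[["rr"]] %in% names(df)) {
    stop("CSV '", path, "' is missing the mandatory RR column '",
         if ("rr" %in% names(columns)) columns[["rr"]] else "rr", "'")
  }
  rr <- as.numeric(df[[columns[["rr"]]]])
  t_cum <- cumsum(rr) / 1000
  if ("time" %in% names(columns) && columns[["time"]] %in% names(df)) {
    ts <- as.numeric(df[[columns[["time"]]]])
    span_ts <- max(ts) - min(ts)
    span_rr <- t_cum[length(t_cum)] - t_cum[1L]
    if (span_rr > 0 && abs(span_ts - span_rr) > 0.01 * span_rr) {
      warning("timestamp span disagrees with cumulative RR by more than 1%; ",
              "using cumulative RR time base")
    }
  }
  channels <- NULL
  if ("power" %in% names(columns) && columns[["power"]] %in% names(df)) {
    channels <- data.frame(time_s = t_cum, power_w = as.numeric(df[[columns[["power"]]]]))
  }
  rr_series(rr, channels = channels, meta = path)
}

#' Write an RR series as plain text
#'
#' One interval (ms) per line, the inverse of [read_rr_text()].
#'
#' @param x an [rr_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(x, path) {
  stopifnot(inherits(x, "rr_series"))
  writeLines(format(x$rr, trim = TRUE, scientific = FALSE, digits = 15), path)
  invisible(path)
}

#' Instantaneous heart rate on a time grid
#'
#' HR at time `t` is `60000 / mean(rr)` over the beats whose end times fall in
#' `(t - window_s, t]` — the reciprocal of the mean interval in a trailing
#' window, in beats per minute.
#'
#' @param x an [rr_series()].
#' @param window_s trailing window width in seconds (> 0).
#' @param times evaluation times in seconds; default a 1-s grid over the
#'   recording.
#' @return `data.frame` with `time_s`, `hr_bpm` and `valid` (FALSE where the
#'   window holds no beats; `hr_bpm` is NA there).
#' @export
instantaneous_hr <- function(x, window_s, times = NULL) {
  stopifnot(inherits(x, "rr_series"), window_s > 0)
  if (is.null(times)) times <- seq(ceiling(x$t[1L]), floor(duration(x)), by = 1)
  hr <- vapply(times, function(tt) {
    sel <- x$t > tt - window_s & x$t <= tt
    if (!any(sel)) return(NA_real_)
    60000 / mean(x$rr[sel])
  }, numeric(1))
  data.frame(time_s = times, hr_bpm = hr, valid = !is.na(hr))
}

# nearest-neighbour lookup of a 1-Hz channel value at arbitrary times
channel_at <- function(channels, column, times) {
  if (is.null(channels) || !column %in% names(channels)) {
    return(rep(NA_real_, length(times)))
  }
  idx <- vapply(times, function(tt) which.min(abs(channels$time_s - tt)), integer(1))
  channels[[column]][idx]
}

#' Write and read a rolling alpha1 series as CSV
#'
#' The CSV schema is `window_end_s, alpha1, hr_bpm, power_w, artifact_pct,
#' valid`, with alpha1 rounded to 3 decimals and HR to 1, so a
#' write-then-read round trip is lossless at those stated precisions.
#'
#' @param alpha an `alpha_series` as returned by [alpha1_rolling()].
#' @param path output (input) file.
#' @return `write_alpha_csv()` returns `path` invisibly; `read_alpha_csv()`
#'   returns an `alpha_series` data frame.
#' @export
write_alpha_csv <- function(alpha, path) {
  stopifnot(is.data.frame(alpha))
  if (nrow(alpha) == 0L) warning("writing an empty alpha series (header only)")
  out <- data.frame(
    window_end_s = alpha$window_end_s,
    alpha1       = round(alpha$alpha1, 3),
    hr_bpm       = round(alpha$hr_bpm, 1),
    power_w      = if ("power_w" %in% names(alpha)) round(alpha$power_w, 1) else NA_real_,
    artifact_pct = round(alpha$artifact_pct, 2),
    valid        = alpha$valid
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alpha_csv
#' @export
read_alpha_csv <- function(path) {
  df <- utils::read.csv(path)
  df$valid <- as.logical(df$valid)
  class(df) <- c("alpha_series", "data.frame")
  df
}

#' Write a threshold fit as JSON
#'
#' Serialises every field of the threshold estimates of an [hrvt()] fit (or a
#' single estimate) to JSON; numbers are written unrounded.
#'
#' @param x an `hrvt` fit or the `data.frame` of its `$estimates`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(x, path) {
  if (inherits(x, "hrvt")) x <- x$estimates
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
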