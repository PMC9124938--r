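#' Estimate heart-rate-variability thresholds from an alpha1 series
#'
#' Fits the decline of the short-term DFA scaling exponent alpha1 against a
#' predictor (heart rate, time or power) over an incremental ramp and solves
#' for the intensities at which alpha1 crosses its threshold values: 0.75
#' (HRVT, a surrogate for the first ventilatory/lactate threshold) and 0.5
#' (HRVT2, a surrogate for the second).
#'
#' The default estimator fits ordinary least squares of alpha1 on the
#' predictor over the valid windows whose alpha1 lies in the regression band
#' (default \[0.4, 1.0\], excluding the pre-ramp correlated plateau and the
#' anticorrelated floor) inside the analysis bounds, then solves
#' `predictor = (target - intercept) / slope`. The in-band set is taken as the
#' contiguous run of windows between the smoothed trace's entry into and exit
#' from the band, so that window-level estimation noise at the band edges
#' cannot truncate asymmetrically and dilute the slope. When the fit is poor
#' (`r2 < 0.5`) or the slope is not negative, it falls back to first-crossing
#' linear interpolation on the 4-point moving average of the alpha trace, with
#' a QC flag. If the (smoothed) alpha trace never reaches a target, that
#' estimate carries a `no_crossing` flag and no value. When both targets are
#' estimated in HR terms, the ordering HRVT2 HR >= HRVT HR is checked and both
#' are flagged `inconsistent` when violated.
#'
#' @param object an [rr_series()] (the rolling alpha series is computed first
#'   with `config`) or an `alpha_series` from [alpha1_rolling()].
#' @param predictor `"hr"` (default), `"time"` or `"power"`.
#' @param targets named numeric vector of alpha1 threshold values
#'   (default `c(hrvt = 0.75, hrvt2 = 0.5)`).
#' @param bounds optional length-2 numeric, analysis window `[from, to]` in
#'   seconds of window end time, used to exclude warm-up and cool-down;
#'   default the full recording.
#' @param band regression band on alpha1, default `c(0.4, 1.0)`.
#' @param ma_k moving-average length for the fallback interpolation
#'   (default 4).
#' @param config [dfa_config()] used when `object` is an `rr_series`.
#' @param ... unused.
#' @return an object of class `hrvt`: list with `estimates` (data frame, one
#'   row per target: `target`, `value` — the predictor at the crossing —,
#'   `hr`, `time_s`, `power`, `method`, `slope`, `intercept`, `r2`,
#'   `n_windows`, `qc`), `alpha` (the alpha series used), `predictor`, `fit`
#'   (the underlying `lm`), `band`, `bounds` and `call`. Methods:
#'   [print.hrvt()], [summary.hrvt()], [coef.hrvt()], [predict.hrvt()],
#'   [plot.hrvt()], [residuals.hrvt()].
#' @examples
#' ramp <- generate_exercise_ramp(hrv_scenarios()$clean_ramp)
#' fit <- hrvt(ramp$series)
#' coef(fit)      # HR at alpha1 = 0.75 and 0.5
#' @export
hrvt <- function(object, ...) UseMethod("hrvt")

#' @rdname hrvt
#' @export
hrvt.rr_series <- function(object, predictor = c("hr", "time", "power"),
                           targets = c(hrvt = 0.75, hrvt2 = 0.5),
                           bounds = NULL, band = c(0.4, 1.0), ma_k = 4L,
                           config = dfa_config(), ...) {
  alpha <- alpha1_rolling(object, config)
  out <- hrvt.alpha_series(alpha, predictor = predictor, targets = targets,
                           bounds = bounds, band = band, ma_k = ma_k)
  out$call <- match.call()
  out
}

#' @rdname hrvt
#' @export
hrvt.alpha_series <- function(object, predictor = c("hr", "time", "power"),
                              targets = c(hrvt = 0.75, hrvt2 = 0.5),
                              bounds = NULL, band = c(0.4, 1.0), ma_k = 4L,
                              ...) {
  predictor <- match.arg(predictor)
  stopifnot(all(targets > 0 & targets < 2))
  if (is.null(names(targets))) names(targets) <- paste0("target", seq_along(targets))
  est <- lapply(seq_along(targets), function(i) {
    estimate_threshold(object, predictor = predictor, target = targets[[i]],
                       bounds = bounds, band = band, ma_k = ma_k)
  })
  estimates <- do.call(rbind, lapply(est, function(e) e$row))
  estimates$name <- names(targets)
  # ordering QC in HR terms: the lower alpha target must come at higher HR
  if (all(c(0.75, 0.5) %in% round(estimates$target, 6))) {
    h1 <- estimates$hr[match(0.75, round(estimates$target, 6))]
    h2 <- estimates$hr[match(0.5, round(estimates$target, 6))]
    if (!is.na(h1) && !is.na(h2) && h2 < h1) {
      estimates$qc <- paste0(estimates$qc, ";inconsistent_order")
    }
  }
  estimates$qc <- sub("^;", "", estimates$qc)
  structure(list(estimates = estimates, alpha = object, predictor = predictor,
                 fit = est[[1L]]$fit, band = band,
                 bounds = est[[1L]]$bounds, targets = targets,
                 call = match.call()),
            class = "hrvt")
}

# one-target estimator; returns list(row = 1-row data.frame, fit, bounds)
estimate_threshold <- function(alpha, predictor = "hr", target = 0.75,
                               bounds = NULL, band = c(0.4, 1.0), ma_k = 4L) {
  stopifnot(is.data.frame(alpha))
  if (is.null(bounds)) bounds <- c(-Inf, Inf)
  pcol <- switch(predictor, hr = "hr_bpm", time = "window_end_s",
                 power = "power_w")
  inb <- alpha$window_end_s >= bounds[1L] & alpha$window_end_s <= bounds[2L]
  ok <- alpha$valid & inb & !is.na(alpha[[pcol]]) & !is.na(alpha$alpha1)
  n_ok <- sum(ok)
  if (n_ok < 5L) {
    stop("need at least 5 valid windows inside bounds, have ", n_ok)
  }
  x_all <- alpha[[pcol]][ok]
  y_all <- alpha$alpha1[ok]
  t_all <- alpha$window_end_s[ok]
  qc <- character(0)
  # smoothed trace (trailing ma_k-point mean), in time order
  ord <- order(t_all)
  ys <- y_all[ord]
  k <- as.integer(ma_k)
  ysm <- vapply(seq_along(ys), function(i) mean(ys[max(1L, i - k + 1L):i]),
                numeric(1))
  xsm <- x_all[ord]
  # regression windows: the contiguous run from where the smoothed trace first
  # drops to the band ceiling until it falls below the band floor. Selecting a
  # time segment from the smoothed trajectory, rather than thresholding the
  # noisy per-window estimates, avoids the edge-truncation bias that would
  # otherwise flatten the fitted slope at both band limits.
  i1 <- which(ysm <= band[2L])[1L]
  i2 <- which(ysm < band[1L])[1L]
  i2 <- if (is.na(i2)) length(ysm) else max(i2 - 1L, 1L)
  sel <- if (is.na(i1) || i1 > i2) integer(0) else i1:i2
  fit <- NULL; slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  if (length(sel) >= 5L) {
    fit <- stats::lm(y ~ x, data = data.frame(x = xsm[sel], y = ys[sel]))
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
  }
  crosses <- min(ysm) <= target
  value <- NA_real_
  method <- NA_character_
  if (!crosses) {
    qc <- c(qc, "no_crossing")
  } else if (!is.null(fit) && !is.na(r2) && r2 >= 0.5 && slope < 0) {
    method <- "regression"
    value <- (target - intercept) / slope
  } else {
    method <- "first_crossing"
    qc <- c(qc, if (is.null(fit)) "too_few_in_band" else "poor_fit")
    br <- which(ysm[-length(ysm)] > target & ysm[-1L] <= target)
    if (!length(br)) {
      # trace starts at/below target: take the first point
      value <- xsm[which(ysm <= target)[1L]]
    } else {
      i <- br[1L]
      f <- (ysm[i] - target) / (ysm[i] - ysm[i + 1L])
      value <- xsm[i] + f * (xsm[i + 1L] - xsm[i])
      if (length(br) > 1L) qc <- c(qc, "multiple_crossings")
    }
  }
  # express the crossing in the other coordinates by interpolation in time
  to_coord <- function(col) {
    v <- alpha[[col]][ok][ord]
    if (all(is.na(v)) || is.na(value)) return(NA_real_)
    stats::approx(xsm, v, xout = value, ties = mean, rule = 2)$y
  }
  hr <- time_s <- power <- NA_real_
  if (!is.na(value)) {
    hr <- if (pcol == "hr_bpm") value else to_coord("hr_bpm")
    time_s <- if (pcol == "window_end_s") value else to_coord("window_end_s")
    power <- if (pcol == "power_w") value else to_coord("power_w")
  }
  row <- data.frame(target = target, value = value, hr = hr, time_s = time_s,
                    power = power, predictor = predictor, method = method,
                    slope = slope, intercept = intercept, r2 = r2,
                    n_windows = n_ok,
                    qc = paste(qc, collapse = ";"), stringsAsFactors = FALSE)
  list(row = row, fit = fit, bounds = bounds)
}

#' Alpha1 drift under constant load
#'
#' Quantifies the downward drift of alpha1 over a bounded segment of constant
#' external load — the minimal support for durability and fatigue inspection:
#' a fading athlete shows declining alpha1 at stable pace or power.
#'
#' @param alpha an `alpha_series`.
#' @param bounds length-2 numeric, segment `[from, to]` in seconds of window
#'   end time; default the full series.
#' @return list with `slope_per_h` (OLS slope of alpha1 on time, per hour),
#'   `mean_alpha1`, `mean_hr`, `mean_power`, `n_windows`.
#' @export
load_drift <- function(alpha, bounds = NULL) {
  stopifnot(is.data.frame(alpha))
  if (is.null(bounds)) bounds <- c(-Inf, Inf)
  ok <- alpha$valid & alpha$window_end_s >= bounds[1L] &
    alpha$window_end_s <= bounds[2L] & !is.na(alpha$alpha1)
  if (sum(ok) < 10L) stop("need at least 10 valid windows in bounds, have ", sum(ok))
  tt <- alpha$window_end_s[ok] / 3600
  fit <- stats::lsfit(tt, alpha$alpha1[ok])
  list(slope_per_h = unname(fit$coefficients[2L]),
       mean_alpha1 = mean(alpha$alpha1[ok]),
       mean_hr = mean(alpha$hr_bpm[ok], na.rm = TRUE),
       mean_power = mean(alpha$power_w[ok], na.rm = TRUE),
       n_windows = sum(ok))
}

#' @export
print.hrvt <- function(x, ...) {
  cat("Heart-rate-variability thresholds (DFA alpha1)\n")
  cat(sprintf("  predictor: %s; %d windows; regression band alpha1 [%.2f, %.2f]\n",
              x$predictor, x$estimates$n_windows[1L], x$band[1L], x$band[2L]))
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    lab <- toupper(e$name)
    if (nzchar(e$qc) && grepl("no_crossing", e$qc)) {
      cat(sprintf("  %s (alpha1 = %.2f): not reached [%s]\n", lab, e$target, e$qc))
    } else {
      unit <- switch(x$predictor, hr = "bpm", time = "s", power = "W")
      cat(sprintf("  %s (alpha1 = %.2f): %.1f %s (HR %.1f bpm, t %.0f s)%s\n",
                  lab, e$target, e$value, unit, e$hr, e$time_s,
                  if (nzchar(e$qc)) paste0(" [", e$qc, "]") else ""))
    }
  }
  invisible(x)
}

#' @export
summary.hrvt <- function(object, ...) {
  structure(list(fit = object), class = "summary.hrvt")
}

#' @export
print.summary.hrvt <- function(x, ...) {
  print(x$fit)
  e <- x$fit$estimates[1L, ]
  if (!is.na(e$slope)) {
    cat(sprintf("  regression: alpha1 = %.4f %+.5f x %s, r2 = %.3f\n",
                e$intercept, e$slope, x$fit$predictor, e$r2))
  }
  a <- x$fit$alpha
  cat(sprintf("  windows: %d total, %d valid; mean artifact %.2f%%\n",
              nrow(a), sum(a$valid), mean(a$artifact_pct, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.hrvt <- function(object, ...) {
  stats::setNames(object$estimates$value, object$estimates$name)
}

#' Predicted alpha1 at new predictor values
#'
#' Evaluates the fitted alpha1-on-predictor regression line.
#'
#' @param object an `hrvt` fit (must have a regression component).
#' @param newdata numeric vector of predictor values (HR in bpm, time in s or
#'   power in W, matching the fit's predictor); default the observed values.
#' @param ... unused.
#' @return numeric vector of predicted alpha1.
#' @export
predict.hrvt <- function(object, newdata = NULL, ...) {
  if (is.null(object$fit)) stop("fit has no regression component")
  if (is.null(newdata)) return(unname(stats::fitted(object$fit)))
  unname(stats::predict(object$fit, data.frame(x = as.numeric(newdata))))
}

#' @export
residuals.hrvt <- function(object, ...) {
  if (is.null(object$fit)) stop("fit has no regression component")
  unname(stats::residuals(object$fit))
}

#' Plot an HRVT fit
#'
#' Alpha1 against the predictor with the regression line, the target levels
#' and the estimated crossings; the customary view of a time-varying DFA
#' analysis of a ramp test.
#'
#' @param x an `hrvt` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hrvt <- function(x, ...) {
  a <- x$alpha
  pcol <- switch(x$predictor, hr = "hr_bpm", time = "window_end_s",
                 power = "power_w")
  xlab <- switch(x$predictor, hr = "heart rate (bpm)", time = "time (s)",
                 power = "power (W)")
  ok <- a$valid & !is.na(a[[pcol]])
  graphics::plot(a[[pcol]][ok], a$alpha1[ok], xlab = xlab,
                 ylab = expression(alpha[1]), pch = 16,
                 col = "grey40", ...)
  if (!is.null(x$fit)) graphics::abline(x$fit, col = "steelblue", lwd = 2)
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    graphics::abline(h = e$target, lty = 3)
    if (!is.na(e$value)) {
      graphics::abline(v = e$value, lty = 2, col = "firebrick")
      graphics::mtext(sprintf("%s = %.1f", toupper(e$name), e$value),
                      side = 3, at = e$value, cex = 0.8)
    }
  }
  invisible(x)
}
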