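# Named absolute-deviation thresholds (ms) for the threshold detector,
# following the consumer-software convention: a beat is an artifact when it
# deviates from the local median by more than the level's threshold.
.threshold_levels <- c(very_low = 450, low = 350, medium = 250,
                       strong = 150, very_strong = 50)

# median of the 11 nearest intervals centred on i, excluding i itself,
# truncated at the edges
local_median <- function(rr, half = 5L) {
  n <- length(rr)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    idx <- setdiff(lo:hi, i)
    stats::median(rr[idx])
  }, numeric(1))
}

#' Detect artifact beats in an RR series
#'
#' Two detectors are provided. The `"threshold"` method flags beat `i` when
#' `|rr[i] - local_median|` exceeds a fixed absolute deviation, where the local
#' median is taken over the 11 nearest intervals centred on `i` (the candidate
#' itself excluded, edge-truncated). Named levels follow the convention of
#' consumer HRV software: very_low 0.45 s, low 0.35 s, medium 0.25 s (default),
#' strong 0.15 s, very_strong 0.05 s.
#'
#' The `"automatic"` method is a successive-difference robust-z classifier:
#' within a sliding 91-beat context the quartile deviation (half the IQR) of
#' the successive differences sets a local scale, and beat `i` is flagged when
#' the smaller of its two adjacent successive differences exceeds
#' `z_cutoff` (default 5.2) times that scale — requiring both a large jump in
#' and a large jump out isolates the aberrant beat itself rather than its
#' neighbours. A merged-beat pattern check additionally flags intervals close
#' to twice the local median (ratio within [1.6, 2.4]), the signature of an
#' undetected R peak.
#'
#' @param x an [rr_series()].
#' @param method `"threshold"` or `"automatic"`.
#' @param level named threshold level (threshold method only).
#' @param z_cutoff robust-z cutoff (automatic method only).
#' @param context sliding context width in beats for the robust scale
#'   (automatic method only; odd).
#' @return an `artifact_report`: list with `method`, `level`, `flagged`
#'   (sorted beat indices), `pct`, `n`, and the detector parameters.
#' @export
detect_artifacts <- function(x, method = c("threshold", "automatic"),
                             level = "medium", z_cutoff = 5.2, context = 91L) {
  stopifnot(inherits(x, "rr_series"))
  method <- match.arg(method)
  rr <- x$rr
  n <- length(rr)
  if (method == "threshold") {
    if (n < 11L) stop("threshold detection needs at least 11 beats, got ", n)
    if (!level %in% names(.threshold_levels)) {
      stop("unknown threshold level '", level, "'; use one of: ",
           paste(names(.threshold_levels), collapse = ", "))
    }
    thr <- .threshold_levels[[level]]
    med <- local_median(rr)
    flagged <- which(abs(rr - med) > thr)
  } else {
    if (n < 30L) stop("automatic detection needs at least 30 beats, got ", n)
    level <- NA_character_
    drr <- diff(rr)                      # drr[i] = rr[i+1] - rr[i]
    half <- (as.integer(context) - 1L) %/% 2L
    nd <- length(drr)
    qd <- vapply(seq_len(nd), function(i) {
      lo <- max(1L, i - half); hi <- min(nd, i + half)
      max(stats::IQR(drr[lo:hi]) / 2, 1)   # floor at 1 ms: guards constant series
    }, numeric(1))
    # jump into beat i is drr[i-1], jump out is drr[i]
    z_in  <- c(Inf, abs(drr) / qd)        # first beat: only the outgoing jump
    z_out <- c(abs(drr) / qd, Inf)        # last beat: only the incoming jump
    z <- pmin(z_in, z_out)
    med <- local_median(rr)
    merged <- rr / med >= 1.6 & rr / med <= 2.4
    flagged <- which(z > z_cutoff | merged)
  }
  structure(
    list(method = method, level = level, flagged = as.integer(flagged),
         pct = 100 * length(flagged) / n, n = n,
         params = list(z_cutoff = z_cutoff, context = as.integer(context)),
         corrected = 0L),
    class = "artifact_report"
  )
}

#' @export
print.artifact_report <- function(x, ...) {
  lvl <- if (is.na(x$level)) "" else paste0(" (", x$level, ")")
  cat(sprintf("artifact_report: %s%s, %d/%d beats flagged (%.2f%%)\n",
              x$method, lvl, length(x$flagged), x$n, x$pct))
  invisible(x)
}

#' Correct flagged artifact beats
#'
#' Flagged intervals are replaced by cubic-spline interpolation through the
#' neighbouring non-flagged intervals. A flagged interval exceeding 1.75 times
#' the local median — the signature of one or more missed beats — is first
#' split into `k = round(rr / local_median)` sub-intervals; the spline values
#' filling those slots are rescaled so their sum equals the original interval,
#' conserving total recording duration exactly for every split. Beats created
#' or replaced by correction are marked in the returned series' `corrected`
#' field.
#'
#' @param x an [rr_series()].
#' @param report an `artifact_report` from [detect_artifacts()].
#' @return a corrected [rr_series()]; identical to `x` when nothing is flagged.
#' @export
correct_artifacts <- function(x, report) {
  stopifnot(inherits(x, "rr_series"), inherits(report, "artifact_report"))
  flags <- report$flagged
  if (length(flags) == 0L) return(x)
  n <- length(x$rr)
  if (length(flags) >= n) stop("every beat is flagged; nothing to interpolate from")
  rr <- x$rr
  med <- local_median(rr)
  # expand each flagged interval into k slots (k >= 2 only for merged beats)
  k <- rep(1L, n)
  is_flag <- logical(n); is_flag[flags] <- TRUE
  split_sel <- is_flag & rr > 1.75 * med
  k[split_sel] <- pmax(2L, round(rr[split_sel] / med[split_sel]))
  pos <- rep(seq_len(n), times = k)           # original index of each slot
  new_rr <- rep(NA_real_, length(pos))
  keep <- !is_flag[pos]
  new_rr[keep] <- rr[pos[keep]]
  good_idx <- which(keep)
  sp <- stats::spline(x = good_idx, y = new_rr[good_idx],
                      xout = which(!keep), method = "fmm")
  new_rr[!keep] <- sp$y
  # rescale split groups so each conserves its original duration exactly
  for (i in which(split_sel)) {
    slots <- which(pos == i)
    s <- sum(new_rr[slots])
    if (s <= 0) new_rr[slots] <- rr[i] / length(slots)
    else new_rr[slots] <- new_rr[slots] * rr[i] / s
  }
  new_rr <- pmax(new_rr, 1)                   # intervals must stay positive
  corrected <- x$corrected[pos]
  corrected[!keep] <- TRUE
  out <- suppressWarnings(
    rr_series(new_rr, channels = x$channels, meta = x$meta, corrected = corrected)
  )
  out
}

#' Inject missed-beat artifact
#'
#' Emulates dropped QRS detections: `round(pct/100 * n)` interior beats are
#' deleted, chosen uniformly without replacement with no two adjacent.
#' Deleting beat `i` merges intervals `i` and `i + 1` into a single interval of
#' their sum, so the beat count drops by one per deletion and total recording
#' duration is conserved exactly.
#'
#' @param x an [rr_series()].
#' @param pct target artifact percentage, in (0, 20].
#' @param seed integer seed making the deletion pattern reproducible.
#' @return list with `series` (degraded [rr_series()]) and `log` (sorted
#'   indices of the deleted beats in the original series).
#' @export
inject_missed_beats <- function(x, pct, seed = NULL) {
  stopifnot(inherits(x, "rr_series"))
  if (!(pct > 0 && pct <= 20)) stop("pct must be in (0, 20], got ", pct)
  n <- length(x$rr)
  m <- round(pct / 100 * n)
  if (m == 0L) {
    warning("requested artifact level rounds to 0 deletions; series unchanged")
    return(list(series = x, log = integer(0)))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  interior <- 2:(n - 1L)
  cand <- sample(interior)
  chosen <- integer(0)
  taken <- logical(n)
  for (i in cand) {
    if (length(chosen) == m) break
    if (!taken[i - 1L] && !taken[i] && !taken[i + 1L]) {
      chosen <- c(chosen, i)
      taken[i] <- TRUE
    }
  }
  if (length(chosen) < m) {
    stop("cannot place ", m, " non-adjacent deletions among ", n - 2L,
         " interior beats")
  }
  chosen <- sort(chosen)
  rr <- x$rr
  for (i in rev(chosen)) {                    # merge i into i+1, drop i
    rr[i + 1L] <- rr[i] + rr[i + 1L]
    rr <- rr[-i]
  }
  out <- suppressWarnings(rr_series(rr, channels = x$channels, meta = x$meta))
  list(series = out, log = chosen)
}

#' Smoothness-priors detrending
#'
#' Removes the slow trend of an RR window by the regularised fit
#' `trend = (I + lambda^2 t(D2) D2)^{-1} z`, where `D2` is the second-difference
#' operator and `lambda` the smoothing parameter (default 500, the convention
#' in HRV preprocessing). The window mean is removed first and not restored, so
#' the output is the zero-mean detrended fluctuation signal. `lambda = 0`
#' reproduces the input as its own trend and returns zeros.
#'
#' @param z numeric window of RR intervals (ms), length at least 3.
#' @param lambda smoothing parameter, `>= 0`.
#' @return numeric vector, `z - mean(z) - trend`.
#' @export
sp_detrend <- function(z, lambda = 500) {
  n <- length(z)
  if (n < 3L) stop("smoothness-priors detrending needs at least 3 samples")
  stopifnot(lambda >= 0)
  z0 <- z - mean(z)
  if (lambda == 0) return(rep(0, n))
  D2 <- diff(diag(n), differences = 2L)
  trend <- solve(diag(n) + lambda^2 * crossprod(D2), z0)
  as.numeric(z0 - trend)
}
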