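# Per-minute HRV feature extraction from interbeat-interval (IBI) streams.
#
# The raw signal is a beat train: for each detected R peak, the time of the
# beat (seconds since local midnight) and the interval to the next beat (ms).
# All downstream symbols (RMSSD, SDNN, band powers, validity flags) are
# derived per calendar minute from this stream.

#' Interbeat-interval series for one person-day
#'
#' Light container for a beat stream: ordered timestamps (seconds since local
#' midnight) with the interbeat interval (ms) attached to each beat.
#' Timestamps must be strictly increasing and intervals positive.  Each
#' timestamp is expected to equal the previous timestamp plus the previous
#' interval in seconds; larger deviations are allowed (dropout gaps) and are
#' counted in the `n_gaps` attribute rather than rejected.
#'
#' @param person_id opaque person identifier.
#' @param day calendar day label (anything coercible to character).
#' @param t numeric vector, beat timestamps in seconds since midnight.
#' @param ibi numeric vector, interbeat intervals in milliseconds.
#' @param tol continuity tolerance in seconds when checking that consecutive
#'   timestamps agree with the intervals.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(person_id, day, t, ibi, tol = 0.005) {
  stopifnot(length(t) == length(ibi))
  if (length(t)) {
    if (any(diff(t) <= 0))
      stop_addhrvr("beat timestamps must be strictly increasing",
                   "addhrvr_bad_input")
    if (any(!is.finite(ibi)) || any(ibi <= 0))
      stop_addhrvr("interbeat intervals must be positive and finite",
                   "addhrvr_bad_input")
  }
  n_gaps <- if (length(t) > 1L)
    sum(abs(diff(t) - ibi[-length(ibi)] / 1000) > tol) else 0L
  structure(
    list(person_id = person_id, day = as.character(day),
         beats = data.frame(t = as.numeric(t), ibi = as.numeric(ibi))),
    n_gaps = n_gaps, class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  b <- x$beats
  cat(sprintf("<ibi_series> person %s day %s: %d beats", x$person_id, x$day,
              nrow(b)))
  if (nrow(b))
    cat(sprintf(" [%s-%s], %d gap(s)", fmt_clock(floor(b$t[1])),
                fmt_clock(floor(b$t[nrow(b)])), attr(x, "n_gaps")))
  cat("\n")
  invisible(x)
}

#' Root mean square of successive differences
#'
#' Time-domain, vagally sensitive HRV statistic: the square root of the mean
#' squared difference between successive interbeat intervals.  Requires at
#' least three intervals; otherwise returns `NA` (too little data for a
#' variability estimate, matching the per-minute missing rule).
#'
#' @param ibi numeric vector of interbeat intervals (ms).
#' @return RMSSD in ms, or `NA_real_`.
#' @export
rmssd <- function(ibi) {
  ibi <- ibi[!is.na(ibi)]
  if (length(ibi) < 3L) return(NA_real_)
  sqrt(mean(diff(ibi)^2))
}

#' Standard deviation of normal-to-normal intervals
#'
#' Sample standard deviation (n-1 denominator) of the interbeat intervals;
#' the overall-magnitude HRV statistic.  At least three intervals required.
#'
#' @inheritParams rmssd
#' @return SDNN in ms, or `NA_real_`.
#' @export
sdnn <- function(ibi) {
  ibi <- ibi[!is.na(ibi)]
  if (length(ibi) < 3L) return(NA_real_)
  stats::sd(ibi)
}

#' Natural-log transform for HRV quantities
#'
#' HRV magnitudes are right-skewed; models work on the natural-log scale.
#' Zero, negative or missing input maps to `NA`.
#'
#' @param x numeric vector (ms or ms^2).
#' @return `log(x)` with non-positive and missing inputs as `NA`.
#' @export
ln_hrv <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok] <- log(x[ok])
  out
}

# Welch power spectral density of an evenly sampled, zero-mean signal.
# Linear detrend + Hann taper per segment, one-sided density in ms^2/Hz.
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(n, nperseg %||% n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  nf <- nperseg %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    idx <- seq_len(nperseg)
    seg <- stats::lm.fit(cbind(1, idx), seg)$residuals   # detrend
    sp <- abs(stats::fft(seg * w))^2
    acc <- acc + 2 * sp[2:(nf + 1L)] / (fs * sum(w^2))
  }
  list(freq = (1:nf) * fs / nperseg, psd = acc / length(starts))
}

# Trapezoidal integral of psd over [lo, hi], with linear interpolation at the
# band edges so adjacent bands share a boundary point without double counting.
integrate_band <- function(freq, psd, lo, hi) {
  lo <- max(lo, freq[1]); hi <- min(hi, freq[length(freq)])
  if (hi <= lo) return(0)
  grid <- sort(unique(c(lo, freq[freq > lo & freq < hi], hi)))
  vals <- stats::approx(freq, psd, xout = grid)$y
  sum(diff(grid) * (vals[-1] + vals[-length(vals)]) / 2)
}

#' Spectral band power of an IBI window
#'
#' Integrated power of the interbeat-interval tachogram over a frequency band
#' (HF 0.15-0.40 Hz, LF 0.04-0.15 Hz).  The irregularly sampled tachogram is
#' cubic-spline interpolated onto an even 4 Hz grid, linearly detrended,
#' Hann-tapered Welch periodograms are averaged, and the one-sided density is
#' integrated over the band by the trapezoid rule.
#'
#' The window must span at least two cycles of the band's lower edge
#' (e.g. 50 s for LF); shorter windows return `NA`.
#'
#' @param ibi numeric vector of interbeat intervals (ms) in the window.
#' @param band length-2 numeric, `c(lo, hi)` in Hz.
#' @param t optional beat timestamps (s); defaults to the cumulative sum of
#'   the intervals.
#' @param fs resampling rate in Hz.
#' @param nperseg Welch segment length in samples (default: one segment).
#' @return band power in ms^2, or `NA_real_` for a too-short window.
#' @export
band_power <- function(ibi, band, t = NULL, fs = 4, nperseg = NULL) {
  stopifnot(length(band) == 2L, band[1] >= 0, band[2] > band[1])
  ibi <- as.numeric(ibi)
  if (is.null(t)) t <- cumsum(ibi) / 1000
  keep <- !is.na(ibi) & !is.na(t)
  ibi <- ibi[keep]; t <- t[keep]
  if (length(ibi) < 4L) return(NA_real_)
  dur <- t[length(t)] - t[1]
  if (band[1] > 0 && dur < 2 / band[1]) return(NA_real_)
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  if (length(grid) < 8L) return(NA_real_)
  x <- stats::spline(t, ibi, xout = grid, method = "natural")$y
  ps <- welch_psd(x, fs, nperseg = nperseg)
  max(0, integrate_band(ps$freq, ps$psd, band[1], band[2]))
}

#' Artifact-screening rules for one-minute IBI segments
#'
#' Explicit, configurable surrogate for a device-internal validity check:
#' a minute is set to missing when any interval falls outside physiological
#' bounds, when a successive interval changes by more than a fraction of its
#' predecessor (ectopic beats, detection errors), or when too few beats were
#' detected.
#'
#' @param max_rel_jump maximal allowed |successive difference| as a fraction
#'   of the preceding interval.
#' @param ibi_min,ibi_max physiological interval bounds in ms.
#' @param min_beats minimal beat count per minute.
#' @return a list of class `artifact_rules`.
#' @export
artifact_rules <- function(max_rel_jump = 0.30, ibi_min = 300, ibi_max = 2000,
                           min_beats = 30L) {
  stopifnot(max_rel_jump > 0, ibi_min > 0, ibi_max > ibi_min, min_beats >= 0)
  structure(list(max_rel_jump = max_rel_jump, ibi_min = ibi_min,
                 ibi_max = ibi_max, min_beats = as.integer(min_beats)),
            class = "artifact_rules")
}

# TRUE when the minute's interval vector passes every rule.
check_artifacts <- function(ibi, rules = artifact_rules()) {
  if (length(ibi) < rules$min_beats) return(FALSE)
  if (any(ibi < rules$ibi_min | ibi > rules$ibi_max)) return(FALSE)
  if (length(ibi) > 1L) {
    rel <- abs(diff(ibi)) / ibi[-length(ibi)]
    if (any(rel > rules$max_rel_jump)) return(FALSE)
  }
  TRUE
}

#' Apply artifact rules to one minute record
#'
#' Re-evaluates a populated minute record against a rule set; when any rule
#' fires, `valid` is set to `FALSE` and all HRV fields are set to missing
#' (invalid minutes propagate as missing, never as zero).
#'
#' @param record a one-row data frame as produced by [segment_minutes()].
#' @param ibi the minute's interval vector (ms).
#' @param rules an [artifact_rules()] object.
#' @return the record, with `valid` and HRV fields updated.
#' @export
validate_minute <- function(record, ibi, rules = artifact_rules()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (!check_artifacts(ibi, rules)) {
    record$valid <- FALSE
    record[c("rmssd", "sdnn", "hf", "lf")] <- NA_real_
  }
  record
}

#' Segment a beat stream into per-minute HRV records
#'
#' Cuts the day window into half-open calendar minutes `[t, t+60)`, assigns
#' each beat to the minute containing its timestamp, screens each minute with
#' the artifact rules, and computes RMSSD, SDNN and (optionally) HF/LF band
#' power from the surviving intervals.  Exactly one record per minute of the
#' window is returned; minutes failing the rules have `valid = FALSE` and
#' missing HRV fields.
#'
#' @param series an [ibi_series()].
#' @param day_window length-2 numeric `[start, end)` in seconds since
#'   midnight, aligned to whole minutes.  Default 09:00-21:00, the waking-day
#'   monitoring window.
#' @param rules an [artifact_rules()] object.
#' @param met optional per-minute movement values (metabolic equivalents),
#'   one per minute of the window.
#' @param bands compute HF (0.15-0.40 Hz) and LF (0.04-0.15 Hz) power per
#'   minute (slower); otherwise those columns are `NA`.
#' @return data frame with one row per minute: `person_id`, `day`,
#'   `minute_start`, `rmssd`, `sdnn`, `hf`, `lf`, `met`, `valid`, `n_beats`.
#' @export
segment_minutes <- function(series, day_window = c(9L, 21L) * 3600,
                            rules = artifact_rules(), met = NULL,
                            bands = TRUE) {
  stopifnot(inherits(series, "ibi_series"), length(day_window) == 2L,
            day_window[2] > day_window[1])
  if (any(day_window %% 60 != 0))
    stop_addhrvr("day_window must be aligned to whole minutes",
                 "addhrvr_bad_input")
  starts <- seq(day_window[1], day_window[2] - 60, by = 60)
  n_min <- length(starts)
  if (!is.null(met)) stopifnot(length(met) == n_min)
  out <- data.frame(
    person_id = rep(series$person_id, n_min), day = rep(series$day, n_min),
    minute_start = starts, rmssd = NA_real_, sdnn = NA_real_, hf = NA_real_,
    lf = NA_real_, met = if (is.null(met)) NA_real_ else as.numeric(met),
    valid = FALSE, n_beats = 0L, stringsAsFactors = FALSE)
  b <- series$beats
  if (!nrow(b)) return(out)
  idx <- findInterval(b$t, c(starts, day_window[2]))
  inside <- idx >= 1L & idx <= n_min & b$t >= day_window[1] &
    b$t < day_window[2]
  split_ibi <- split(b$ibi[inside], idx[inside])
  split_t <- split(b$t[inside], idx[inside])
  for (key in names(split_ibi)) {
    i <- as.integer(key)
    v <- split_ibi[[key]]
    out$n_beats[i] <- length(v)
    if (!check_artifacts(v, rules)) next
    out$valid[i] <- TRUE
    out$rmssd[i] <- rmssd(v)
    out$sdnn[i] <- sdnn(v)
    if (bands) {
      out$lf[i] <- band_power(v, c(0.04, 0.15), t = split_t[[key]])
      out$hf[i] <- band_power(v, c(0.15, 0.40), t = split_t[[key]])
    }
  }
  out
}

#' Read an IBI stream CSV
#'
#' Expects columns `person_id`, `day`, `t_seconds`, `ibi_ms`; returns one
#' [ibi_series()] per person-day.
#'
#' @param path file path.
#' @return named list of `ibi_series` (names `person_id/day`).
#' @export
read_ibi_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "day", "t_seconds", "ibi_ms")
  if (!all(need %in% names(d)))
    stop_addhrvr(paste("IBI CSV must have columns:",
                       paste(need, collapse = ", ")), "addhrvr_bad_input")
  key <- paste(d$person_id, d$day, sep = "/")
  lapply(split(d, key), function(g) {
    g <- g[order(g$t_seconds), ]
    ibi_series(g$person_id[1], g$day[1], g$t_seconds, g$ibi_ms)
  })
}

#' Write IBI series to CSV
#' @param series_list a list of [ibi_series()] objects (or a single one).
#' @param path file path.
#' @export
write_ibi_csv <- function(series_list, path) {
  if (inherits(series_list, "ibi_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s)
    data.frame(person_id = s$person_id, day = s$day, t_seconds = s$beats$t,
               ibi_ms = s$beats$ibi, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-minute HRV records to CSV
#'
#' Missing values are written as empty fields.
#' @param minutes data frame from [segment_minutes()].
#' @param path file path.
#' @export
write_minutes_csv <- function(minutes, path) {
  utils::write.csv(minutes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-minute HRV records from CSV
#' @param path file path.
#' @return data frame in the [segment_minutes()] layout.
#' @export
read_minutes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$valid <- as.logical(d$valid)
  d
}
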