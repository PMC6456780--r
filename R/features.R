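#' Locate the MMN peak on a ROI trace
#'
#' Returns the most negative sample in the analysis window and its latency;
#' ties are broken by the earliest time.
#'
#' @param wave Numeric ROI trace, or an `mmn_diffwave`.
#' @param time_ms Time axis (ms); taken from the object if `wave` is an
#'   `mmn_diffwave`.
#' @param window_ms Search window (ms post-stimulus).
#' @return List with `latency_ms` and `raw_value_uV`.
#' @export
find_peak <- function(wave, time_ms = NULL, window_ms = c(100, 250)) {
  if (inherits(wave, "mmn_diffwave")) {
    time_ms <- wave$time_ms
    wave <- wave$roi_trace
  }
  stop_if_not(length(wave) == length(time_ms), "wave and time axis differ in length")
  win <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  stop_if_not(length(win) > 0, "empty search window")
  i <- win[which.min(wave[win])]   # which.min returns the first minimum
  list(latency_ms = time_ms[i], raw_value_uV = wave[i])
}

# Indices of interior local maxima: rising (or flat) into the point and
# falling after it, with strictly greater than the previous sample.
local_maxima <- function(w) {
  n <- length(w)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[w[i] > w[i - 1] & w[i] >= w[i + 1]]
}

#' Reference level: nearest extremum to the MMN peak
#'
#' Amplitude is measured relative to the voltage of the local maximum
#' nearest in time to the MMN peak, searched over the whole trace on both
#' sides (the preceding side wins ties). If the trace has no interior local
#' maximum, the prestimulus baseline level (0) is used.
#'
#' @param wave Numeric ROI trace, or an `mmn_diffwave`.
#' @param time_ms Time axis (ms).
#' @param peak A peak from [find_peak()].
#' @return Reference level in microvolts.
#' @export
reference_extremum <- function(wave, time_ms = NULL, peak) {
  if (inherits(wave, "mmn_diffwave")) {
    time_ms <- wave$time_ms
    wave <- wave$roi_trace
  }
  lm <- local_maxima(wave)
  if (length(lm) == 0) return(0)
  dt <- abs(time_ms[lm] - peak$latency_ms)
  best <- dt == min(dt)
  cand <- lm[best]
  if (length(cand) > 1) {                    # tie: prefer the preceding side
    prev <- cand[time_ms[cand] <= peak$latency_ms]
    cand <- if (length(prev) > 0) max(prev) else min(cand)
  }
  wave[cand[1]]
}

#' Area under the curve of the MMN deflection
#'
#' Integrates `reference_level - wave(t)` over the maximal interval
#' containing the peak on which the wave stays below the reference level,
#' bounded by the (linearly interpolated) crossings of the reference level
#' or the ends of the trace; trapezoidal rule, units microvolt-milliseconds.
#'
#' @param wave Numeric ROI trace, or an `mmn_diffwave`.
#' @param time_ms Time axis (ms).
#' @param peak A peak from [find_peak()].
#' @param reference_level Reference voltage from [reference_extremum()].
#' @return Non-negative AUC; 0 with a warning if the peak does not lie below
#'   the reference level.
#' @export
area_under_curve <- function(wave, time_ms = NULL, peak, reference_level) {
  if (inherits(wave, "mmn_diffwave")) {
    time_ms <- wave$time_ms
    wave <- wave$roi_trace
  }
  if (peak$raw_value_uV >= reference_level) {
    warning("MMN peak is not below the reference level; AUC set to 0")
    return(0)
  }
  ip <- which.min(abs(time_ms - peak$latency_ms))
  below <- wave < reference_level
  lo <- ip
  while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- ip
  n <- length(wave)
  while (hi < n && below[hi + 1]) hi <- hi + 1

  tt <- time_ms[lo:hi]
  dd <- reference_level - wave[lo:hi]        # depth below reference, >= 0
  # interpolated crossings as zero-depth endpoints
  if (lo > 1) {
    d0 <- reference_level - wave[lo - 1]     # <= 0 on the outside
    frac <- dd[1] / (dd[1] - d0)
    tt <- c(time_ms[lo] - frac * (time_ms[lo] - time_ms[lo - 1]), tt)
    dd <- c(0, dd)
  }
  if (hi < n) {
    d1 <- reference_level - wave[hi + 1]
    frac <- dd[length(dd)] / (dd[length(dd)] - d1)
    tt <- c(tt, time_ms[hi] + frac * (time_ms[hi + 1] - time_ms[hi]))
    dd <- c(dd, 0)
  }
  sum(diff(tt) * (head(dd, -1) + dd[-1]) / 2)
}

#' Extract the MMN feature set of one subject
#'
#' Composes peak finding, nearest-extremum referencing, AUC and the mastoid
#' polarity-reversal check for every deviant difference wave of a subject.
#' Amplitude is reported as the signed peak value relative to the reference
#' level (negative for a genuine MMN).
#'
#' @param diffwaves Named list of `mmn_diffwave`, one per deviant kind.
#' @param subject_id,group Subject metadata copied into the table.
#' @param window_ms MMN analysis window (ms).
#' @param kinds Deviant kinds expected; a missing kind yields a row of `NA`s
#'   rather than a fabricated feature.
#' @return Tibble with one row per deviant kind: `subject_id`, `group`,
#'   `deviant_kind`, `amplitude_uV`, `latency_ms`, `auc_uVms`,
#'   `reference_uV`, `reversal_ok`.
#' @export
extract_features <- function(diffwaves, subject_id = NA_character_,
                             group = NA_character_, window_ms = c(100, 250),
                             kinds = setdiff(deviant_kinds(), "standard")) {
  rows <- lapply(kinds, function(k) {
    dw <- diffwaves[[k]]
    if (is.null(dw)) {
      return(tibble::tibble(
        subject_id = subject_id, group = group, deviant_kind = k,
        amplitude_uV = NA_real_, latency_ms = NA_real_, auc_uVms = NA_real_,
        reference_uV = NA_real_, reversal_ok = NA
      ))
    }
    pk <- find_peak(dw, window_ms = window_ms)
    ref <- reference_extremum(dw, peak = pk)
    auc <- if (pk$raw_value_uV < ref) {
      area_under_curve(dw, peak = pk, reference_level = ref)
    } else 0
    rev <- tryCatch(polarity_reversal_check(dw, window_ms)$reversed,
                    error = function(e) NA)
    tibble::tibble(
      subject_id = subject_id, group = group, deviant_kind = k,
      amplitude_uV = pk$raw_value_uV - ref, latency_ms = pk$latency_ms,
      auc_uVms = auc, reference_uV = ref, reversal_ok = rev
    )
  })
  do.call(rbind, rows)
}

#' Write / read a feature table CSV
#'
#' Columns: `subject_id`, `group`, `deviant_kind`, `amplitude_uV`,
#' `latency_ms`, `auc_uVms`, `reference_uV`, `reversal_ok`.
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  stop_if_not(file.exists(path), "feature file not found: %s", path)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
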