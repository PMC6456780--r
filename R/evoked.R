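#' Average kept epochs per stimulus condition
#'
#' @param epochs An `mmn_epochs`.
#' @param kinds Conditions to average; defaults to every kind present.
#' @return Named list of `mmn_evoked` objects (`data` channels x samples,
#'   `n_trials`, `condition`, `time_ms`, `labels`).
#' @export
average_by_condition <- function(epochs, kinds = unique(epochs$info$kind)) {
  out <- list()
  for (k in kinds) {
    sel <- epochs$info$kind == k & epochs$info$keep
    if (!any(sel)) {
      stop("no kept trials for condition '", k, "'", call. = FALSE)
    }
    m <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1)
    dimnames(m) <- list(epochs$labels, NULL)
    out[[k]] <- structure(
      list(data = m, n_trials = sum(sel), condition = k,
           time_ms = epochs$time_ms, labels = epochs$labels),
      class = "mmn_evoked"
    )
  }
  out
}

#' Deviant-minus-standard difference wave
#'
#' Subtracts the standard evoked response from a deviant evoked response
#' channel-wise, and collapses the result to the frontocentral ROI trace
#' (unweighted mean over F3, F4, Fz, FC3, FC4, FCz, Cz).
#'
#' @param deviant,standard `mmn_evoked` objects on the same layout and time
#'   axis.
#' @param roi ROI channel labels.
#' @return An `mmn_diffwave`: `data` (channels x samples), `roi_trace`,
#'   `roi`, `kind`, `time_ms`, `labels`.
#' @export
difference_wave <- function(deviant, standard, roi = roi_channels()) {
  stop_if_not(identical(deviant$labels, standard$labels) &&
                length(deviant$time_ms) == length(standard$time_ms) &&
                max(abs(deviant$time_ms - standard$time_ms)) < 1e-9,
              "deviant and standard evoked have mismatched layout or time axis")
  stop_if_not(all(roi %in% deviant$labels), "ROI channel(s) absent: %s",
              paste(setdiff(roi, deviant$labels), collapse = ", "))
  d <- deviant$data - standard$data
  structure(
    list(data = d, roi_trace = colMeans(d[roi, , drop = FALSE]), roi = roi,
         kind = deviant$condition, time_ms = deviant$time_ms,
         labels = deviant$labels),
    class = "mmn_diffwave"
  )
}

#' Check the mastoid polarity reversal
#'
#' An MMN of auditory-cortex origin inverts its sign at the mastoids under a
#' nose reference. The check locates the ROI-trace minimum in the analysis
#' window and compares the sign of the mean of M1 and M2 at that latency
#' with the sign of the ROI value there (`mode = "peak"`), or compares
#' window-mean values (`mode = "mean"`).
#'
#' @param diff An `mmn_diffwave` containing M1 and M2.
#' @param window_ms Analysis window (ms).
#' @param mode `"peak"` (instantaneous value at ROI-peak latency, default)
#'   or `"mean"` (window means).
#' @return List with `reversed` (logical), `m1_value`, `m2_value`,
#'   `roi_value`, `latency_ms`.
#' @export
polarity_reversal_check <- function(diff, window_ms = c(100, 250),
                                    mode = c("peak", "mean")) {
  mode <- match.arg(mode)
  stop_if_not(all(c("M1", "M2") %in% diff$labels),
              "mastoid channels M1/M2 missing")
  win <- diff$time_ms >= window_ms[1] & diff$time_ms <= window_ms[2]
  stop_if_not(any(win), "window outside the epoch span")
  if (mode == "peak") {
    i <- which(win)[which.min(diff$roi_trace[win])]
    roi_v <- unname(diff$roi_trace[i])
    m1 <- unname(diff$data["M1", i])
    m2 <- unname(diff$data["M2", i])
    lat <- diff$time_ms[i]
  } else {
    roi_v <- mean(diff$roi_trace[win])
    m1 <- mean(diff$data["M1", win])
    m2 <- mean(diff$data["M2", win])
    lat <- NA_real_
  }
  mast <- (m1 + m2) / 2
  list(reversed = (roi_v != 0 && mast != 0 && sign(mast) == -sign(roi_v)),
       m1_value = m1, m2_value = m2, roi_value = roi_v, latency_ms = lat)
}

#' Export an evoked or difference waveform as wide CSV
#'
#' Time column (ms) plus one column per channel.
#'
#' @param x An `mmn_evoked` or `mmn_diffwave`.
#' @param path Output CSV.
#' @export
write_waveform_csv <- function(x, path) {
  df <- data.frame(time_ms = x$time_ms, t(x$data), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
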