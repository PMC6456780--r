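#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass (default 1-20 Hz) forward and
#' backward (`signal::filtfilt`) to every channel, EOG included, so that the
#' filter delay is fully compensated.
#'
#' @param rec An `mmn_recording`.
#' @param low_hz,high_hz Band edges (Hz); must satisfy
#'   `0 < low < high < Nyquist`.
#' @param order Butterworth order per pass.
#' @param method `"fft"` (default) applies the squared Butterworth magnitude
#'   in the frequency domain — the stationary response of the
#'   forward-backward cascade, computed in one pass over all channels;
#'   `"filtfilt"` runs [signal::filtfilt()] per channel in the time domain.
#'   The two agree away from the recording edges.
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low_hz = 1, high_hz = 20, order = 4,
                     method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  fs <- rec$sample_rate_hz
  stop_if_not(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2,
              "invalid band [%g, %g] Hz for sampling rate %g Hz",
              low_hz, high_hz, fs)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- rec
  if (method == "filtfilt") {
    out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  } else {
    n <- ncol(rec$data)
    m <- next_fast_len(n)
    w <- 2 * pi * (seq_len(m) - 1) / m              # digital frequency grid
    ejw <- exp(-1i * outer(w, seq_along(bf$b) - 1))
    H <- (ejw %*% bf$b) / (ejw %*% bf$a)
    G <- as.vector(Mod(H)^2)                        # zero-phase |H|^2
    X <- rbind(t(rec$data), matrix(0, m - n, nrow(rec$data)))
    spec <- mvfft(X) * G
    out$data <- t(Re(mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE] / m)
  }
  dimnames(out$data) <- dimnames(rec$data)
  out
}

#' Remove ocular artifacts
#'
#' Default method decomposes all channels (scalp + EOG) with FastICA and
#' removes every component whose absolute Pearson correlation with either
#' EOG channel exceeds `cor_threshold`, then reconstructs the recording. If
#' the decomposition fails, or with `method = "regression"`, the EOG signals
#' are instead projected out of the scalp channels by least squares.
#'
#' @param rec An `mmn_recording`.
#' @param eog_channels Labels of the EOG channels.
#' @param method `"ica"` (default) or `"regression"`.
#' @param cor_threshold Absolute correlation above which a component is
#'   classified as ocular.
#' @return The cleaned recording; attribute `n_removed` reports how many
#'   components were removed (ICA) and attribute `ocular_method` the method
#'   actually used.
#' @export
remove_ocular <- function(rec, eog_channels = rec$layout$eog,
                          method = c("ica", "regression"),
                          cor_threshold = 0.7) {
  method <- match.arg(method)
  labels <- rownames(rec$data)
  stop_if_not(all(eog_channels %in% labels), "EOG channel(s) not present: %s",
              paste(setdiff(eog_channels, labels), collapse = ", "))
  eog <- rec$data[eog_channels, , drop = FALSE]
  out <- rec

  if (method == "ica") {
    res <- tryCatch(fast_ica(rec$data), error = function(e) e)
    if (inherits(res, "error")) {
      warning("ICA decomposition failed (", conditionMessage(res),
              "); falling back to EOG regression")
      method <- "regression"
    } else {
      r <- suppressWarnings(abs(cor(t(res$S), t(eog))))
      r[!is.finite(r)] <- 0                # silent EOG channel: nothing ocular
      ocular <- apply(r, 1, max) > cor_threshold
      keep <- !ocular
      out$data <- res$A[, keep, drop = FALSE] %*% res$S[keep, , drop = FALSE] +
        res$mean
      dimnames(out$data) <- dimnames(rec$data)
      attr(out, "n_removed") <- sum(ocular)
      attr(out, "ocular_method") <- "ica"
      return(out)
    }
  }

  # regression: subtract the least-squares EOG projection from scalp channels
  scalp <- setdiff(labels, eog_channels)
  E <- t(eog)                             # samples x 2
  Ec <- sweep(E, 2, colMeans(E))
  if (all(apply(Ec, 2, function(v) max(abs(v))) < 1e-9)) {
    attr(out, "n_removed") <- 0L          # silent EOG: nothing to remove
    attr(out, "ocular_method") <- "regression"
    return(out)
  }
  S <- t(rec$data[scalp, , drop = FALSE])
  Sc <- sweep(S, 2, colMeans(S))
  beta <- solve(crossprod(Ec), crossprod(Ec, Sc))
  out$data[scalp, ] <- t(S - Ec %*% beta)
  attr(out, "n_removed") <- NA_integer_
  attr(out, "ocular_method") <- "regression"
  out
}

#' Cut stimulus-locked epochs
#'
#' One epoch per event, spanning `tmin_ms` to `tmax_ms` relative to stimulus
#' onset; the per-channel mean of the prestimulus interval (time <= 0) is
#' subtracted from every epoch. Events whose epoch would run past either
#' recording edge are flagged (`keep = FALSE`, reason `"edge"`), not dropped.
#'
#' @param rec An `mmn_recording` (filtered and cleaned).
#' @param tmin_ms,tmax_ms Epoch span relative to onset (ms).
#' @return An `mmn_epochs` object: `data` (trials x channels x samples array,
#'   microvolts), `time_ms`, `labels`, `eog`, and an `info` tibble
#'   (`kind`, `block`, `trial`, `is_warmup`, `keep`, `reason`).
#' @export
extract_epochs <- function(rec, tmin_ms = -50, tmax_ms = 900) {
  fs <- rec$sample_rate_hz
  o1 <- round(tmin_ms / 1000 * fs)
  o2 <- round(tmax_ms / 1000 * fs)
  offsets <- o1:o2
  time_ms <- offsets / fs * 1000
  n_tr <- nrow(rec$events)
  labels <- rownames(rec$data)
  n_samp <- ncol(rec$data)
  data <- array(0, dim = c(n_tr, length(labels), length(offsets)),
                dimnames = list(NULL, labels, NULL))
  keep <- rep(TRUE, n_tr)
  reason <- rep(NA_character_, n_tr)
  base_idx <- which(time_ms <= 0)
  for (i in seq_len(n_tr)) {
    i0 <- round(rec$events$onset_s[i] * fs) + 1
    idx <- i0 + offsets
    if (idx[1] < 1 || idx[length(idx)] > n_samp) {
      keep[i] <- FALSE
      reason[i] <- "edge"
      next
    }
    ep <- rec$data[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, base_idx, drop = FALSE])
    data[i, , ] <- ep
  }
  info <- tibble::tibble(
    kind = rec$events$kind, block = rec$events$block,
    trial = rec$events$trial, is_warmup = rec$events$is_warmup,
    keep = keep, reason = reason
  )
  structure(
    list(data = data, time_ms = time_ms, labels = labels,
         eog = intersect(rec$layout$eog, labels), info = info,
         sample_rate_hz = fs),
    class = "mmn_epochs"
  )
}

#' Reject epochs on an absolute amplitude criterion
#'
#' Trials whose maximum absolute (baseline-corrected) amplitude over the
#' scalp channels (EOG excluded) exceeds the threshold are flagged
#' `keep = FALSE` with reason `"amplitude"`.
#'
#' @param epochs An `mmn_epochs`.
#' @param threshold_uV Rejection threshold (microvolts).
#' @return The epoch set with updated keep-flags; attribute `n_rejected`
#'   counts newly rejected trials.
#' @export
reject_epochs <- function(epochs, threshold_uV = 50) {
  scalp <- setdiff(epochs$labels, epochs$eog)
  sub <- epochs$data[, scalp, , drop = FALSE]
  peak <- apply(abs(sub), 1, max)
  bad <- peak > threshold_uV & epochs$info$keep
  epochs$info$keep[bad] <- FALSE
  epochs$info$reason[bad] <- "amplitude"
  if (!any(epochs$info$keep)) {
    stop("all trials rejected at ", threshold_uV,
         " uV; review the rejection threshold", call. = FALSE)
  }
  attr(epochs, "n_rejected") <- sum(bad)
  epochs
}

#' Exclude warm-up standards from averaging
#'
#' Flags the leading warm-up standards of each block (`is_warmup`) with
#' `keep = FALSE`, reason `"warmup"`. Idempotent.
#'
#' @param epochs An `mmn_epochs`.
#' @return The epoch set with updated keep-flags.
#' @export
drop_warmup_standards <- function(epochs) {
  bad <- epochs$info$is_warmup & epochs$info$keep
  epochs$info$keep[bad] <- FALSE
  epochs$info$reason[bad] <- "warmup"
  epochs
}

#' Serialize an epoch set to a single-file container
#'
#' A JSON header (shape, time axis, labels, keep-flags) followed by the raw
#' float-32 tensor payload.
#'
#' @param epochs An `mmn_epochs`.
#' @param path Output path.
#' @return `write_epochs()` the path invisibly; `read_epochs()` the epoch
#'   set.
#' @export
write_epochs <- function(epochs, path) {
  hdr <- jsonlite::toJSON(list(
    dim = dim(epochs$data), time_ms = epochs$time_ms, labels = epochs$labels,
    eog = epochs$eog, sample_rate_hz = epochs$sample_rate_hz,
    info = epochs$info
  ), digits = NA, auto_unbox = TRUE, na = "null")
  raw_hdr <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(raw_hdr), con, size = 4, endian = "little")
  writeBin(raw_hdr, con)
  writeBin(as.numeric(epochs$data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n_hdr <- readBin(con, integer(), size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), n = n_hdr)))
  d <- hdr$dim
  x <- readBin(con, numeric(), n = prod(d), size = 4, endian = "little")
  info <- tibble::as_tibble(hdr$info)
  info$reason <- as.character(info$reason)
  structure(
    list(data = array(x, dim = d, dimnames = list(NULL, hdr$labels, NULL)),
         time_ms = hdr$time_ms, labels = hdr$labels, eog = hdr$eog,
         info = info, sample_rate_hz = hdr$sample_rate_hz),
    class = "mmn_epochs"
  )
}
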