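# BrainVision (.vhdr / .vmrk / .eeg) reader and writer. The binary payload is
# multiplexed IEEE float-32 in microvolts (resolution 1), which round-trips
# EEG data losslessly to float32 precision. Events are written both as
# Stimulus markers in the .vmrk and as a sidecar `<base>_events.csv` in the
# package's events dialect (the CSV carries block/trial/warm-up metadata the
# marker format cannot).

#' Write / read a multichannel EEG recording (BrainVision format)
#'
#' @param rec An `mmn_recording`.
#' @param path Base path or `.vhdr` path; `.vhdr`, `.vmrk`, `.eeg` and
#'   `_events.csv` files are written next to it.
#' @param require_channels Optional channel labels that must be present when
#'   reading; a missing label is an error naming it.
#' @return `write_recording()` returns the `.vhdr` path invisibly;
#'   `read_recording()` an `mmn_recording`.
#' @export
write_recording <- function(rec, path) {
  base <- sub("\\.vhdr$", "", path)
  name <- basename(base)
  labels <- rownames(rec$data)
  n_ch <- nrow(rec$data)
  vhdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$sample_rate_hz),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(n_ch), labels)
  )
  writeLines(vhdr, paste0(base, ".vhdr"))

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", name, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(rec$events) > 0) {
    pos <- round(rec$events$onset_s * rec$sample_rate_hz) + 1
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L, rec$events$kind, pos))
  }
  writeLines(mk, paste0(base, ".vmrk"))

  con <- file(paste0(base, ".eeg"), "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)

  write_events(rec$events, paste0(base, "_events.csv"))
  invisible(paste0(base, ".vhdr"))
}

parse_vhdr <- function(lines) {
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, require_channels = NULL) {
  vhdr_path <- if (grepl("\\.vhdr$", path)) path else paste0(path, ".vhdr")
  stop_if_not(file.exists(vhdr_path), "header file not found: %s", vhdr_path)
  base <- sub("\\.vhdr$", "", vhdr_path)
  hdr <- parse_vhdr(readLines(vhdr_path, warn = FALSE))
  stop_if_not(identical(hdr[["DataFormat"]], "BINARY") &&
                identical(hdr[["DataOrientation"]], "MULTIPLEXED") &&
                identical(hdr[["BinaryFormat"]], "IEEE_FLOAT_32"),
              "unsupported BrainVision variant in %s", vhdr_path)
  n_ch <- as.integer(hdr[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(hdr[["SamplingInterval"]])
  ch_keys <- sprintf("Ch%d", seq_len(n_ch))
  labels <- unname(vapply(strsplit(hdr[ch_keys], ","), `[[`, character(1), 1))

  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, labels)
    stop_if_not(length(missing) == 0, "recording is missing channel(s): %s",
                paste(missing, collapse = ", "))
  }

  eeg_path <- file.path(dirname(vhdr_path), hdr[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  x <- readBin(con, numeric(), n = sz %/% 4L, size = 4, endian = "little")
  close(con)
  data <- matrix(x, nrow = n_ch, dimnames = list(labels, NULL))

  ev_csv <- paste0(base, "_events.csv")
  events <- if (file.exists(ev_csv)) {
    read_events(ev_csv)
  } else {
    mk <- grep("^Mk[0-9]+=Stimulus,", readLines(paste0(base, ".vmrk"), warn = FALSE),
               value = TRUE)
    parts <- strsplit(sub("^[^=]*=", "", mk), ",")
    tibble::tibble(
      onset_s = (as.numeric(vapply(parts, `[[`, character(1), 3)) - 1) / fs,
      kind = vapply(parts, `[[`, character(1), 2),
      block = NA_integer_, trial = NA_integer_, is_warmup = FALSE
    )
  }

  lay <- channel_layout()
  if (!setequal(labels, lay$labels)) {
    lay <- structure(list(scalp = setdiff(labels, lay$eog),
                          eog = intersect(labels, lay$eog),
                          labels = labels, reference = "nose"),
                     class = "mmn_layout")
  }
  structure(
    list(data = data, sample_rate_hz = fs, layout = lay, events = events,
         subject_id = NULL, group = NULL),
    class = "mmn_recording"
  )
}
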