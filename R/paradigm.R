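#' Configuration of the multifeature oddball paradigm
#'
#' Holds the stimulus and sequencing parameters of the paradigm: a standard
#' complex of three simultaneous sinusoids (7,500 / 8,000 / 8,500 Hz, 75 ms,
#' 5 ms rise/fall), frequency deviants shifted by +/-10\%, a 25 ms duration
#' deviant, a gap deviant with a 7 ms central silence, 900 ms offset-to-onset
#' interstimulus interval, and four blocks of 91 trials opening with 10
#' warm-up standards.
#'
#' @param standard_freqs_hz Frequencies (Hz) of the three components of the
#'   standard complex.
#' @param duration_ms Stimulus duration (ms) of standard, frequency and gap
#'   stimuli.
#' @param rise_ms,fall_ms Onset/offset ramp durations (ms).
#' @param amplitude Peak amplitude of the summed complex (linear, arbitrary
#'   units standing in for 85 dB SPL); each component carries `amplitude / 3`.
#' @param freq_shift Fractional frequency shift of the frequency deviants
#'   (0.10 means +/-10\%).
#' @param duration_deviant_ms Total duration (ms) of the duration deviant
#'   (15 ms plateau plus the 5 ms ramps).
#' @param gap_ms Length (ms) of the silent gap inserted at the centre of the
#'   gap deviant.
#' @param gap_edge_ramp_ms Ramp (ms) on each edge of the silent gap.
#' @param isi_ms Interstimulus interval (ms), measured offset-to-onset.
#' @param n_blocks,trials_per_block,n_warmup Block structure: number of
#'   blocks, trials per block, and leading warm-up standards per block.
#' @param audio_sample_rate_hz Audio sampling rate (Hz) for stimulus
#'   synthesis.
#' @param ramp_shape `"hann"` (raised-cosine, default) or `"linear"` ramps.
#' @param seed Integer seed governing block randomization.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(standard_freqs_hz = c(7500, 8000, 8500),
                            duration_ms = 75,
                            rise_ms = 5,
                            fall_ms = 5,
                            amplitude = 1,
                            freq_shift = 0.10,
                            duration_deviant_ms = 25,
                            gap_ms = 7,
                            gap_edge_ramp_ms = 1,
                            isi_ms = 900,
                            n_blocks = 4,
                            trials_per_block = 91,
                            n_warmup = 10,
                            audio_sample_rate_hz = 44100,
                            ramp_shape = c("hann", "linear"),
                            seed = 1L) {
  ramp_shape <- match.arg(ramp_shape)
  cfg <- list(
    standard_freqs_hz = as.numeric(standard_freqs_hz),
    duration_ms = duration_ms, rise_ms = rise_ms, fall_ms = fall_ms,
    amplitude = amplitude, freq_shift = freq_shift,
    duration_deviant_ms = duration_deviant_ms,
    gap_ms = gap_ms, gap_edge_ramp_ms = gap_edge_ramp_ms,
    isi_ms = isi_ms, n_blocks = n_blocks,
    trials_per_block = trials_per_block, n_warmup = n_warmup,
    audio_sample_rate_hz = audio_sample_rate_hz,
    ramp_shape = ramp_shape, seed = as.integer(seed)
  )
  validate_paradigm_config(cfg)
  structure(cfg, class = "paradigm_config")
}

validate_paradigm_config <- function(cfg) {
  stop_if_not(length(cfg$standard_freqs_hz) == 3 && all(cfg$standard_freqs_hz > 0),
              "standard_freqs_hz must be three positive frequencies")
  stop_if_not(cfg$duration_ms > 0 && cfg$rise_ms >= 0 && cfg$fall_ms >= 0,
              "durations must be positive, ramps non-negative")
  stop_if_not(cfg$rise_ms + cfg$fall_ms <= cfg$duration_ms,
              "rise_ms + fall_ms must not exceed duration_ms")
  stop_if_not(cfg$rise_ms + cfg$fall_ms <= cfg$duration_deviant_ms,
              "rise_ms + fall_ms must not exceed duration_deviant_ms")
  stop_if_not(cfg$amplitude > 0, "amplitude must be positive")
  stop_if_not(cfg$freq_shift > 0 && cfg$freq_shift < 1,
              "freq_shift must be in (0, 1)")
  stop_if_not(cfg$gap_ms > 2 * cfg$gap_edge_ramp_ms,
              "gap_ms must exceed its two edge ramps")
  stop_if_not(cfg$isi_ms > 0 && cfg$n_blocks >= 1 && cfg$trials_per_block >= 1 &&
                cfg$n_warmup >= 0,
              "sequencing parameters must be positive")
  stop_if_not(cfg$trials_per_block > cfg$n_warmup,
              "trials_per_block must exceed n_warmup")
  fmax <- max(cfg$standard_freqs_hz) * (1 + cfg$freq_shift)
  stop_if_not(cfg$audio_sample_rate_hz >= 2.2 * fmax,
              "audio sample rate %.0f Hz too low for maximum component %.0f Hz",
              cfg$audio_sample_rate_hz, fmax)
  invisible(cfg)
}

# Half-raised-cosine (or linear) onset ramp of n samples rising 0 -> 1;
# first sample is exactly 0 so that ramped stimuli start and end at zero.
ramp_window <- function(n, shape) {
  if (n <= 0) return(numeric(0))
  if (n == 1) return(0)
  x <- seq(0, 1, length.out = n)
  if (shape == "hann") 0.5 * (1 - cos(pi * x)) else x
}

stimulus_duration_ms <- function(kind, config) {
  if (kind == "duration") config$duration_deviant_ms else config$duration_ms
}

#' Synthesize a standard or deviant stimulus waveform
#'
#' Builds the tone complex for one stimulus class. The standard is the
#' equal-amplitude sum of three sinusoids with raised-cosine rise/fall ramps.
#' Frequency deviants rescale all three component frequencies by
#' `1 +/- freq_shift`; the duration deviant shortens the complex to
#' `duration_deviant_ms`; the gap deviant silences a central `gap_ms`
#' interval whose edges carry `gap_edge_ramp_ms` ramps, leaving exact zeros
#' in between.
#'
#' @param kind One of [deviant_kinds()].
#' @param config A [paradigm_config()].
#' @return An object of class `mmn_stimulus`: list with `samples`,
#'   `sample_rate_hz`, `kind`, `frequencies_hz` and `duration_ms`.
#' @export
synthesize_stimulus <- function(kind, config = paradigm_config()) {
  kind <- match.arg(kind, deviant_kinds())
  validate_paradigm_config(config)
  scale <- switch(kind,
    frequency_high = 1 + config$freq_shift,
    frequency_low  = 1 - config$freq_shift,
    1
  )
  freqs <- config$standard_freqs_hz * scale
  fs <- config$audio_sample_rate_hz
  stop_if_not(max(freqs) < fs / 2, "component frequency above Nyquist")
  dur_ms <- stimulus_duration_ms(kind, config)
  n <- round(dur_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- config$amplitude / length(freqs)
  x <- rowSums(vapply(freqs, function(f) amp * sin(2 * pi * f * t), numeric(n)))

  n_rise <- round(config$rise_ms / 1000 * fs)
  n_fall <- round(config$fall_ms / 1000 * fs)
  stop_if_not(n_rise + n_fall <= n, "ramps longer than the stimulus")
  env <- rep(1, n)
  if (n_rise > 0) env[seq_len(n_rise)] <- ramp_window(n_rise, config$ramp_shape)
  if (n_fall > 0) env[n - seq_len(n_fall) + 1] <- ramp_window(n_fall, config$ramp_shape)
  x <- x * env

  if (kind == "gap") {
    n_gap <- round(config$gap_ms / 1000 * fs)
    n_edge <- round(config$gap_edge_ramp_ms / 1000 * fs)
    g0 <- floor((n - n_gap) / 2) + 1          # first sample inside the gap
    g1 <- g0 + n_gap - 1
    gw <- rep(0, n_gap)                       # exact silence in the middle
    if (n_edge > 0) {
      gw[seq_len(n_edge)] <- rev(ramp_window(n_edge, config$ramp_shape))
      gw[n_gap - seq_len(n_edge) + 1] <- ramp_window(n_edge, config$ramp_shape)
    }
    x[g0:g1] <- x[g0:g1] * gw
  }

  structure(
    list(samples = x, sample_rate_hz = fs, kind = kind,
         frequencies_hz = freqs, duration_ms = dur_ms),
    class = "mmn_stimulus"
  )
}

#' Generate one pseudo-randomized oddball block
#'
#' The block opens with `n_warmup` standards; thereafter trials strictly
#' alternate deviant/standard starting with a deviant, so that every deviant
#' is immediately preceded by a standard and two standards never follow each
#' other after the warm-up run. Deviant kinds are allocated in
#' as-equal-as-possible counts over the four deviant classes and shuffled.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `mmn_block_plan`: tibble with columns `trial`, `kind`,
#'   `is_warmup`, and attributes `n_warmup` and `counts` (named vector of
#'   per-kind trial counts).
#' @export
generate_block <- function(config = paradigm_config(), seed = config$seed) {
  validate_paradigm_config(config)
  n <- config$trials_per_block
  w <- config$n_warmup
  kinds <- rep("standard", n)
  n_rest <- n - w
  deviant_slots <- w + seq(1, n_rest, by = 2)  # alternation starts with a deviant
  nd <- length(deviant_slots)
  classes <- setdiff(deviant_kinds(), "standard")
  base <- nd %/% length(classes)
  rem <- nd %% length(classes)
  kinds[deviant_slots] <- with_seed(seed, {
    alloc <- rep(classes, base)
    if (rem > 0) alloc <- c(alloc, sample(classes, rem))
    sample(alloc)
  })
  counts <- table(factor(kinds, levels = deviant_kinds()))
  plan <- tibble::tibble(
    trial = seq_len(n),
    kind = kinds,
    is_warmup = seq_len(n) <= w
  )
  attr(plan, "n_warmup") <- w
  attr(plan, "counts") <- setNames(as.integer(counts), names(counts))
  class(plan) <- c("mmn_block_plan", class(plan))
  plan
}

#' Schedule trial events over concatenated blocks
#'
#' Lays the blocks out on a single timeline: each next onset follows the
#' previous stimulus offset by the interstimulus interval (offset-to-onset),
#' across block boundaries as well.
#'
#' @param blocks List of block plans from [generate_block()].
#' @param config A [paradigm_config()].
#' @return Tibble of trial events with columns `onset_s`, `kind`, `block`,
#'   `trial`, `is_warmup`; attribute `total_span_s` is the time from the first
#'   onset to the last stimulus offset.
#' @export
schedule_events <- function(blocks, config = paradigm_config()) {
  stop_if_not(length(blocks) >= 1, "blocks must be non-empty")
  kind <- unlist(lapply(blocks, `[[`, "kind"))
  durs_s <- unname(vapply(kind, stimulus_duration_ms, numeric(1),
                          config = config)) / 1000
  isi_s <- config$isi_ms / 1000
  onset <- cumsum(c(0, head(durs_s + isi_s, -1)))
  ev <- tibble::tibble(
    onset_s = onset,
    kind = kind,
    block = rep(seq_along(blocks), vapply(blocks, nrow, integer(1))),
    trial = unlist(lapply(blocks, `[[`, "trial")),
    is_warmup = unlist(lapply(blocks, `[[`, "is_warmup"))
  )
  attr(ev, "total_span_s") <- onset[length(onset)] + durs_s[length(durs_s)]
  ev
}

#' Generate the full default paradigm
#'
#' Convenience wrapper: `n_blocks` pseudo-randomized blocks scheduled on one
#' timeline.
#'
#' @inheritParams generate_block
#' @return Event tibble as from [schedule_events()].
#' @export
generate_paradigm <- function(config = paradigm_config(), seed = config$seed) {
  block_seeds <- with_seed(seed, sample.int(.Machine$integer.max, config$n_blocks))
  blocks <- lapply(block_seeds, function(s) generate_block(config, seed = s))
  schedule_events(blocks, config)
}

#' Export stimulus audio and the event table
#'
#' Writes one float-PCM WAV file per stimulus kind and the event table as
#' CSV (`onset_s`, `kind`, `block`, `trial`, `is_warmup` with 0/1 flags).
#'
#' @param events Event tibble from [schedule_events()].
#' @param config A [paradigm_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_paradigm <- function(events, config = paradigm_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in deviant_kinds()) {
    stim <- synthesize_stimulus(k, config)
    p <- file.path(out_dir, paste0("stimulus_", k, ".wav"))
    write_wav(stim$samples, stim$sample_rate_hz, p)
    paths <- c(paths, p)
  }
  csv <- file.path(out_dir, "events.csv")
  write_events(events, csv)
  invisible(c(paths, csv))
}

#' Write / read the events CSV
#'
#' @param events Event tibble.
#' @param path CSV path.
#' @return `read_events()` returns the event tibble; `write_events()` the
#'   path, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(
    onset_s = events$onset_s, kind = events$kind, block = events$block,
    trial = events$trial, is_warmup = as.integer(events$is_warmup)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  stop_if_not(file.exists(path), "events file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    onset_s = as.numeric(df$onset_s), kind = as.character(df$kind),
    block = as.integer(df$block), trial = as.integer(df$trial),
    is_warmup = as.logical(df$is_warmup)
  )
}
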