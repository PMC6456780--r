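#' Group-level MMN parameter distributions
#'
#' Between-subject means and standard deviations of MMN amplitude (signed
#' microvolts at the frontocentral ROI) and latency (ms) for each deviant
#' kind in the three study groups: normal-hearing controls, compensated
#' tinnitus (habituated, low distress) and decompensated tinnitus (high
#' distress). These distributions are the ground truth from which synthetic
#' cohorts are drawn; amplitudes are most negative in the compensated group
#' and least negative (smallest MMN) in the decompensated group for the
#' higher-frequency deviant.
#'
#' @return Tibble with columns `group`, `kind`, `amplitude_mean`,
#'   `amplitude_sd`, `latency_mean`, `latency_sd`.
#' @export
default_group_parameters <- function() {
  tibble::tribble(
    ~group, ~kind, ~amplitude_mean, ~amplitude_sd, ~latency_mean, ~latency_sd,
    "control",       "frequency_high", -5.49, 1.68, 150.27,  7.75,
    "compensated",   "frequency_high", -6.64, 2.08, 158.14, 10.67,
    "decompensated", "frequency_high", -3.78, 1.55, 152.35, 18.03,
    "control",       "frequency_low",  -3.04, 1.65, 149.64, 16.45,
    "compensated",   "frequency_low",  -4.02, 1.95, 140.45, 17.43,
    "decompensated", "frequency_low",  -3.39, 1.66, 146.74, 19.74,
    "control",       "duration",       -3.00, 1.14, 143.60, 15.22,
    "compensated",   "duration",       -3.70, 1.66, 145.83, 15.37,
    "decompensated", "duration",       -2.90, 1.47, 137.44, 15.63,
    "control",       "gap",            -4.20, 1.16, 143.98, 10.99,
    "compensated",   "gap",            -4.03, 2.13, 151.44, 16.68,
    "decompensated", "gap",            -2.85, 1.53, 144.92, 17.74
  )
}

#' Study group labels
#' @return Character vector of the three group labels.
#' @export
study_groups <- function() c("control", "compensated", "decompensated")

#' Background-activity model for the EEG simulator
#'
#' @param pink_exponent Spectral exponent of the 1/f background (power ~
#'   1/f^exponent).
#' @param pink_rms_uV RMS (microvolts) of the broadband 1/f background per
#'   channel.
#' @param alpha_rms_uV RMS of posterior-dominant 10 Hz alpha activity at its
#'   maximal site.
#' @param blink_rate_per_min Mean eye-blink rate (Poisson).
#' @param blink_amp_uV Blink amplitude at the EOG channels.
#' @param line_50hz_rms_uV RMS of 50 Hz mains interference (0 = off).
#' @return A `noise_model` list.
#' @export
noise_model <- function(pink_exponent = 1,
                        pink_rms_uV = 3.5,
                        alpha_rms_uV = 2,
                        blink_rate_per_min = 12,
                        blink_amp_uV = 150,
                        line_50hz_rms_uV = 0) {
  stop_if_not(pink_rms_uV >= 0 && alpha_rms_uV >= 0 && blink_rate_per_min >= 0 &&
                line_50hz_rms_uV >= 0,
              "noise RMS values and rates must be non-negative")
  structure(
    list(pink_exponent = pink_exponent, pink_rms_uV = pink_rms_uV,
         alpha_rms_uV = alpha_rms_uV, blink_rate_per_min = blink_rate_per_min,
         blink_amp_uV = blink_amp_uV, line_50hz_rms_uV = line_50hz_rms_uV),
    class = "noise_model"
  )
}

#' Zero-background noise model (for ground-truth checks)
#' @export
no_noise <- function() {
  noise_model(pink_rms_uV = 0, alpha_rms_uV = 0, blink_rate_per_min = 0,
              line_50hz_rms_uV = 0)
}

#' Gaussian evoked-component kernel
#'
#' Evoked components are modelled as Gaussians in time:
#' `amp * exp(-(t - latency)^2 / (2 width^2))`.
#'
#' @param name Component name (`"N1"`, `"P2"`, `"MMN"`).
#' @param amplitude_uV Signed peak amplitude (microvolts).
#' @param latency_ms Peak latency (ms post-stimulus).
#' @param width_ms Gaussian SD (ms).
#' @return A `component_kernel` list.
#' @export
component_kernel <- function(name, amplitude_uV, latency_ms, width_ms) {
  stop_if_not(width_ms > 0 && latency_ms > 0, "kernel latency and width must be positive")
  structure(list(name = name, amplitude_uV = amplitude_uV,
                 latency_ms = latency_ms, width_ms = width_ms),
            class = "component_kernel")
}

# Kernel sampled on the simulation grid; support truncated at +/- 5 SD.
kernel_samples <- function(kernel, fs) {
  half <- ceiling(5 * kernel$width_ms / 1000 * fs)
  centre <- kernel$latency_ms / 1000 * fs
  idx <- seq(max(0, floor(centre - half)), ceiling(centre + half))
  val <- kernel$amplitude_uV * exp(-((idx - centre) / fs * 1000)^2 /
                                     (2 * kernel$width_ms^2))
  list(offsets = idx, values = val)
}

#' Draw a cohort of subject profiles
#'
#' Per-subject MMN amplitudes and latencies are drawn
#' `Normal(mean, SD)` from [default_group_parameters()], with amplitudes
#' clipped at 0 (an MMN is a negativity) and latencies clipped to
#' `[100, 250]` ms. Obligatory N1/P2 responses are identical across subjects.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer seed; the draw is reproducible under it.
#' @param groups Which groups to simulate.
#' @param params Parameter table in the format of
#'   [default_group_parameters()].
#' @param noise A [noise_model()] shared by all subjects.
#' @return List of `subject_profile` objects.
#' @export
sample_cohort <- function(n_per_group, seed = 1L,
                          groups = study_groups(),
                          params = default_group_parameters(),
                          noise = noise_model()) {
  stop_if_not(n_per_group >= 1, "n_per_group must be >= 1")
  with_seed(seed, {
    profiles <- list()
    i <- 0L
    for (g in groups) {
      pg <- params[params$group == g, ]
      stop_if_not(nrow(pg) > 0, "no parameters for group '%s'", g)
      for (s in seq_len(n_per_group)) {
        i <- i + 1L
        amp <- pmin(0, rnorm(nrow(pg), pg$amplitude_mean, pg$amplitude_sd))
        lat <- pmin(250, pmax(100, rnorm(nrow(pg), pg$latency_mean, pg$latency_sd)))
        profiles[[i]] <- structure(
          list(
            subject_id = sprintf("S%03d", i),
            group = g,
            mmn = tibble::tibble(kind = pg$kind, amplitude_uV = amp,
                                 latency_ms = lat),
            n1 = component_kernel("N1", -2.5, 100, 15),
            p2 = component_kernel("P2", 2.0, 180, 25),
            mmn_width_ms = 25,
            noise = noise,
            seed = sample.int(.Machine$integer.max, 1)
          ),
          class = "subject_profile"
        )
      }
    }
    profiles
  })
}

# --- background generators ---------------------------------------------------

# 1/f^(exponent/2) amplitude-shaped Gaussian noise, one channel per row,
# standardized to unit RMS per channel.
pink_noise <- function(n_channels, n_samples, exponent, fs) {
  m <- next_fast_len(n_samples)
  w <- matrix(rnorm(n_channels * m), nrow = m)
  spec <- mvfft(w)
  f <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * fs / m
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(mvfft(spec * shape, inverse = TRUE))[seq_len(n_samples), , drop = FALSE] / m
  x <- sweep(x, 2, apply(x, 2, rms), "/")
  t(x)
}

# Hann-shaped blink transient, ~300 ms.
blink_kernel <- function(fs, width_s = 0.3) {
  n <- round(width_s * fs)
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Forward-simulate one subject's EEG recording
#'
#' The recording is the linear superposition of stimulus-locked evoked
#' responses and background activity, sampled at 1,024 Hz on the 29-channel
#' scalp montage plus two EOG channels (nose reference). Every stimulus
#' evokes the subject's N1 and P2; deviant trials additionally evoke an MMN
#' Gaussian with the subject's per-kind amplitude and latency, projected
#' through a frontocentral topography whose mastoid gains are sign-inverted
#' (polarity reversal). Background activity comprises 1/f noise, posterior
#' alpha, frontal-dominant eye blinks mirrored on the EOG channels, and
#' optional 50 Hz mains interference.
#'
#' @param profile A `subject_profile` from [sample_cohort()].
#' @param events Event tibble from [generate_paradigm()] /
#'   [schedule_events()].
#' @param noise Noise model; defaults to the profile's.
#' @param sample_rate_hz EEG sampling rate (Hz).
#' @param duration_pad_s Padding after the last stimulus offset (s).
#' @param pre_pad_s Lead-in recorded before the first stimulus (s); event
#'   onsets in the returned recording are on the recording clock, i.e.
#'   shifted by this amount.
#' @param layout Channel layout.
#' @param seed Seed for the background draw; defaults to the profile's.
#' @return An `mmn_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `sample_rate_hz`, `layout`, `events`, `subject_id`,
#'   `group`.
#' @export
simulate_subject <- function(profile, events,
                             noise = profile$noise,
                             sample_rate_hz = 1024,
                             duration_pad_s = 1,
                             pre_pad_s = 1,
                             layout = channel_layout(),
                             seed = profile$seed) {
  fs <- sample_rate_hz
  labels <- layout$labels
  n_ch <- length(labels)
  events$onset_s <- events$onset_s + pre_pad_s   # recording clock
  span <- max(events$onset_s) + 1 + duration_pad_s
  n <- ceiling(span * fs)
  stop_if_not(max(events$onset_s) * fs < n, "event past recording end")
  data <- matrix(0, nrow = n_ch, ncol = n, dimnames = list(labels, NULL))

  topo <- mmn_topography(layout)[labels]
  # one response template per stimulus kind (identical across its trials)
  templates <- list()
  for (k in unique(events$kind)) {
    ks <- list(kernel_samples(profile$n1, fs), kernel_samples(profile$p2, fs))
    if (k != "standard") {
      row <- profile$mmn[profile$mmn$kind == k, ]
      stop_if_not(nrow(row) == 1, "profile lacks MMN parameters for kind '%s'", k)
      ks <- c(ks, list(kernel_samples(
        component_kernel("MMN", row$amplitude_uV, row$latency_ms,
                         profile$mmn_width_ms), fs)))
    }
    off0 <- min(vapply(ks, function(z) min(z$offsets), numeric(1)))
    off1 <- max(vapply(ks, function(z) max(z$offsets), numeric(1)))
    tmpl <- numeric(off1 - off0 + 1)
    for (z in ks) tmpl[z$offsets - off0 + 1] <- tmpl[z$offsets - off0 + 1] + z$values
    templates[[k]] <- list(offset = off0, wave = tmpl)
  }
  for (i in seq_len(nrow(events))) {
    tm <- templates[[events$kind[i]]]
    i0 <- round(events$onset_s[i] * fs) + 1 + tm$offset
    idx <- i0:(i0 + length(tm$wave) - 1)
    ok <- idx >= 1 & idx <= n
    data[, idx[ok]] <- data[, idx[ok]] + outer(topo, tm$wave[ok])
  }

  with_seed(seed, {
    if (noise$pink_rms_uV > 0) {
      data <- data + noise$pink_rms_uV *
        pink_noise(n_ch, n, noise$pink_exponent, fs)
    }
    if (noise$alpha_rms_uV > 0) {
      ag <- alpha_topography(layout)[labels]
      tt <- (seq_len(n) - 1) / fs
      src <- sqrt(2) * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
      data <- data + noise$alpha_rms_uV * outer(ag, src)
    }
    if (noise$blink_rate_per_min > 0 && noise$blink_amp_uV != 0) {
      bg <- blink_topography(layout)[labels]
      bk <- blink_kernel(fs)
      n_blinks <- rpois(1, noise$blink_rate_per_min * n / fs / 60)
      if (n_blinks > 0) {
        at <- sort(round(runif(n_blinks, 1, n - length(bk))))
        for (b in at) {
          idx <- b:(b + length(bk) - 1)
          data[, idx] <- data[, idx] + noise$blink_amp_uV * outer(bg, bk)
        }
      }
    }
    if (noise$line_50hz_rms_uV > 0) {
      tt <- (seq_len(n) - 1) / fs
      data <- data + noise$line_50hz_rms_uV * sqrt(2) *
        matrix(sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi)),
               nrow = n_ch, ncol = n, byrow = TRUE)
    }
    data
  }) -> data

  structure(
    list(data = data, sample_rate_hz = fs, layout = layout, events = events,
         subject_id = profile$subject_id, group = profile$group),
    class = "mmn_recording"
  )
}

#' @export
print.mmn_recording <- function(x, ...) {
  cat(sprintf("<mmn_recording> %s (%s): %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id %||% "?", x$group %||% "?",
              nrow(x$data), ncol(x$data), x$sample_rate_hz, nrow(x$events)))
  invisible(x)
}
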