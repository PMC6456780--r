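#' Deviant kinds of the multifeature oddball paradigm
#'
#' The five stimulus classes: the repeated standard plus four deviant types
#' (frequency shifted up or down by 10\%, shortened duration, inserted silent
#' gap).
#'
#' @return Character vector of the five kind labels.
#' @export
deviant_kinds <- function() {
  c("standard", "frequency_high", "frequency_low", "duration", "gap")
}

#' Frontocentral region of interest
#'
#' The seven frontocentral electrodes where the auditory MMN is maximal and
#' over which amplitude, latency and area under the curve are measured.
#'
#' @return Character vector of ROI channel labels.
#' @export
roi_channels <- function() {
  c("F3", "F4", "Fz", "FC3", "FC4", "FCz", "Cz")
}

#' Standard EEG channel layout
#'
#' Twenty-nine scalp sites of the international 10-10 system (including the
#' mastoids M1/M2) referenced to the tip of the nose, plus two EOG channels
#' (below and at the outer canthus of the left eye).
#'
#' @return An object of class `mmn_layout` with elements `scalp` (29 labels),
#'   `eog` (2 labels), `labels` (all 31, scalp first) and `reference`.
#' @export
channel_layout <- function() {
  scalp <- c(
    "FP1", "FPz", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8", "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8", "P3", "Pz", "P4", "POz", "M1", "M2"
  )
  eog <- c("EOG_lower", "EOG_canthus")
  structure(
    list(scalp = scalp, eog = eog, labels = c(scalp, eog), reference = "nose"),
    class = "mmn_layout"
  )
}

#' Scalp topography of the simulated cortical components
#'
#' Per-channel gains applied to the evoked-component kernels: the
#' frontocentral ROI carries the full component (gain 1), immediately
#' neighbouring sites half of it, distant sites a tenth, and the mastoids a
#' sign-inverted fraction (-0.4) reproducing the polarity reversal expected of
#' an auditory-cortex generator under a nose reference. EOG channels carry no
#' cortical signal.
#'
#' @param layout A channel layout, as from [channel_layout()].
#' @return Named numeric vector of gains in `[-1, 1]`, one per channel.
#' @export
mmn_topography <- function(layout = channel_layout()) {
  g <- setNames(rep(0.1, length(layout$labels)), layout$labels)
  g[roi_channels()] <- 1.0
  neighbours <- c("FP1", "FPz", "FP2", "F7", "F8", "FT7", "FT8",
                  "C3", "C4", "CP3", "CPz", "CP4")
  g[neighbours] <- 0.5
  g[c("M1", "M2")] <- -0.4
  g[layout$eog] <- 0
  g
}

# Frontal-dominant projection of eye blinks; EOG channels see the source at
# full gain, frontopolar sites strongly, and gain decays toward posterior
# sites. Mastoids are taken as blink-free.
blink_topography <- function(layout = channel_layout()) {
  g <- setNames(rep(0.02, length(layout$labels)), layout$labels)
  g[c("FP1", "FPz", "FP2")] <- 0.6
  g[c("F7", "F3", "Fz", "F4", "F8")] <- 0.3
  g[c("FT7", "FC3", "FCz", "FC4", "FT8")] <- 0.15
  g[c("T7", "C3", "Cz", "C4", "T8")] <- 0.05
  g[c("M1", "M2")] <- 0
  g[layout$eog] <- 1.0
  g
}

# Posterior-dominant alpha weights.
alpha_topography <- function(layout = channel_layout()) {
  g <- setNames(rep(0.1, length(layout$labels)), layout$labels)
  g[c("P3", "Pz", "P4", "POz")] <- 1.0
  g[c("TP7", "CP3", "CPz", "CP4", "TP8")] <- 0.6
  g[c("T7", "C3", "Cz", "C4", "T8")] <- 0.3
  g[layout$eog] <- 0
  g
}
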