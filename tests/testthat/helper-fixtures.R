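# Shared fixtures: all synthetic, built in code at test time.

# Shortened paradigm for pipeline tests: 2 blocks of 21 trials, 4 warm-up
# standards each (~41 s of recording instead of ~6 min).
quick_paradigm <- function(trials = 21, warmup = 4, blocks = 2, seed = 1L) {
  paradigm_config(trials_per_block = trials, n_warmup = warmup,
                  n_blocks = blocks, seed = seed)
}

# One subject whose MMN parameters sit exactly on the group means
# (between-subject SDs zeroed), by default without background activity.
flat_profile <- function(group = "decompensated", seed = 5, noise = no_noise()) {
  params <- default_group_parameters()
  params$amplitude_sd <- 0
  params$latency_sd <- 0
  sample_cohort(1, seed = seed, groups = group, params = params,
                noise = noise)[[1]]
}

# Wrap a channels x samples matrix (31 standard channels) as a recording.
toy_recording <- function(data, fs = 1024, events = empty_events()) {
  lay <- channel_layout()
  stopifnot(nrow(data) == length(lay$labels))
  rownames(data) <- lay$labels
  structure(
    list(data = data, sample_rate_hz = fs, layout = lay, events = events,
         subject_id = "TOY", group = "control"),
    class = "mmn_recording"
  )
}

empty_events <- function() {
  tibble::tibble(onset_s = numeric(0), kind = character(0),
                 block = integer(0), trial = integer(0), is_warmup = logical(0))
}

one_event <- function(onset_s, kind = "frequency_high") {
  tibble::tibble(onset_s = onset_s, kind = kind, block = 1L, trial = 1L,
                 is_warmup = FALSE)
}

# Epochs built directly from an array (trials x 31 channels x samples).
toy_epochs <- function(arr, fs = 1024, tmin_ms = -50,
                       kinds = rep("standard", dim(arr)[1]),
                       is_warmup = rep(FALSE, dim(arr)[1])) {
  lay <- channel_layout()
  stopifnot(dim(arr)[2] == length(lay$labels))
  dimnames(arr) <- list(NULL, lay$labels, NULL)
  n_s <- dim(arr)[3]
  offsets <- round(tmin_ms / 1000 * fs) + seq_len(n_s) - 1
  structure(
    list(data = arr, time_ms = offsets / fs * 1000, labels = lay$labels,
         eog = lay$eog,
         info = tibble::tibble(kind = kinds, block = 1L,
                               trial = seq_len(dim(arr)[1]),
                               is_warmup = is_warmup,
                               keep = TRUE, reason = NA_character_),
         sample_rate_hz = fs),
    class = "mmn_epochs"
  )
}

# Independent brute-force one-way ANOVA by explicit sum-of-squares
# decomposition (oracle; kept free of package internals).
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups)
  N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Brute-force one-factor repeated-measures F via explicit SS decomposition.
oracle_rm_F <- function(mat) {
  n <- nrow(mat); c <- ncol(mat)
  gm <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_subj <- c * sum((rowMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (c - 1)) / (ss_err / ((c - 1) * (n - 1)))
}

# Brute-force Mann-Whitney U by counting pairs (0.5 per tie).
oracle_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
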