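# Pipeline entry points tying the stages together: cohort simulation to
# disk, full analysis of a simulated (or recorded) dataset, and a plain-text
# report. These functions are what the `inst/cli/mmn.R` script wraps.

#' Assemble a run configuration
#'
#' All randomness of a run flows from the single `seed`. The configuration
#' can be written to / read from YAML.
#'
#' @param n_per_group Subjects per group.
#' @param groups Group labels to simulate.
#' @param seed Root seed of the run.
#' @param paradigm A [paradigm_config()].
#' @param noise A [noise_model()].
#' @param preprocessing List of preprocessing parameters: `low_hz`,
#'   `high_hz`, `threshold_uV`, `ocular` (`"ica"`, `"regression"` or
#'   `"none"`).
#' @param window_ms MMN analysis window.
#' @return A `run_config` list.
#' @export
run_config <- function(n_per_group = 20,
                       groups = study_groups(),
                       seed = 1L,
                       paradigm = paradigm_config(),
                       noise = noise_model(),
                       preprocessing = list(low_hz = 1, high_hz = 20,
                                            threshold_uV = 50,
                                            ocular = "regression"),
                       window_ms = c(100, 250)) {
  structure(
    list(n_per_group = n_per_group, groups = groups, seed = as.integer(seed),
         paradigm = paradigm, noise = noise, preprocessing = preprocessing,
         window_ms = window_ms),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$paradigm <- unclass(x$paradigm)
  x$noise <- unclass(x$noise)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    n_per_group = x$n_per_group %||% 20,
    groups = unlist(x$groups) %||% study_groups(),
    seed = x$seed %||% 1L,
    paradigm = do.call(paradigm_config, x$paradigm %||% list()),
    noise = do.call(noise_model, x$noise %||% list()),
    preprocessing = x$preprocessing %||% list(low_hz = 1, high_hz = 20,
                                              threshold_uV = 50,
                                              ocular = "regression"),
    window_ms = unlist(x$window_ms) %||% c(100, 250)
  )
}

#' Simulate a cohort and write the recordings to disk
#'
#' Writes one BrainVision recording (plus events CSV) per simulated subject
#' and a `manifest.csv` (`subject_id`, `group`, `seed`, `file`). Refuses to
#' overwrite an existing manifest unless `overwrite = TRUE`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param overwrite Overwrite an existing simulation.
#' @return Invisibly, the manifest tibble.
#' @export
mmn_simulate <- function(config, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  stop_if_not(overwrite || !file.exists(manifest_path),
              "simulation already exists in %s (use overwrite = TRUE)", out_dir)
  profiles <- sample_cohort(config$n_per_group, seed = config$seed,
                            groups = config$groups, noise = config$noise)
  paradigm_seeds <- with_seed(config$seed + 1L,
                              sample.int(.Machine$integer.max, length(profiles)))
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    events <- generate_paradigm(config$paradigm, seed = paradigm_seeds[i])
    rec <- simulate_subject(pr, events)
    f <- file.path(out_dir, pr$subject_id)
    write_recording(rec, f)
    rows[[i]] <- tibble::tibble(subject_id = pr$subject_id, group = pr$group,
                                seed = pr$seed,
                                file = paste0(pr$subject_id, ".vhdr"))
  }
  manifest <- do.call(rbind, rows)
  write.csv(as.data.frame(manifest), manifest_path, row.names = FALSE)
  invisible(manifest)
}

#' Analyse one recording into an MMN feature table
#'
#' Runs band-pass filtering, optional ocular artifact removal, epoching,
#' amplitude rejection, warm-up exclusion, per-condition averaging,
#' difference waves and feature extraction for a single subject.
#'
#' @param rec An `mmn_recording`.
#' @param preprocessing Preprocessing parameter list (see [run_config()]).
#' @param window_ms MMN analysis window (ms).
#' @param subject_id,group Metadata for the feature rows; default to the
#'   recording's.
#' @return Feature tibble (one row per deviant kind); attribute
#'   `n_rejected` carries the amplitude-rejection count.
#' @export
analyze_recording <- function(rec,
                              preprocessing = list(low_hz = 1, high_hz = 20,
                                                   threshold_uV = 50,
                                                   ocular = "regression"),
                              window_ms = c(100, 250),
                              subject_id = rec$subject_id,
                              group = rec$group) {
  rec <- bandpass(rec, preprocessing$low_hz %||% 1, preprocessing$high_hz %||% 20)
  oc <- preprocessing$ocular %||% "regression"
  if (oc != "none") rec <- remove_ocular(rec, method = oc)
  ep <- extract_epochs(rec)
  ep <- reject_epochs(ep, preprocessing$threshold_uV %||% 50)
  ep <- drop_warmup_standards(ep)
  ev <- average_by_condition(ep)
  kinds <- setdiff(names(ev), "standard")
  dw <- lapply(ev[kinds], difference_wave, standard = ev$standard)
  feats <- extract_features(dw, subject_id = subject_id %||% NA_character_,
                            group = group %||% NA_character_,
                            window_ms = window_ms, kinds = kinds)
  attr(feats, "n_rejected") <- attr(ep, "n_rejected")
  feats
}

#' Analyse a simulated dataset end to end
#'
#' Reads every recording named in the manifest, extracts per-subject MMN
#' features, runs the group-statistics battery, and writes `features.csv`,
#' `stats.json` and a `run_log.json` capturing parameters, seeds and
#' rejection counts.
#'
#' @param in_dir Directory holding `manifest.csv` and the recordings.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param config A [run_config()] supplying preprocessing parameters.
#' @return Invisibly, a list with `features` and `stats`.
#' @export
mmn_analyze <- function(in_dir, out_dir = in_dir, config = run_config()) {
  manifest_path <- file.path(in_dir, "manifest.csv")
  stop_if_not(file.exists(manifest_path), "manifest not found: %s", manifest_path)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- vector("list", nrow(manifest))
  n_rej <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- read_recording(file.path(in_dir, manifest$file[i]),
                          require_channels = c(roi_channels(), "M1", "M2"))
    f <- tryCatch(
      analyze_recording(rec, config$preprocessing, config$window_ms,
                        subject_id = manifest$subject_id[i],
                        group = manifest$group[i]),
      error = function(e) stop("analysis failed for ", manifest$subject_id[i],
                               ": ", conditionMessage(e), call. = FALSE)
    )
    n_rej[i] <- attr(f, "n_rejected") %||% NA_integer_
    feats[[i]] <- f
  }
  features <- do.call(rbind, feats)
  stats <- run_study(features)
  write_features(features, file.path(out_dir, "features.csv"))
  write_stats_bundle(stats, file.path(out_dir, "stats.json"))
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = nrow(manifest),
         preprocessing = config$preprocessing,
         window_ms = config$window_ms,
         rejected_per_subject = setNames(as.list(n_rej), manifest$subject_id)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(features = features, stats = stats))
}

#' Print a stats bundle as a plain-text report
#'
#' One line per test (feature, deviant/group, statistic, df, p) in a
#' deterministic order.
#'
#' @param stats An `mmn_stats_bundle` or the path of a `stats.json`.
#' @param file Connection or filename passed to [cat()]; default stdout.
#' @return Invisibly, the report lines.
#' @export
mmn_report <- function(stats, file = "") {
  if (is.character(stats) && length(stats) == 1) stats <- read_stats_bundle(stats)
  lines <- character(0)
  fmt_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
  if (!is.null(stats$oneway) && nrow(stats$oneway) > 0) {
    ow <- stats$oneway[order(stats$oneway$feature, stats$oneway$deviant_kind), ]
    lines <- c(lines, "Between-group one-way ANOVA",
               sprintf("  %-13s %-15s F(%d,%d) = %6.2f  p = %s",
                       ow$feature, ow$deviant_kind, ow$df1, ow$df2, ow$F,
                       fmt_p(ow$p)))
  }
  if (!is.null(stats$rm) && nrow(stats$rm) > 0) {
    rm_ <- stats$rm[order(stats$rm$group, stats$rm$feature), ]
    lines <- c(lines, "Within-group repeated-measures ANOVA",
               sprintf("  %-13s %-15s F(%d,%d) = %6.2f  p = %s",
                       rm_$group, rm_$feature, rm_$df1, rm_$df2, rm_$F,
                       fmt_p(rm_$p)))
  }
  if (length(lines) == 0) lines <- "no tests in bundle"
  cat(paste(lines, collapse = "\n"), "\n", sep = "", file = file)
  invisible(lines)
}
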