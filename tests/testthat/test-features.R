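test_that("peak finding recovers the analytic minimum of a half-sine dip", {
  t_ms <- seq(0, 900, by = 1)
  w <- numeric(length(t_ms))
  in_dip <- t_ms >= 100 & t_ms <= 250
  w[in_dip] <- -5 * sin(pi * (t_ms[in_dip] - 100) / 150)
  pk <- find_peak(w, t_ms)
  expect_equal(pk$latency_ms, 175)
  expect_equal(pk$raw_value_uV, -5)
})

test_that("an all-zero wave peaks at the window start by tie-break", {
  t_ms <- seq(-50, 900, by = 2)
  pk <- find_peak(numeric(length(t_ms)), t_ms)
  expect_identical(pk$raw_value_uV, 0)
  expect_equal(pk$latency_ms, t_ms[which(t_ms >= 100)[1]])
})

test_that("peak finding matches an exhaustive scan on random waves", {
  set.seed(30)
  t_ms <- seq(-50, 900, length.out = 974)
  for (i in 1:100) {
    w <- as.vector(arima.sim(list(ar = 0.95), 974))
    pk <- find_peak(w, t_ms)
    win <- which(t_ms >= 100 & t_ms <= 250)
    vals <- w[win]
    expect_identical(pk$raw_value_uV, min(vals))
    expect_identical(pk$latency_ms, t_ms[win[which(vals == min(vals))[1]]])
  }
})

test_that("the reference level is the nearest local maximum, 0 as fallback", {
  t_ms <- seq(0, 300, by = 1)
  # bump to +2 at 120 ms, dip to -5 at 160 ms
  w <- 2 * exp(-(t_ms - 120)^2 / 50) - 5 * exp(-(t_ms - 160)^2 / 200)
  pk <- find_peak(w, t_ms)
  ref <- reference_extremum(w, t_ms, pk)
  expect_equal(ref, max(w), tolerance = 1e-6)

  mono <- seq(-1, 1, length.out = 301)           # no interior maximum
  pk2 <- find_peak(mono, t_ms, window_ms = c(100, 250))
  expect_identical(reference_extremum(mono, t_ms, pk2), 0)
})

test_that("reference search matches a brute-force derivative-sign scan", {
  set.seed(31)
  t_ms <- seq(-50, 900, length.out = 500)
  for (i in 1:100) {
    w <- as.vector(arima.sim(list(ar = c(1.5, -0.55)), 500))
    pk <- find_peak(w, t_ms)
    ref <- reference_extremum(w, t_ms, pk)
    # oracle: scan every interior sample for a rise-then-fall sign change
    cand <- integer(0)
    for (j in 2:(length(w) - 1)) {
      if (w[j] > w[j - 1] && w[j] >= w[j + 1]) cand <- c(cand, j)
    }
    if (length(cand) == 0) {
      expect_identical(ref, 0)
    } else {
      d <- abs(t_ms[cand] - pk$latency_ms)
      nearest <- cand[d == min(d)]
      pick <- if (any(t_ms[nearest] <= pk$latency_ms)) {
        max(nearest[t_ms[nearest] <= pk$latency_ms])
      } else min(nearest)
      expect_identical(ref, w[pick])
    }
  }
})

test_that("AUC of a triangular dip is the exact triangle area", {
  t_ms <- seq(0, 900, by = 1)
  w <- numeric(length(t_ms))
  up <- t_ms >= 100 & t_ms <= 150
  down <- t_ms > 150 & t_ms <= 200
  w[up] <- -4 * (t_ms[up] - 100) / 50
  w[down] <- -4 * (200 - t_ms[down]) / 50
  pk <- find_peak(w, t_ms)
  expect_equal(area_under_curve(w, t_ms, pk, reference_level = 0),
               0.5 * 100 * 4)
})

test_that("AUC of a half-sine dip matches its closed form (2/pi) d w", {
  t_ms <- seq(0, 900, by = 1000 / 1024)
  d <- 6
  wdt <- 120
  w <- numeric(length(t_ms))
  dip <- t_ms >= 130 & t_ms <= 130 + wdt
  w[dip] <- -d * sin(pi * (t_ms[dip] - 130) / wdt)
  pk <- find_peak(w, t_ms)
  expect_equal(area_under_curve(w, t_ms, pk, reference_level = 0),
               2 / pi * d * wdt, tolerance = 0.01)
})

test_that("AUC matches an independent crossing-bounded trapezoid oracle", {
  set.seed(32)
  t_ms <- seq(-50, 900, length.out = 974)
  for (i in 1:100) {
    w <- as.vector(arima.sim(list(ar = c(1.5, -0.55)), 974))
    pk <- find_peak(w, t_ms)
    ref <- reference_extremum(w, t_ms, pk)
    if (pk$raw_value_uV >= ref) next
    # oracle: walk out from the peak, clip segments at interpolated crossings
    f <- ref - w                       # positive inside the deflection
    ip <- which.min(abs(t_ms - pk$latency_ms))
    lo <- ip; while (lo > 1 && f[lo - 1] > 0) lo <- lo - 1
    hi <- ip; while (hi < length(f) && f[hi + 1] > 0) hi <- hi + 1
    area <- 0
    if (hi > lo) {
      for (j in lo:(hi - 1)) {
        area <- area + (f[j] + f[j + 1]) / 2 * (t_ms[j + 1] - t_ms[j])
      }
    }
    if (lo > 1) {
      dt <- t_ms[lo] - t_ms[lo - 1]
      area <- area + f[lo] / 2 * dt * f[lo] / (f[lo] - f[lo - 1])
    }
    if (hi < length(f)) {
      dt <- t_ms[hi + 1] - t_ms[hi]
      area <- area + f[hi] / 2 * dt * f[hi] / (f[hi] - f[hi + 1])
    }
    got <- area_under_curve(w, t_ms, pk, ref)
    expect_equal(got, area, tolerance = 1e-8)
  }
})

test_that("AUC is zero with a warning when the peak is not below reference", {
  t_ms <- seq(0, 900, by = 1)
  w <- rep(1, length(t_ms))
  pk <- list(latency_ms = 150, raw_value_uV = 1)
  expect_warning(a <- area_under_curve(w, t_ms, pk, reference_level = 0.5),
                 "reference")
  expect_identical(a, 0)
})

test_that("scaling and shifting transform amplitude, AUC and latency correctly", {
  set.seed(33)
  t_ms <- seq(-50, 900, length.out = 974)
  # flanking bumps keep the deflection bounded by true reference crossings
  w <- -6 * exp(-(t_ms - 170)^2 / (2 * 25^2)) +
    1.5 * exp(-(t_ms - 90)^2 / (2 * 20^2)) +
    2 * exp(-(t_ms - 280)^2 / (2 * 20^2))
  pk <- find_peak(w, t_ms)
  ref <- reference_extremum(w, t_ms, pk)
  auc <- area_under_curve(w, t_ms, pk, ref)

  for (c_scale in c(0.5, 2, 3.7)) {
    pk_c <- find_peak(c_scale * w, t_ms)
    ref_c <- reference_extremum(c_scale * w, t_ms, pk_c)
    expect_equal(pk_c$latency_ms, pk$latency_ms)
    expect_equal(pk_c$raw_value_uV - ref_c,
                 c_scale * (pk$raw_value_uV - ref))
    expect_equal(area_under_curve(c_scale * w, t_ms, pk_c, ref_c),
                 c_scale * auc, tolerance = 1e-10)
  }

  dt <- 30                        # whole-sample shift within the window
  shift_n <- round(dt / (t_ms[2] - t_ms[1]))
  w_s <- c(rep(w[1], shift_n), w[1:(length(w) - shift_n)])
  pk_s <- find_peak(w_s, t_ms)
  ref_s <- reference_extremum(w_s, t_ms, pk_s)
  expect_equal(pk_s$latency_ms - pk$latency_ms, shift_n * (t_ms[2] - t_ms[1]))
  expect_equal(pk_s$raw_value_uV - ref_s, pk$raw_value_uV - ref)
  expect_equal(area_under_curve(w_s, t_ms, pk_s, ref_s), auc,
               tolerance = 1e-6)
})

test_that("feature extraction assembles one row per deviant kind", {
  pr <- flat_profile("decompensated")
  cfg <- quick_paradigm()
  ev <- generate_paradigm(cfg, seed = 9)
  rec <- simulate_subject(pr, ev, noise = no_noise())
  ep <- drop_warmup_standards(extract_epochs(rec))
  avg <- average_by_condition(ep)
  kinds <- setdiff(names(avg), "standard")
  dw <- lapply(avg[kinds], difference_wave, standard = avg$standard)
  feats <- extract_features(dw, subject_id = "S1", group = "decompensated")
  expect_identical(nrow(feats), 4L)
  expect_setequal(feats$deviant_kind, kinds)
  expect_true(all(feats$amplitude_uV < 0))
  expect_true(all(feats$reversal_ok))
  m <- merge(feats, pr$mmn, by.x = "deviant_kind", by.y = "kind")
  expect_true(all(abs(m$amplitude_uV.x - m$amplitude_uV.y) /
                    abs(m$amplitude_uV.y) < 0.15))
  expect_true(all(abs(m$latency_ms.x - m$latency_ms.y) < 5))

  # a missing kind yields NA features, never fabricated numbers
  feats2 <- extract_features(dw[setdiff(kinds, "gap")], subject_id = "S1",
                             group = "decompensated")
  expect_true(is.na(feats2$amplitude_uV[feats2$deviant_kind == "gap"]))
  expect_identical(nrow(feats2), 4L)
})

test_that("all-zero difference waves give zero amplitude and AUC", {
  arr <- array(0, dim = c(2, 31, 974))
  ep <- toy_epochs(arr, kinds = c("standard", "gap"))
  avg <- average_by_condition(ep)
  dw <- list(gap = difference_wave(avg$gap, avg$standard))
  feats <- extract_features(dw, kinds = "gap")
  expect_identical(feats$amplitude_uV, 0)
  expect_identical(feats$auc_uVms, 0)
})

test_that("feature tables round-trip through CSV", {
  pr <- flat_profile()
  feats <- tibble::tibble(
    subject_id = "S1", group = "control", deviant_kind = "gap",
    amplitude_uV = -4.2, latency_ms = 150.5, auc_uVms = 240.1,
    reference_uV = 0.3, reversal_ok = TRUE
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, p)
  expect_equal(as.data.frame(read_features(p)), as.data.frame(feats))
})
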