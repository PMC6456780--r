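make_sine_rec <- function(freq_hz, n = 10240, fs = 1024, amp = 1) {
  tt <- (seq_len(n) - 1) / fs
  toy_recording(matrix(rep(amp * sin(2 * pi * freq_hz * tt), each = 31),
                       nrow = 31, byrow = FALSE), fs = fs)
}

test_that("band-pass keeps 10 Hz, suppresses 50 Hz and removes DC", {
  r50 <- bandpass(make_sine_rec(50))
  expect_lt(sd(r50$data[5, ]) / sd(make_sine_rec(50)$data[5, ]), 0.01)
  r10 <- bandpass(make_sine_rec(10))
  expect_equal(sd(r10$data[5, ]) / sd(make_sine_rec(10)$data[5, ]), 1,
               tolerance = 0.05)
  rdc <- bandpass(toy_recording(matrix(100, nrow = 31, ncol = 10240)))
  expect_lt(abs(mean(rdc$data[5, ])), 1)
})

test_that("the frequency-domain filter matches filtfilt away from edges", {
  set.seed(4)
  rec <- toy_recording(matrix(rnorm(31 * 8192), nrow = 31))
  a <- bandpass(rec, method = "fft")
  b <- bandpass(rec, method = "filtfilt")
  # the two realizations share |H|^2 exactly and differ only in boundary
  # handling; the 1 Hz poles ring for seconds, so compare well inside
  mid <- 3073:5120
  expect_lt(max(abs(a$data[, mid] - b$data[, mid])) / sd(b$data[, mid]), 0.06)
})

test_that("filtering is linear", {
  set.seed(1)
  x <- toy_recording(matrix(rnorm(31 * 4096), nrow = 31))
  y <- toy_recording(matrix(rnorm(31 * 4096), nrow = 31))
  z <- toy_recording(2 * x$data - 3 * y$data)
  lhs <- bandpass(z)$data
  rhs <- 2 * bandpass(x)$data - 3 * bandpass(y)$data
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("invalid bands are rejected", {
  rec <- make_sine_rec(10, n = 1024)
  expect_error(bandpass(rec, low_hz = 0), "invalid band")
  expect_error(bandpass(rec, low_hz = 30, high_hz = 20), "invalid band")
  expect_error(bandpass(rec, high_hz = 600), "invalid band")
})

test_that("ICA removes blink components and leaves clean recordings alone", {
  pr <- flat_profile("control",
                     noise = noise_model(pink_rms_uV = 0.5, alpha_rms_uV = 0,
                                         blink_rate_per_min = 30))
  ev <- one_event(25, "standard")
  rec <- simulate_subject(pr, ev, seed = 44)
  eog <- rec$data["EOG_lower", ]
  blink_win <- which(abs(eog) > 30)
  expect_gt(length(blink_win), 100)          # fixture sanity: blinks present
  cleaned <- remove_ocular(rec, method = "ica")
  expect_gte(attr(cleaned, "n_removed"), 1)
  reduction <- 1 - sqrt(mean(cleaned$data["FP1", blink_win]^2)) /
    sqrt(mean(rec$data["FP1", blink_win]^2))
  expect_gte(reduction, 0.7)

  # nothing ocular: reconstruction returns the input
  quiet <- simulate_subject(flat_profile("control"), ev, noise = no_noise())
  same <- remove_ocular(quiet, method = "ica")
  expect_lt(sqrt(mean((same$data - quiet$data)^2)), 1)
})

test_that("MMN amplitude survives blink removal within 10% of truth", {
  pr <- flat_profile("decompensated",
                     noise = noise_model(pink_rms_uV = 0, alpha_rms_uV = 0,
                                         blink_rate_per_min = 20))
  # full-length paradigm: blink/ERP sample correlation shrinks with duration
  ev <- generate_paradigm(paradigm_config(), seed = 8)
  rec <- simulate_subject(pr, ev, seed = 15)
  feats <- analyze_recording(rec, preprocessing = list(ocular = "ica"))
  truth <- pr$mmn
  m <- merge(feats, truth, by.x = "deviant_kind", by.y = "kind")
  expect_true(all(abs(m$amplitude_uV.x - m$amplitude_uV.y) /
                    abs(m$amplitude_uV.y) < 0.10))
})

test_that("regression fallback also suppresses blinks", {
  pr <- flat_profile("control",
                     noise = noise_model(pink_rms_uV = 0.5, alpha_rms_uV = 0,
                                         blink_rate_per_min = 30))
  ev <- one_event(25, "standard")
  rec <- simulate_subject(pr, ev, seed = 44)
  blink_win <- which(abs(rec$data["EOG_lower", ]) > 30)
  cleaned <- remove_ocular(rec, method = "regression")
  expect_identical(attr(cleaned, "ocular_method"), "regression")
  reduction <- 1 - sqrt(mean(cleaned$data["FP1", blink_win]^2)) /
    sqrt(mean(rec$data["FP1", blink_win]^2))
  expect_gte(reduction, 0.7)
})

test_that("epoching cuts one baseline-corrected epoch per event", {
  pr <- flat_profile("control")
  cfg <- quick_paradigm()
  ev <- generate_paradigm(cfg, seed = 5)
  rec <- simulate_subject(pr, ev, noise = no_noise())
  ep <- extract_epochs(rec)
  expect_identical(dim(ep$data)[1], nrow(ev))
  expect_equal(dim(ep$data)[3], round(0.95 * 1024) + 1)
  expect_equal(ep$time_ms[1], -51 / 1024 * 1000)
  expect_equal(max(ep$time_ms), 922 / 1024 * 1000)
  # prestimulus mean is zero after baseline correction
  base <- ep$time_ms <= 0
  expect_lt(max(abs(apply(ep$data[, , base], c(1, 2), mean))), 1e-9)
})

test_that("a constant channel epochs to all zeros after baseline", {
  rec <- toy_recording(matrix(7.5, nrow = 31, ncol = 4096),
                       events = one_event(1, "standard"))
  ep <- extract_epochs(rec)
  expect_true(all(ep$data == 0))
})

test_that("events lacking full epoch support are flagged, not dropped", {
  rec <- toy_recording(matrix(0, nrow = 31, ncol = 2048),
                       events = rbind(one_event(0.5), one_event(1.9)))
  ep <- extract_epochs(rec)
  expect_identical(dim(ep$data)[1], 2L)
  expect_identical(ep$info$keep, c(TRUE, FALSE))
  expect_identical(ep$info$reason[2], "edge")
})

test_that("amplitude rejection flags exactly the over-threshold trials", {
  set.seed(10)
  arr <- array(rnorm(20 * 31 * 100, sd = 5), dim = c(20, 31, 100))
  arr[7, which(channel_layout()$labels == "Cz"), 40] <- 60   # spike on Cz
  arr[3, which(channel_layout()$labels == "EOG_lower"), ] <- 200  # EOG only
  ep <- reject_epochs(toy_epochs(arr), threshold_uV = 50)
  expect_false(ep$info$keep[7])
  expect_identical(ep$info$reason[7], "amplitude")
  expect_true(ep$info$keep[3])               # EOG excluded from the criterion

  # oracle: brute-force scan over scalp channels
  scalp_idx <- which(!channel_layout()$labels %in% channel_layout()$eog)
  oracle <- vapply(seq_len(20), function(i) max(abs(arr[i, scalp_idx, ])) > 50,
                   TRUE)
  expect_identical(!ep$info$keep, oracle)
})

test_that("all-zero epochs are never rejected and total rejection errors", {
  arr0 <- array(0, dim = c(4, 31, 50))
  expect_true(all(reject_epochs(toy_epochs(arr0))$info$keep))
  arr_big <- array(100, dim = c(4, 31, 50))
  expect_error(reject_epochs(toy_epochs(arr_big)), "threshold")
})

test_that("rejection is permutation-equivariant", {
  set.seed(11)
  arr <- array(rnorm(30 * 31 * 60, sd = 14), dim = c(30, 31, 60))
  ep <- reject_epochs(toy_epochs(arr), threshold_uV = 50)
  perm <- sample(30)
  ep_p <- reject_epochs(toy_epochs(arr[perm, , , drop = FALSE]),
                        threshold_uV = 50)
  expect_identical(ep_p$info$keep, ep$info$keep[perm])
})

test_that("warm-up standards are flagged idempotently", {
  cfg <- paradigm_config()
  ev <- generate_paradigm(cfg, seed = 2)
  ev$onset_s <- ev$onset_s + 1              # recording lead-in
  fs <- 64  # coarse grid: only the bookkeeping is under test
  rec <- toy_recording(matrix(0, nrow = 31, ncol = ceiling(360 * fs)),
                       fs = fs, events = ev)
  ep <- drop_warmup_standards(extract_epochs(rec))
  expect_identical(sum(ep$info$reason == "warmup", na.rm = TRUE), 40L)
  ep2 <- drop_warmup_standards(ep)
  expect_identical(ep2$info, ep$info)

  ev0 <- generate_paradigm(paradigm_config(n_warmup = 0), seed = 2)
  ev0$onset_s <- ev0$onset_s + 1
  rec0 <- toy_recording(matrix(0, nrow = 31, ncol = ceiling(400 * fs)),
                        fs = fs, events = ev0)
  ep0 <- drop_warmup_standards(extract_epochs(rec0))
  expect_identical(sum(ep0$info$reason == "warmup", na.rm = TRUE), 0L)
})

test_that("epoch sets round-trip through the JSON+binary container", {
  set.seed(12)
  arr <- array(rnorm(6 * 31 * 40), dim = c(6, 31, 40))
  ep <- toy_epochs(arr, kinds = rep(c("standard", "gap"), 3))
  ep$info$keep[2] <- FALSE
  ep$info$reason[2] <- "amplitude"
  p <- withr::local_tempfile(fileext = ".epo")
  write_epochs(ep, p)
  back <- read_epochs(p)
  expect_lt(max(abs(back$data - ep$data)), 1e-6)
  expect_equal(back$time_ms, ep$time_ms)
  expect_identical(back$labels, ep$labels)
  expect_identical(back$info$keep, ep$info$keep)
  expect_identical(back$info$kind, ep$info$kind)
})
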