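test_that("average re-reference reconstructs the reference and zeroes means", {
  # hand-computed 3-channel example
  rec <- nap_recording(matrix(c(1, 2, 3), 3, 1), c("A", "B", "C"), 100)
  rr <- rereference_average(rec, "FCz")
  expect_equal(unname(rr$data[, 1]), c(-1, 0, 1, -2))

  # identical channels become zero; reference = -signal
  x <- rnorm(50)
  rec2 <- nap_recording(rbind(x, x), c("A", "B"), 100)
  rr2 <- rereference_average(rec2, "ref")
  expect_equal(max(abs(rr2$data[1:2, ])), 0)
  expect_equal(unname(rr2$data[3, ]), -x)

  # algebraic identity: every output channel sums with n * reference / n,
  # i.e. data-channel mean equals the reconstructed reference at each sample
  rec3 <- nap_recording(matrix(rnorm(200), 4), paste0("c", 1:4), 100)
  rr3 <- rereference_average(rec3, "ref")
  expect_equal(colMeans(rr3$data[1:4, ]), unname(-rr3$data["ref", ] * 0),
               tolerance = 1e-12)
  expect_equal(unname(rr3$data["ref", ]), -colMeans(rec3$data))

  expect_error(rereference_average(rec, "A"), "duplicates")
})

test_that("line-noise regression is deep at 60 Hz and narrow elsewhere", {
  rate <- 250
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  psd_at <- function(x, f) {
    w <- napstat:::welch_psd(x, rate, 4 * rate)
    w$psd[which.min(abs(w$freq - f))]
  }
  # pure 60 Hz: >= 20 dB attenuation
  rec <- nap_recording(matrix(sin(2 * pi * 60 * t), 1), "Cz", rate)
  out <- remove_line_noise(rec, 60)
  expect_gt(10 * log10(psd_at(rec$data[1, ], 60) / psd_at(out$data[1, ], 60)),
            20)
  # 10 Hz tone untouched within 1 dB
  rec2 <- nap_recording(matrix(sin(2 * pi * 10 * t), 1), "Cz", rate)
  out2 <- remove_line_noise(rec2, 60)
  expect_lt(abs(10 * log10(psd_at(rec2$data[1, ], 10) /
                             psd_at(out2$data[1, ], 10))), 1)
  # noise floor unchanged within 1 dB in presence of 60 Hz
  set.seed(1)
  nse <- rnorm(length(t))
  rec3 <- nap_recording(matrix(sin(2 * pi * 60 * t) + nse, 1), "Cz", rate)
  out3 <- remove_line_noise(rec3, 60)
  for (f in c(10, 30, 45)) {
    expect_lt(abs(10 * log10(psd_at(rec3$data[1, ], f) /
                               psd_at(out3$data[1, ], f))), 1)
  }
  expect_error(remove_line_noise(rec, 200), "Nyquist")
})

test_that("bad-channel rejection: degenerate, single outlier, two-pass masking", {
  rate <- 250
  # identical channels: zero spread, nothing flagged
  x <- rnorm(1000)
  reci <- nap_recording(matrix(rep(x, 5), 5, byrow = TRUE),
                        paste0("c", 1:5), rate)
  expect_equal(nrow(detect_bad_channels(reci)), 0)

  # one channel scaled x100 among 10 iid channels
  set.seed(2)
  X <- matrix(rnorm(10 * 5000), 10)
  X[4, ] <- X[4, ] * 100
  rec <- nap_recording(X, paste0("c", 1:10), rate)
  bad <- detect_bad_channels(rec)
  expect_equal(bad$channel, "c4")

  # masking: huge channel A inflates the scale and hides B until pass 2
  set.seed(3)
  Y <- matrix(rnorm(12 * 5000), 12)
  Y[1, ] <- Y[1, ] * 100
  Y[2, ] <- Y[2, ] * 3.2
  rec2 <- nap_recording(Y, paste0("c", 1:12), rate)
  bad2 <- detect_bad_channels(rec2)
  expect_setequal(bad2$channel, c("c1", "c2"))
  expect_equal(bad2$pass[bad2$channel == "c1"], 1)
  expect_equal(bad2$pass[bad2$channel == "c2"], 2)

  expect_error(detect_bad_channels(
    nap_recording(matrix(rnorm(300), 3), paste0("c", 1:3), rate)),
    "4 channels")
})

test_that("gain-corrupted channels are recovered without false positives", {
  # k = 2 corrupted channels in the full 55-channel montage
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(55 * 7500), 55)
    bad <- sample(55, 2)
    X[bad, ] <- X[bad, ] * 20
    det <- detect_bad_channels(nap_recording(X, montage_55(), 250))
    setequal(det$channel, montage_55()[bad])
  }, logical(1))
  expect_true(all(ok))

  # clean synthetic recordings: no channel ever flagged
  fp <- vapply(1:10, function(s) {
    sp <- cohort_spec(n_pairs = 1, nap_duration = 120, seed = s)
    g <- generate_eeg(sp, generate_hypnogram(sp, s), s)
    bp <- bandpass_recording(rereference_average(g$recording, "FCz"), 1, 250)
    nrow(detect_bad_channels(bp))
  }, numeric(1))
  expect_equal(sum(fp), 0)
})

test_that("ocular ICA removes frontal low-frequency sources and only those", {
  rate <- 250
  n <- 30 * rate
  set.seed(5)
  chans <- montage_8()
  # no ocular source: identity path
  recn <- nap_recording(matrix(rnorm(8 * n), 8) * 10, chans, rate)
  resn <- suppressWarnings(remove_ocular_components(recn))
  expect_equal(sum(resn$components$removed), 0)
  rel_err <- sqrt(mean((resn$recording$data - recn$data)^2)) /
    sqrt(mean(recn$data^2))
  expect_lt(rel_err, 0.01)

  # frontal-dominant blink source: removed, frontal 0.5-5 Hz variance halved
  blink <- numeric(n)
  for (b in round(seq(2, 28, by = 2) * rate)) {
    blink[b:(b + 75)] <- blink[b:(b + 75)] + 120 * sin(pi * (0:75) / 75)^2
  }
  X <- 10 * matrix(rnorm(8 * n), 8) +
    outer(napstat:::ocular_weights(chans), blink)
  rec <- nap_recording(X, chans, rate)
  res <- suppressWarnings(remove_ocular_components(rec))
  expect_gte(sum(res$components$removed), 1)
  lowvar <- function(v) var(napstat:::butter_filtfilt(v, rate, 0.5, 5))
  expect_lt(lowvar(res$recording$data[1, ]), 0.5 * lowvar(rec$data[1, ]))
  expect_true(all(res$components$score >= 0 & res$components$score <= 1))
})

test_that("amplitude mask: strict threshold and exact +-200 ms dilation", {
  rate <- 250
  x <- numeric(1000)
  x[251] <- 150            # t = 1.0 s
  m <- mark_amplitude_artifacts(nap_recording(matrix(x, 1), "Cz", rate))
  expect_equal(sum(m), 101)
  expect_equal(range(which(m[1, ])), c(201, 301))  # t in [0.8, 1.2] s

  # all-zero signal: empty mask
  m0 <- mark_amplitude_artifacts(nap_recording(matrix(0, 1, 500), "Cz", rate))
  expect_equal(sum(m0), 0)

  # exactly 100 uV is clean (strict >)
  x2 <- numeric(500); x2[100] <- 100
  m2 <- mark_amplitude_artifacts(nap_recording(matrix(x2, 1), "Cz", rate))
  expect_equal(sum(m2), 0)

  # dilation symmetry for interior flags
  margin <- round(0.2 * rate)
  flagged <- which(m[1, ])
  core <- 251
  expect_true(all((core - margin):(core + margin) %in% flagged))
})

test_that("power-epoch mask flags high-power epochs one-sidedly", {
  rate <- 250
  elen <- 2 * rate
  # amplified epoch among quiet ones
  set.seed(4)
  x <- rnorm(50 * elen)
  x[(10 * elen + 1):(11 * elen)] <- x[(10 * elen + 1):(11 * elen)] * 10
  m <- mark_power_artifacts(nap_recording(matrix(x, 1), "Cz", rate))
  expect_equal(unique(ceiling(which(m[1, ]) / elen)), 11)

  # constant sinusoid: zero across-epoch variance, nothing flagged
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  ms <- mark_power_artifacts(
    nap_recording(matrix(10 * sin(2 * pi * 5 * t), 1), "Cz", rate))
  expect_equal(sum(ms), 0)

  # stationary noise: one-sided tail keeps flagged fraction < 2%
  set.seed(6)
  xs <- rnorm(1000 * elen)
  mf <- mark_power_artifacts(nap_recording(matrix(xs, 1), "Cz", rate))
  expect_lt(mean(mf), 0.02)
})

test_that("saturated channels are dropped strictly above 20% and masks recomputed", {
  rate <- 250
  n <- 100 * rate
  cfg <- preprocess_config()
  mk <- function(frac) {
    x <- numeric(n)
    # isolated spikes every second so dilation windows do not overlap:
    # each spike flags 101 samples = 0.404% of a 100-s record
    k <- round(frac * n / 101)
    x[seq(1000, by = rate, length.out = k)] <- 150
    x
  }
  X <- rbind(mk(0.199), mk(0.25), rnorm(n))
  rec <- nap_recording(X, c("borderline", "saturated", "clean"), rate)
  amp <- mark_amplitude_artifacts(rec, cfg)
  res <- drop_saturated_channels(rec, amp, cfg)
  expect_equal(res$dropped, "saturated")
  expect_true(all(c("borderline", "clean") %in% res$recording$channel_names))
  # recomputation happened on survivors only
  expect_equal(rownames(res$mask$bad_samples), c("borderline", "clean"))
})

test_that("spherical-spline interpolation recovers smooth scalp fields", {
  pos <- montage_positions(montage_55())
  # constant field: exact
  recc <- nap_recording(matrix(5, 55, 3), pos$channel, 100)
  outc <- interpolate_channels(recc, c("Cz", "P3"), pos)
  expect_lt(max(abs(outc$data[c("Cz", "P3"), ] - 5)) / 5, 0.01)

  # first-order spherical harmonic within 5% RMS
  v <- pos$y
  rech <- nap_recording(matrix(v, ncol = 1), pos$channel, 100)
  outh <- interpolate_channels(rech, c("Cz", "F3"), pos)
  err <- sqrt(mean((outh$data[c("Cz", "F3"), 1] -
                      rech$data[c("Cz", "F3"), 1])^2)) /
    sqrt(mean(v^2))
  expect_lt(err, 0.05)

  # idempotence: repeating the interpolation reproduces it exactly
  out2 <- interpolate_channels(outh, c("Cz", "F3"), pos)
  expect_identical(out2$data, outh$data)

  expect_error(
    interpolate_channels(nap_recording(matrix(rnorm(15), 5),
                                       c("Cz", "Pz", "Fz", "Oz", "QQ1"), 100),
                         "QQ1",
                         montage_positions(c("Cz", "Pz", "Fz", "Oz"))),
    "QQ1")
})

test_that("full pipeline cleans a synthetic recording and bounds its spectrum", {
  sp <- cohort_spec(n_pairs = 1, nap_duration = 120, seed = 11)
  h <- generate_hypnogram(sp, 11)
  g <- generate_eeg(sp, h, 11)
  res <- suppressWarnings(run_preprocessing(g$recording))
  expect_equal(res$qc$n_interpolated, 0)
  expect_lt(res$qc$union_fraction, 0.02)
  # 40 Hz low-pass efficacy: relative power above 45 Hz < 1%
  w <- napstat:::welch_psd(res$recording$data[1, ],
                           res$recording$sampling_rate, 4 * 250)
  hi <- napstat:::integrate_band(w$freq, w$psd, 45, 125)
  tot <- napstat:::integrate_band(w$freq, w$psd, 0.5, 125)
  expect_lt(hi / tot, 0.01)

  # determinism with a fixed ICA seed
  res2 <- suppressWarnings(run_preprocessing(g$recording))
  expect_identical(res$recording$data, res2$recording$data)
})

test_that("pipeline counts planted bad channels and transients in the QC report", {
  sp <- cohort_spec(
    n_pairs = 1, nap_duration = 120, seed = 12,
    artifact_params = utils::modifyList(
      default_artifact_params(),
      list(n_bad_channels = 1, bad_gain = 5, transient_rate_per_min = 2)))
  h <- generate_hypnogram(sp, 12)
  g <- generate_eeg(sp, h, 12)
  res <- suppressWarnings(run_preprocessing(g$recording))
  expect_equal(res$qc$n_interpolated, 1)
  expect_setequal(res$qc$bad_channels_power, g$truth$bad_channels$channel)
  # planted transients leave a nonzero amplitude-flagged fraction
  expect_gt(res$qc$amplitude_fraction, 0)
})
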