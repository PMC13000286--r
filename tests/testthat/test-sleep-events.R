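test_that("slow-wave filter passes 2 Hz, rejects 10 Hz and DC", {
  rate <- 250
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  mid <- (5 * rate):(15 * rate)
  f2 <- slow_wave_filter(sin(2 * pi * 2 * t), rate)
  expect_lt(abs(max(f2[mid]) - 1), 0.05)
  f10 <- slow_wave_filter(sin(2 * pi * 10 * t), rate)
  expect_lt(20 * log10(max(abs(f10[mid]))), -20)
  fdc <- slow_wave_filter(rep(5, length(t)), rate)
  expect_lt(max(abs(fdc[mid])), 0.05)
})

test_that("zero-crossing detection counts waves and amplitudes exactly", {
  rate <- 250
  t <- seq(0, 6 - 1 / rate, by = 1 / rate)
  # trough-first 2 Hz tone, one clean 6-s epoch: 12 waves of 2x amplitude
  f <- slow_wave_filter(-50 * sin(2 * pi * 2 * t), rate)
  ev <- detect_slow_waves(f, rate)
  expect_equal(nrow(ev), 12)
  expect_lt(abs(median(ev$amplitude_uV) - 100) / 100, 0.05)

  # interior epoch without filter edge effects: every amplitude exact
  t3 <- seq(0, 18 - 1 / rate, by = 1 / rate)
  f3 <- slow_wave_filter(-50 * sin(2 * pi * 2 * t3), rate)
  ev3 <- detect_slow_waves(f3, rate)
  mid <- ev3[ev3$epoch == 2, ]
  expect_equal(nrow(mid), 12)
  expect_true(all(abs(mid$amplitude_uV - 100) < 1))

  # flat signal: no waves
  ev0 <- detect_slow_waves(numeric(6 * rate), rate)
  expect_equal(nrow(ev0), 0)
  expect_equal(attr(ev0, "n_valid_epochs"), 1)

  # an epoch containing any flagged sample contributes nothing
  mask <- logical(6 * rate); mask[100] <- TRUE
  evm <- detect_slow_waves(f, rate, mask = mask)
  expect_equal(nrow(evm), 0)
  expect_equal(attr(evm, "n_valid_epochs"), 0)
})

test_that("slow-wave statistics average per-epoch with the empty-epoch rule", {
  ev <- tibble::tibble(channel = "Cz", onset_s = seq(0.1, 5.6, by = 0.5),
                       duration_s = 0.5, amplitude_uV = 50,
                       kind = "slow_wave", epoch = 1L)
  # one epoch, 12 waves of 50 uV -> (50, 12, 600)
  st <- slow_wave_stats(ev, 1)
  expect_equal(c(st$mean_amplitude, st$density, st$summation), c(50, 12, 600))

  # adding an empty epoch halves density and summation, halves mean amplitude
  st2 <- slow_wave_stats(ev, 2)
  expect_equal(c(st2$mean_amplitude, st2$density, st2$summation),
               c(25, 6, 300))

  # doubling amplitudes doubles amplitude and summation, not density
  ev2 <- ev; ev2$amplitude_uV <- 100
  st3 <- slow_wave_stats(ev2, 1)
  expect_equal(st3$density, st$density)
  expect_equal(st3$mean_amplitude, 2 * st$mean_amplitude)
  expect_equal(st3$summation, 2 * st$summation)

  expect_error(slow_wave_stats(ev, 0), "unusable")
})

test_that("per-epoch identity summation = density x mean amplitude is exact", {
  # property over random event tables
  for (s in 1:20) {
    set.seed(s)
    k <- sample(0:15, 1)
    if (k == 0) next
    ev <- tibble::tibble(channel = "Cz", onset_s = sort(runif(k, 0, 6)),
                         duration_s = 0.5,
                         amplitude_uV = runif(k, 20, 120),
                         kind = "slow_wave", epoch = 1L)
    st <- slow_wave_stats(ev, 1)
    expect_equal(st$summation, st$density * st$mean_amplitude)
  }
})

test_that("A7 spindle detection finds a planted burst and respects gating", {
  rate <- 250
  set.seed(42)
  n <- 60 * rate
  noise <- 10 * as.numeric(scale(stats::filter(rnorm(n), rep(1, 3) / 3,
                                               circular = TRUE)))
  tb <- seq(0, 1, by = 1 / rate)
  burst <- 30 * sin(2 * pi * 13.5 * tb) * napstat:::hann_window(length(tb))
  x <- noise
  i0 <- 10 * rate
  x[i0:(i0 + length(burst) - 1)] <- x[i0:(i0 + length(burst) - 1)] + burst

  hyp_n2 <- hypnogram(rep("N2", 2))
  ev <- detect_spindles_a7(x, rate, hyp = hyp_n2, stage = "N2")
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration_s, 0.7)
  expect_lte(ev$duration_s, 1.3)
  expect_lt(abs(ev$onset_s - 10), 0.3)

  # same burst in a W epoch with N2 requested: stage gate closes
  hyp_w <- hypnogram(rep("W", 2))
  evw <- detect_spindles_a7(x, rate, hyp = hyp_w, stage = "N2")
  expect_equal(nrow(evw), 0)

  # pure background: nothing at the default thresholds
  ev0 <- detect_spindles_a7(noise, rate, hyp = hyp_n2, stage = "N2")
  expect_equal(nrow(ev0), 0)

  # events intersecting artifact flags are discarded entirely
  mask <- logical(n); mask[i0 + 100] <- TRUE
  evm <- detect_spindles_a7(x, rate, mask = mask, hyp = hyp_n2, stage = "N2")
  expect_equal(nrow(evm), 0)
})

test_that("spindle statistics apply the zero-fill and exclusion rules", {
  chans <- montage_8()
  ev <- tibble::tibble(
    channel = c("Cz", "Cz", "Pz", "O1"),
    onset_s = c(10, 20, 15, 30), duration_s = c(0.5, 1.0, 0.8, 0.6),
    amplitude_uV = 30, kind = "spindle", stage = "N2")
  out <- spindle_stats(ev, chans)
  expect_true(out$included)
  # channels without events report (0, 0)
  zero <- out$stats[!out$stats$channel %in% c("Cz", "Pz", "O1"), ]
  expect_true(all(zero$count == 0 & zero$mean_duration_s == 0))
  # 2 events of 0.5 and 1.0 s -> count 2, mean duration 0.75
  cz <- out$stats[out$stats$channel == "Cz", ]
  expect_equal(cz$count, 2L)
  expect_equal(cz$mean_duration_s, 0.75)

  # no events anywhere: excluded from the stage analysis
  none <- spindle_stats(ev[0, ], chans)
  expect_false(none$included)
  expect_true(all(none$stats$count == 0))
})

test_that("planted slow waves and spindles are recovered from fixtures", {
  # slow waves >= 40 uV on quiet background, 15 seeds here (acceptance
  # extends to 50)
  res <- t(vapply(1:15, function(s) {
    sp <- sw_fixture_spec()
    hyp <- hypnogram(rep("SWS", 2))
    g <- generate_eeg(sp, hyp, s)
    flt <- slow_wave_filter(g$recording$data[1, ], 250)
    det <- detect_slow_waves(flt, 250, hyp = hyp, amp_threshold = 20)
    overlap_match(det, g$truth$events)
  }, numeric(3)))
  expect_gte(sum(res[, 1]) / sum(res[, 3]), 0.9)
  expect_lte(1 - sum(res[, 1]) / sum(res[, 2]), 0.1)

  res2 <- t(vapply(1:15, function(s) {
    sp <- spindle_fixture_spec()
    hyp <- hypnogram(rep("N2", 8))
    g <- generate_eeg(sp, hyp, s)
    det <- detect_spindles_a7(g$recording$data[1, ], 250, hyp = hyp,
                              stage = "N2")
    overlap_match(det, g$truth$events)
  }, numeric(3)))
  expect_gte(sum(res2[, 1]) / sum(res2[, 3]), 0.9)
  expect_lte(1 - sum(res2[, 1]) / sum(res2[, 2]), 0.1)
})

test_that("stage percentages partition the nap interval", {
  h <- hypnogram(rep("W", 10))
  p <- stage_percentages(h)
  expect_equal(p$percent[p$stage == "W"], 100)
  expect_equal(sum(p$percent), 100)

  h2 <- hypnogram(c(rep("SWS", 24), rep("N2", 216)))
  p2 <- stage_percentages(h2)
  expect_equal(p2$percent[p2$stage == "SWS"], 10)
  expect_equal(sum(p2$percent), 100)

  # property: any hypnogram sums to 100
  for (s in 1:5) {
    sp <- cohort_spec(nap_duration = 3600)
    expect_equal(sum(stage_percentages(generate_hypnogram(sp, s))$percent),
                 100)
  }
})
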