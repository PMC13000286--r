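# Shared fixture builders and oracles.

# All n! permutations of 1:n (exhaustive permutation-test oracle; keep n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Greedy 1-1 matching of detected to planted events by interval overlap
overlap_match <- function(det, truth) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    hit <- !used &
      truth$onset_s < det$onset_s[i] + det$duration_s[i] &
      truth$onset_s + truth$duration_s > det$onset_s[i]
    if (any(hit)) {
      used[which(hit)[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, n_det = nrow(det), n_planted = nrow(truth))
}

# Single-channel tone recording
tone_recording <- function(freq, dur_s, rate = 250, amp = 1, channel = "Cz") {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  nap_recording(matrix(amp * sin(2 * pi * freq * t), 1), channel, rate)
}

# Cohort spec that plants only slow waves on a quiet background
sw_fixture_spec <- function(rate_per_min = 8, amp_mean = 60, amp_sd = 10) {
  cohort_spec(
    n_pairs = 1, nap_duration = 60, channel_names = "Cz",
    noise = list(sd = 3, exponent = 1),
    event_rates = list(
      slow_wave = list(rate_per_min = list(SWS = rate_per_min),
                       amp_mean = amp_mean, amp_sd = amp_sd, freq_hz = 2),
      spindle = list(rate_per_min = list(), amp = 30, freq_hz = 13.5,
                     dur_range = c(0.5, 2)),
      alpha = list(amp = 0, freq_hz = 10)))
}

# Cohort spec that plants only spindle bursts (>= 3x background sigma power)
spindle_fixture_spec <- function(rate_per_min = 2, amp = 30) {
  cohort_spec(
    n_pairs = 1, nap_duration = 240, channel_names = "Cz",
    noise = list(sd = 10, exponent = 1),
    event_rates = list(
      slow_wave = list(rate_per_min = list(), amp_mean = 60, amp_sd = 10,
                       freq_hz = 2),
      spindle = list(rate_per_min = list(N2 = rate_per_min), amp = amp,
                     freq_hz = 13.5, dur_range = c(0.8, 1.5)),
      alpha = list(amp = 0, freq_hz = 10)))
}

# Silent cohort spec (no events, no noise, no artifacts)
silent_spec <- function(nap_duration = 120) {
  cohort_spec(
    n_pairs = 1, nap_duration = nap_duration,
    noise = list(sd = 0, exponent = 1),
    event_rates = list(
      slow_wave = list(rate_per_min = list(), amp_mean = 80, amp_sd = 15,
                       freq_hz = 2),
      spindle = list(rate_per_min = list(), amp = 30, freq_hz = 13.5,
                     dur_range = c(0.5, 2)),
      alpha = list(amp = 0, freq_hz = 10)))
}

# Small rating table: one report x rater grid with given statement values
rating_grid <- function(values_by_rater, report_id = "r1") {
  rows <- lapply(seq_along(values_by_rater), function(r) {
    v <- values_by_rater[[r]]
    tibble::tibble(report_id = report_id, rater = paste0("R", r),
                   s1 = v[1], s2 = v[2], s3 = v[3], s4 = v[4],
                   s5 = v[5], s6 = v[6], s7 = v[7])
  })
  dplyr::bind_rows(rows)
}
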