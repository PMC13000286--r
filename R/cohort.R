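#' Synthetic cohort specification
#'
#' Bundles every knob of the synthetic-cohort generator: montage and rate,
#' nap length, semi-Markov stage dynamics, planted event rates and
#' amplitudes, artifact injection, the physiology-to-score-gain effect and
#' the latent dream-report effect. Identical `(spec, seed)` pairs yield
#' bit-identical cohorts.
#'
#' Defaults emulate the study conditions at test scale: 8 named channels of
#' the 55-channel 10-10 montage at 250 Hz (the full montage and the
#' acquisition rate of 1000 Hz are available by overriding `channel_names`
#' and `sampling_rate`), a 130-min nap opportunity, stage dwell dynamics
#' tuned to a wake-rich daytime nap, and literature-typical slow-wave and
#' spindle densities and amplitudes.
#'
#' @param n_pairs number of prey/predator pairs (>= 1).
#' @param sampling_rate Hz.
#' @param channel_names ordered channel labels from the 10-10 montage.
#' @param nap_duration nap opportunity length in seconds.
#' @param stage_dwell_params tibble with columns `stage`, `mean_s`, `sd_s`:
#'   per-stage dwell-time distribution (normal, rounded to whole 30-s
#'   epochs, floored at one epoch).
#' @param transition matrix of embedded stage-to-stage transition
#'   probabilities (no self-transitions; rows sum to 1).
#' @param event_rates list with `slow_wave`, `spindle`, `alpha` components
#'   (rates in events/min, amplitudes in microvolts).
#' @param artifact_params list: transient rate (events/min/channel) and
#'   amplitude, bad-channel count and gain, 60 Hz line amplitude, ocular
#'   blink rate/amplitude and mixing gain.
#' @param noise list: background `sd` in microvolts, spectral `exponent`
#'   (power ~ 1/f^exponent) and `spatial_corr`, the share of background
#'   variance carried by a common volume-conducted source.
#' @param effect_spec list: `weight` of z-scored planted slow-wave summation
#'   on score gain and gain `noise_sd`.
#' @param dream_effect target Spearman correlation between the latent
#'   "dream about the game" rating and score gain for prey subjects.
#' @param rater_noise sd of the ordinal rater noise (0 = perfect raters).
#' @param seed default integer seed recorded in the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 13,
                        sampling_rate = 250,
                        channel_names = montage_8(),
                        nap_duration = 7800,
                        stage_dwell_params = default_dwell_params(),
                        transition = default_stage_transitions(),
                        event_rates = default_event_rates(),
                        artifact_params = default_artifact_params(),
                        noise = list(sd = 10, exponent = 1, spatial_corr = 0.6),
                        effect_spec = list(weight = 0, noise_sd = 1),
                        dream_effect = 0,
                        rater_noise = 0.7,
                        seed = 1L) {
  stopifnot(n_pairs >= 1, nap_duration > 0, sampling_rate > 0,
            noise$sd >= 0, effect_spec$noise_sd >= 0,
            dream_effect >= -1, dream_effect <= 1)
  unknown <- setdiff(channel_names, montage_55())
  if (length(unknown)) {
    abort(paste0("unknown channel name(s): ", paste(unknown, collapse = ", ")))
  }
  structure(list(
    n_pairs = as.integer(n_pairs), sampling_rate = sampling_rate,
    channel_names = channel_names, nap_duration = nap_duration,
    stage_dwell_params = stage_dwell_params, transition = transition,
    event_rates = event_rates, artifact_params = artifact_params,
    noise = noise, effect_spec = effect_spec, dream_effect = dream_effect,
    rater_noise = rater_noise, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_dwell_params <- function() {
  tibble::tibble(
    stage = c("W", "N1", "N2", "SWS", "REM"),
    mean_s = c(480, 90, 180, 150, 360),
    sd_s = c(240, 45, 120, 90, 180)
  )
}

#' @rdname cohort_spec
#' @export
default_stage_transitions <- function() {
  st <- c("W", "N1", "N2", "SWS", "REM")
  tm <- matrix(0, 5, 5, dimnames = list(st, st))
  tm["W", ] <- c(0, 1, 0, 0, 0)
  tm["N1", ] <- c(0.25, 0, 0.75, 0, 0)
  tm["N2", ] <- c(0.15, 0.25, 0, 0.40, 0.20)
  tm["SWS", ] <- c(0, 0.2, 0.8, 0, 0)
  tm["REM", ] <- c(0.5, 0.5, 0, 0, 0)
  tm
}

#' @rdname cohort_spec
#' @export
default_event_rates <- function() {
  list(
    slow_wave = list(rate_per_min = list(SWS = 30, N2 = 6),
                     amp_mean = 80, amp_sd = 15, freq_hz = 2),
    spindle = list(rate_per_min = list(N2 = 2, SWS = 0.5),
                   amp = 30, freq_hz = 13.5,
                   dur_range = c(0.5, 2)),
    alpha = list(amp = 20, freq_hz = 10)
  )
}

#' @rdname cohort_spec
#' @export
default_artifact_params <- function() {
  list(transient_rate_per_min = 0, transient_amp = 150, transient_dur = 0.12,
       n_bad_channels = 0, bad_gain = 20,
       line_amp = 0, ocular_rate_per_min = 0, ocular_amp = 120,
       ocular_gain = 1)
}

# Expected dwell length in epochs for D = max(1, round(N(mean, sd) / 30)).
expected_dwell_epochs <- function(mean_s, sd_s, epoch_len = 30) {
  if (sd_s == 0) return(max(1, round(mean_s / epoch_len)))
  kmax <- ceiling((mean_s + 10 * sd_s) / epoch_len) + 2
  k <- seq_len(kmax)
  lo <- ifelse(k == 1, -Inf, (k - 0.5) * epoch_len)
  hi <- (k + 0.5) * epoch_len
  p <- stats::pnorm(hi, mean_s, sd_s) - stats::pnorm(lo, mean_s, sd_s)
  sum(k * p) / sum(p)
}

#' Configured stationary stage fractions
#'
#' Closed-form occupancy fractions of the generator's semi-Markov stage
#' process: the embedded chain's stationary distribution weighted by the
#' exact expected dwell length in epochs. Serves as the oracle for
#' Monte-Carlo checks of [generate_hypnogram()].
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `stage` and `fraction` (sums to 1).
#' @export
stationary_stage_fractions <- function(spec) {
  tm <- spec$transition
  # stationary distribution of the embedded chain
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i]); pi_embed <- pi_embed / sum(pi_embed)
  dw <- spec$stage_dwell_params
  ed <- vapply(rownames(tm), function(s) {
    r <- dw[dw$stage == s, ]
    expected_dwell_epochs(r$mean_s, r$sd_s)
  }, numeric(1))
  frac <- pi_embed * ed
  tibble::tibble(stage = rownames(tm), fraction = frac / sum(frac))
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov stage sequence: dwell times are drawn per stage from the
#' configured normal distribution, rounded to whole 30-s epochs (minimum
#' one), and stages follow the embedded transition matrix. A burn-in of one
#' nap length is discarded so occupancy is stationary; lights-off is at
#' t = 0 and lights-on at `nap_duration`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return a [hypnogram()].
#' @export
generate_hypnogram <- function(spec, seed = spec$seed) {
  epoch_len <- 30
  if (spec$nap_duration < epoch_len) {
    abort("nap_duration must cover at least one 30-s epoch.")
  }
  n_epochs <- floor(spec$nap_duration / epoch_len)
  rng <- local_rng(seed, "hypnogram")
  tm <- spec$transition
  stages_all <- rownames(tm)
  dw <- spec$stage_dwell_params
  need <- 2 * n_epochs            # burn-in + kept epochs
  seq_out <- character(0)
  st <- sample(stages_all, 1, prob = stationary_stage_fractions(spec)$fraction)
  while (length(seq_out) < need) {
    r <- dw[dw$stage == st, ]
    d <- max(1, round(rnorm(1, r$mean_s, r$sd_s) / epoch_len))
    seq_out <- c(seq_out, rep(st, d))
    st <- sample(stages_all, 1, prob = tm[st, ])
  }
  hypnogram(seq_out[(need - n_epochs + 1):need], epoch_len = epoch_len,
            lights_off = 0)
}

# Seeded sub-stream RNG: derive a deterministic integer seed from (seed, tag)
# so each generator component has an independent but reproducible stream.
local_rng <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + h %% 100003L)
  invisible(NULL)
}

# 1/f^exponent background noise scaled to target sd (microvolts).
colored_noise <- function(n, rate, sd_uv, exponent) {
  if (sd_uv == 0) return(numeric(n))
  w <- rnorm(n)
  if (exponent == 0) return(w * sd_uv)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid DC blow-up
  f <- pmin(f, n - f + 1)              # mirror for negative freqs
  shape <- f^(-exponent / 2)
  x <- Re(fft(sp * shape, inverse = TRUE)) / n
  x * sd_uv / sd(x)
}

slow_wave_shape <- function(rate, freq_hz, amp_tp) {
  d <- 1 / freq_hz
  t <- seq(0, d, by = 1 / rate)
  -(amp_tp / 2) * sin(2 * pi * t / d)  # trough then rebound peak
}

spindle_shape <- function(rate, freq_hz, dur_s, amp) {
  t <- seq(0, dur_s, by = 1 / rate)
  amp * sin(2 * pi * freq_hz * t) * hann_window(length(t))
}

#' Generate synthetic nap EEG with a ground-truth ledger
#'
#' Per channel: 1/f background noise plus stage-gated planted events (slow
#' waves in SWS/N2, spindle bursts in N2/SWS, continuous alpha in W),
#' optional 60 Hz line noise, high-amplitude transients, designated bad
#' channels (gain-corrupted), and a frontal-dominant ocular source. Every
#' planted event, artifact interval and bad channel is recorded exactly once
#' in the returned truth ledger.
#'
#' @param spec a [cohort_spec()].
#' @param hyp a [hypnogram()] matching `spec$nap_duration`.
#' @param seed integer seed.
#' @return list with `recording` (a [nap_recording()]) and `truth` (list of
#'   tibbles: `events`, `bad_channels`, `artifacts`, `ocular`).
#' @export
generate_eeg <- function(spec, hyp, seed = spec$seed) {
  rate <- spec$sampling_rate
  chans <- spec$channel_names
  n <- round(spec$nap_duration * rate)
  local_rng(seed, "eeg")
  dat <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  rho <- spec$noise$spatial_corr %||% 0
  common <- colored_noise(n, rate, spec$noise$sd, spec$noise$exponent)
  for (ci in seq_along(chans)) {
    own <- colored_noise(n, rate, spec$noise$sd, spec$noise$exponent)
    dat[ci, ] <- sqrt(rho) * common + sqrt(1 - rho) * own
  }

  ev_rows <- list()
  add_event <- function(ch, onset, dur, amp, kind, stage) {
    ev_rows[[length(ev_rows) + 1]] <<- tibble::tibble(
      channel = ch, onset_s = onset, duration_s = dur,
      amplitude_uV = amp, kind = kind, stage = stage)
  }
  place_in_epoch <- function(ep_onset, dur) {
    slack <- 30 - dur
    if (slack <= 0) return(NA_real_)
    ep_onset + runif(1, 0, slack)
  }
  er <- spec$event_rates
  epoch_onsets <- hyp$onset_s
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    for (ei in seq_len(nrow(hyp))) {
      stg <- hyp$stage[ei]
      # slow waves
      rpm <- er$slow_wave$rate_per_min[[stg]]
      if (!is.null(rpm) && rpm > 0) {
        k <- rpois(1, rpm * 0.5)
        for (j in seq_len(k)) {
          amp <- max(10, rnorm(1, er$slow_wave$amp_mean, er$slow_wave$amp_sd))
          dur <- 1 / er$slow_wave$freq_hz
          on <- place_in_epoch(epoch_onsets[ei], dur)
          if (is.na(on)) next
          shp <- slow_wave_shape(rate, er$slow_wave$freq_hz, amp)
          i0 <- round(on * rate) + 1
          ii <- i0:min(n, i0 + length(shp) - 1)
          dat[ci, ii] <- dat[ci, ii] + shp[seq_along(ii)]
          add_event(ch, on, dur, amp, "slow_wave", stg)
        }
      }
      # spindles
      rpm <- er$spindle$rate_per_min[[stg]]
      if (!is.null(rpm) && rpm > 0) {
        k <- rpois(1, rpm * 0.5)
        for (j in seq_len(k)) {
          dur <- runif(1, er$spindle$dur_range[1], er$spindle$dur_range[2])
          on <- place_in_epoch(epoch_onsets[ei], dur)
          if (is.na(on)) next
          shp <- spindle_shape(rate, er$spindle$freq_hz, dur, er$spindle$amp)
          i0 <- round(on * rate) + 1
          ii <- i0:min(n, i0 + length(shp) - 1)
          dat[ci, ii] <- dat[ci, ii] + shp[seq_along(ii)]
          add_event(ch, on, dur, er$spindle$amp, "spindle", stg)
        }
      }
    }
  }
  # waking alpha: continuous within W epochs, occipital-dominant topography
  if (er$alpha$amp > 0) {
    aw <- alpha_weights(chans)
    for (ei in which(hyp$stage == "W")) {
      i0 <- round(epoch_onsets[ei] * rate) + 1
      ii <- i0:min(n, i0 + 30 * rate - 1)
      tt <- (ii - 1) / rate
      dat[, ii] <- dat[, ii, drop = FALSE] +
        outer(aw, er$alpha$amp * sin(2 * pi * er$alpha$freq_hz * tt))
    }
  }

  ap <- spec$artifact_params
  art_rows <- list(); oc_rows <- list()
  if (ap$line_amp > 0) {
    tt <- (seq_len(n) - 1) / rate
    dat <- sweep(dat, 2, ap$line_amp * sin(2 * pi * 60 * tt), "+")
  }
  if (ap$transient_rate_per_min > 0) {
    for (ci in seq_along(chans)) {
      k <- rpois(1, ap$transient_rate_per_min * spec$nap_duration / 60)
      if (k == 0) next
      ons <- sort(runif(k, 0, spec$nap_duration - ap$transient_dur))
      for (on in ons) {
        len <- round(ap$transient_dur * rate)
        i0 <- round(on * rate) + 1
        ii <- i0:min(n, i0 + len - 1)
        dat[ci, ii] <- dat[ci, ii] +
          ap$transient_amp * sin(pi * seq_along(ii) / length(ii))
        art_rows[[length(art_rows) + 1]] <- tibble::tibble(
          channel = chans[ci], start_s = on, end_s = on + ap$transient_dur)
      }
    }
  }
  bad <- character(0)
  if (ap$n_bad_channels > 0) {
    bad <- sample(chans, min(ap$n_bad_channels, length(chans)))
    for (b in bad) dat[b, ] <- dat[b, ] * ap$bad_gain
  }
  if (ap$ocular_rate_per_min > 0) {
    k <- rpois(1, ap$ocular_rate_per_min * spec$nap_duration / 60)
    src <- numeric(n)
    ons <- sort(runif(max(k, 0), 0, spec$nap_duration - 0.4))
    for (on in ons) {
      len <- round(0.35 * rate)
      i0 <- round(on * rate) + 1
      ii <- i0:min(n, i0 + len - 1)
      src[ii] <- src[ii] + ap$ocular_amp * sin(pi * seq_along(ii) / length(ii))^2
      oc_rows[[length(oc_rows) + 1]] <- tibble::tibble(onset_s = on,
                                                       duration_s = 0.35)
    }
    w <- ocular_weights(chans) * ap$ocular_gain
    dat <- dat + outer(w, src)
  }

  truth <- list(
    events = if (length(ev_rows)) dplyr::bind_rows(ev_rows) else
      tibble::tibble(channel = character(), onset_s = double(),
                     duration_s = double(), amplitude_uV = double(),
                     kind = character(), stage = character()),
    bad_channels = tibble::tibble(channel = bad),
    artifacts = if (length(art_rows)) dplyr::bind_rows(art_rows) else
      tibble::tibble(channel = character(), start_s = double(),
                     end_s = double()),
    ocular = if (length(oc_rows)) dplyr::bind_rows(oc_rows) else
      tibble::tibble(onset_s = double(), duration_s = double())
  )
  list(recording = nap_recording(dat, chans, rate, "nap"), truth = truth)
}

# Occipital-dominant alpha topography by 10-10 row.
alpha_weights <- function(chans) {
  vapply(chans, function(ch) {
    row <- sub("^([A-Za-z]+).*$", "\\1", ch)
    switch(row, "O" = 1, "PO" = 0.9, "P" = 0.75, "TP" = 0.6, "CP" = 0.6,
           "T" = 0.45, "C" = 0.45, "FC" = 0.35, "FT" = 0.35, "F" = 0.25,
           "AF" = 0.2, 0.2)
  }, numeric(1))
}

# Frontal-dominant ocular mixing weights by 10-10 row.
ocular_weights <- function(chans) {
  vapply(chans, function(ch) {
    row <- sub("^([A-Za-z]+).*$", "\\1", ch)
    switch(row, "Fp" = 1, "AF" = 1, "F" = 0.6, "FT" = 0.35, "FC" = 0.3,
           "T" = 0.15, "C" = 0.15, "TP" = 0.08, "CP" = 0.08, 0.05)
  }, numeric(1))
}

#' Generate a synthetic single-channel ECG with known beat times
#'
#' Inter-beat intervals follow baseline + low-frequency (~0.1 Hz) sinusoid +
#' high-frequency (~0.25 Hz) sinusoid + Gaussian jitter; a QRS-like template
#' is stamped at each beat. The ledger stores the exact beat times.
#'
#' @param spec a [cohort_spec()] (used for the sampling rate).
#' @param duration_s recording length in seconds (> 10).
#' @param mean_hr mean heart rate in bpm.
#' @param lf_amp,hf_amp modulation amplitudes in seconds at ~0.1 / ~0.25 Hz.
#' @param jitter_sd Gaussian IBI jitter sd in seconds.
#' @param noise_sd additive broadband noise sd in microvolts.
#' @param seed integer seed.
#' @return list with `recording` (single-channel [nap_recording()], block
#'   `round1`) and `beat_times` (seconds).
#' @export
generate_ecg <- function(spec, duration_s = 300, mean_hr = 70,
                         lf_amp = 0.03, hf_amp = 0.02, jitter_sd = 0.01,
                         noise_sd = 5, seed = spec$seed) {
  if (duration_s <= 10) abort("ECG duration must exceed 10 s.")
  rate <- spec$sampling_rate
  local_rng(seed, "ecg")
  base <- 60 / mean_hr
  beats <- 0.5
  t <- beats
  while (TRUE) {
    ibi <- base + lf_amp * sin(2 * pi * 0.1 * t) +
      hf_amp * sin(2 * pi * 0.25 * t) +
      if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
    ibi <- max(0.3, ibi)
    t <- t + ibi
    if (t > duration_s - 0.5) break
    beats <- c(beats, t)
  }
  n <- round(duration_s * rate)
  x <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  tmpl_t <- seq(-0.06, 0.06, by = 1 / rate)
  r_wave <- 1000 * exp(-(tmpl_t / 0.012)^2)
  q_wave <- -150 * exp(-((tmpl_t + 0.028) / 0.009)^2)
  s_wave <- -200 * exp(-((tmpl_t - 0.028) / 0.009)^2)
  tmpl <- r_wave + q_wave + s_wave
  half <- (length(tmpl) - 1) / 2
  for (b in beats) {
    c0 <- round(b * rate) + 1
    ii <- max(1, c0 - half):min(n, c0 + half)
    x[ii] <- x[ii] + tmpl[ii - (c0 - half) + 1]
  }
  list(recording = nap_recording(matrix(x, 1), "ECG", rate, "round1"),
       beat_times = beats)
}

# Normal-copula correlation that yields a target Spearman correlation.
pearson_for_spearman <- function(rs) 2 * sin(pi * rs / 6)

#' Generate rater forms, game counts and score gains for a cohort
#'
#' For each subject a latent Likert profile over the seven report statements
#' is drawn; four raters answer with discretized-Gaussian ordinal noise,
#' and raters whose statement-1 answer is 3 or less leave statements 2-7
#' blank (the instructed convention). Game counts are role-asymmetric
#' Poisson draws (predators exceed prey in wins, prey exceed predators in
#' collections); round-2 counts are adjusted so the realized score gain
#' tracks `effect_spec$weight` x z-scored planted slow-wave summation plus a
#' latent dream-about-game contribution calibrated to `dream_effect`
#' (Spearman scale) plus Gaussian noise.
#'
#' @param spec a [cohort_spec()].
#' @param physiology tibble with columns `subject`, `role` and
#'   `sw_summation` (the planted slow-wave summation summary per subject);
#'   if `NULL`, a standard-normal latent is drawn.
#' @param n_raters number of raters (>= 1).
#' @param seed integer seed.
#' @return list with `ratings` (tibble: report_id, rater, statement columns
#'   s1..s7, blanks as `NA`), `latent` (tibble of latent Likert truths),
#'   `counts` (tibble: subject, role, round, wins, losses, collections) and
#'   `gains` (tibble: subject, role, gain plus latent components).
#' @export
generate_reports_and_scores <- function(spec, physiology = NULL,
                                        n_raters = 4, seed = spec$seed) {
  if (n_raters < 1) abort("need at least 1 rater.")
  local_rng(seed, "reports")
  n <- 2 * spec$n_pairs
  subjects <- sprintf("S%02d", seq_len(n))
  roles <- rep(c("prey", "predator"), spec$n_pairs)
  if (is.null(physiology)) {
    physiology <- tibble::tibble(subject = subjects, role = roles,
                                 sw_summation = rnorm(n))
  }
  stopifnot(nrow(physiology) == n)

  # latent dream-about-game propensity and gain construction
  a <- pearson_for_spearman(spec$dream_effect)
  z_dream <- rnorm(n)
  z_sw <- as.numeric(scale(physiology$sw_summation))
  if (any(!is.finite(z_sw))) z_sw <- rep(0, n)
  eps <- rnorm(n)
  gain_latent <- 5 * (spec$effect_spec$weight * z_sw +
                        a * z_dream +
                        sqrt(max(0, 1 - a^2)) * spec$effect_spec$noise_sd * eps)

  # latent Likert truths: statement values on 1..6
  lik <- function(z) pmin(6, pmax(1, round(3.5 + 1.5 * z)))
  latent <- tibble::tibble(
    report_id = subjects,
    role = roles,
    dreamed = lik(rnorm(n, 0.5)),
    remembers_clearly = lik(rnorm(n)),
    about_game = lik(z_dream),
    about_laboratory = lik(rnorm(n, -0.5)),
    about_personal_life = lik(rnorm(n, -0.5)),
    being_prey = lik(ifelse(roles == "prey", rnorm(n, 0.3), rnorm(n, -0.8))),
    being_predator = lik(ifelse(roles == "predator", rnorm(n, 0.3),
                                rnorm(n, -0.8)))
  )

  stmt_cols <- c("dreamed", "remembers_clearly", "about_game",
                 "about_laboratory", "about_personal_life", "being_prey",
                 "being_predator")
  rows <- list()
  for (i in seq_len(n)) {
    for (r in seq_len(n_raters)) {
      vals <- vapply(stmt_cols, function(s) {
        v <- latent[[s]][i]
        if (spec$rater_noise > 0) v <- v + rnorm(1, 0, spec$rater_noise)
        pmin(6, pmax(1, round(v)))
      }, numeric(1))
      if (vals[1] <= 3) vals[2:7] <- NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        report_id = subjects[i], rater = paste0("R", r),
        !!!stats::setNames(as.list(vals), paste0("s", 1:7)))
    }
  }
  ratings <- dplyr::bind_rows(rows)

  # role-asymmetric game counts; round 2 adjusted to realize the target gain
  lam <- list(prey = c(wins = 2, losses = 5, collections = 10),
              predator = c(wins = 8, losses = 3, collections = 3))
  count_rows <- list(); gain_rows <- list()
  for (i in seq_len(n)) {
    l <- lam[[roles[i]]]
    r1 <- c(wins = rpois(1, l["wins"]), losses = rpois(1, l["losses"]),
            collections = rpois(1, l["collections"]))
    score1 <- if (roles[i] == "prey") r1["collections"] - r1["losses"] else
      r1["wins"] - r1["losses"]
    g <- round(gain_latent[i])
    losses2 <- rpois(1, l["losses"])
    if (roles[i] == "prey") {
      coll2 <- max(0, score1 + g + losses2)
      wins2 <- rpois(1, l["wins"])
      r2 <- c(wins = wins2, losses = losses2, collections = coll2)
      score2 <- coll2 - losses2
    } else {
      wins2 <- max(0, score1 + g + losses2)
      r2 <- c(wins = wins2, losses = losses2,
              collections = rpois(1, l["collections"]))
      score2 <- wins2 - losses2
    }
    count_rows[[length(count_rows) + 1]] <- tibble::tibble(
      subject = subjects[i], role = roles[i], round = c(1L, 2L),
      wins = c(r1["wins"], r2["wins"]),
      losses = c(r1["losses"], r2["losses"]),
      collections = c(r1["collections"], r2["collections"]))
    gain_rows[[length(gain_rows) + 1]] <- tibble::tibble(
      subject = subjects[i], role = roles[i],
      gain = as.numeric(score2 - score1),
      latent_about_game = z_dream[i], z_sw = z_sw[i])
  }
  # five video-game-experience questionnaire answers per subject
  experience <- tibble::tibble(
    subject = subjects, role = roles,
    days_per_week = pmin(7, rpois(n, 3)),
    hours_per_day = round(rexp(n, 1 / 2), 1),
    n_platforms = rpois(n, 2),
    n_genres = rpois(n, 3),
    n_games = rpois(n, 10))

  list(ratings = ratings, latent = latent,
       counts = dplyr::bind_rows(count_rows),
       gains = dplyr::bind_rows(gain_rows),
       experience = experience)
}

#' Lightweight cohort physiology summaries with a planted gain effect
#'
#' Draws per-subject, per-channel slow-wave summation summaries from a
#' log-normal channel model with a shared subject factor, and score gains
#' whose Spearman correlation with the designated effect channels targets
#' `true_spearman`. This is the truth-ledger shortcut used for
#' parameter-recovery studies at many seeds, where synthesizing full EEG for
#' every cohort is unnecessary: the planted quantity itself (not its
#' re-detection) carries the effect.
#'
#' @param n_subjects cohort size.
#' @param channels channel labels.
#' @param effect_channels channels carrying the full effect loading.
#' @param true_spearman target Spearman correlation between summation on an
#'   effect channel and gain (0 = null cohort).
#' @param bystander_loading loading of non-effect channels on the shared
#'   subject factor.
#' @param seed integer seed.
#' @return list with `features` (channels x subjects matrix of summations)
#'   and `gain` (numeric vector).
#' @export
generate_cohort_summaries <- function(n_subjects = 13,
                                      channels = montage_8(),
                                      effect_channels = channels[1:2],
                                      true_spearman = 0,
                                      bystander_loading = 0.9,
                                      seed = 1L) {
  local_rng(seed, "summaries")
  z <- rnorm(n_subjects)
  feats <- matrix(0, length(channels), n_subjects,
                  dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    load <- if (channels[ci] %in% effect_channels) 1 else bystander_loading
    lat <- load * z + sqrt(1 - load^2) * rnorm(n_subjects)
    feats[ci, ] <- exp(5 + 0.5 * lat)     # log-normal summation scale
  }
  a <- pearson_for_spearman(true_spearman)
  gain <- a * z + sqrt(max(0, 1 - a^2)) * rnorm(n_subjects)
  list(features = feats, gain = gain)
}

#' Simulate a full cohort
#'
#' Draws `n_pairs` prey/predator pairs: per subject a hypnogram, a nap EEG
#' recording with truth ledger, a round-1 ECG, and cohort-level rater forms,
#' game counts and gains. The per-subject physiology feeding the gain effect
#' is the total planted slow-wave summation (amplitude sum of planted slow
#' waves) from the truth ledger.
#'
#' @param spec a [cohort_spec()].
#' @param ecg_duration_s round-1 ECG length per subject in seconds.
#' @param seed integer seed.
#' @return list with `subjects` (list of per-subject lists: `subject`,
#'   `role`, `hypnogram`, `eeg`, `truth`, `ecg`, `beat_times`), `ratings`,
#'   `counts`, `gains`, and the `spec`.
#' @export
simulate_cohort <- function(spec, ecg_duration_s = 120, seed = spec$seed) {
  n <- 2 * spec$n_pairs
  subjects <- sprintf("S%02d", seq_len(n))
  roles <- rep(c("prey", "predator"), spec$n_pairs)
  subj <- vector("list", n)
  sw_sum <- numeric(n)
  for (i in seq_len(n)) {
    s_seed <- seed * 1000L + i
    hyp <- generate_hypnogram(spec, s_seed)
    eeg <- generate_eeg(spec, hyp, s_seed)
    ecg <- generate_ecg(spec, duration_s = ecg_duration_s, seed = s_seed)
    ev <- eeg$truth$events
    sw_sum[i] <- sum(ev$amplitude_uV[ev$kind == "slow_wave"])
    subj[[i]] <- list(subject = subjects[i], role = roles[i], hypnogram = hyp,
                      eeg = eeg$recording, truth = eeg$truth,
                      ecg = ecg$recording, beat_times = ecg$beat_times)
  }
  phys <- tibble::tibble(subject = subjects, role = roles,
                         sw_summation = sw_sum)
  rs <- generate_reports_and_scores(spec, physiology = phys, seed = seed)
  c(list(subjects = subj, spec = spec, physiology = phys), rs)
}
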