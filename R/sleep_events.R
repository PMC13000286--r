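#' Slow-wave bandpass filter
#'
#' Zero-phase FIR bandpass with passband 1-3 Hz and stopband edges at 0.1
#' and 3.9 Hz (at least 20 dB stopband attenuation). The filter length is
#' chosen from the sampling rate so the Hamming-window transition width fits
#' inside the 0.9 Hz transition bands.
#'
#' @param x numeric signal (one channel).
#' @param rate sampling rate in Hz (>= 100).
#' @return filtered signal, same length.
#' @export
slow_wave_filter <- function(x, rate) {
  stopifnot(rate >= 100)
  ntaps <- round(4 * rate)
  if (ntaps %% 2 == 1) ntaps <- ntaps + 1
  flt <- signal::fir1(ntaps, c(1, 3) / (rate / 2), type = "pass")
  signal::filtfilt(flt, x)
}

#' Detect slow waves by zero crossings in artifact-free 6-s epochs
#'
#' Within every 6-s epoch free of artifact flags, candidate waves of the
#' slow-wave-filtered signal are counted one per negative-to-positive
#' zero-crossing pair — the negative half-wave (trough) plus its rebound
#' positive half-wave (peak), delimited by the surrounding
#' positive-to-negative crossings. A candidate is kept when its full period
#' lies in 0.33-1.0 s (consistent with 1-3 Hz) and its trough-to-peak
#' amplitude reaches `amp_threshold`. Epochs containing any flagged sample
#' contribute no waves.
#'
#' @param filtered slow-wave-filtered signal (one channel).
#' @param rate sampling rate in Hz.
#' @param mask logical vector of artifact flags for this channel (or `NULL`).
#' @param hyp a [hypnogram()] or `NULL`; when given, each event is tagged
#'   with the stage of its onset epoch.
#' @param channel channel label recorded in the output.
#' @param epoch_len_s evaluation epoch length (6 s).
#' @param amp_threshold minimum trough-to-peak amplitude in microvolts
#'   (default 0, i.e. no amplitude criterion).
#' @param period_range full-period bounds in seconds.
#' @return [tibble::tibble] event table (`channel`, `onset_s`, `duration_s`,
#'   `amplitude_uV`, `kind`, `stage`, `epoch`), plus attribute
#'   `n_valid_epochs`.
#' @export
detect_slow_waves <- function(filtered, rate, mask = NULL, hyp = NULL,
                              channel = "ch", epoch_len_s = 6,
                              amp_threshold = 0,
                              period_range = c(1 / 3, 1)) {
  n <- length(filtered)
  elen <- round(epoch_len_s * rate)
  n_ep <- floor(n / elen)
  if (is.null(mask)) mask <- rep(FALSE, n)
  rows <- list()
  n_valid <- 0L
  for (e in seq_len(n_ep)) {
    ii <- ((e - 1) * elen + 1):(e * elen)
    if (any(mask[ii])) next
    n_valid <- n_valid + 1L
    seg <- filtered[ii]
    s <- sign(seg)
    # a wave is the negative half-wave plus its rebound peak: the two half
    # waves straddle one neg->pos crossing, so waves are delimited by the
    # surrounding pos->neg crossings
    zc <- which(s[-length(s)] > 0 & s[-1] <= 0)
    # epoch edges delimit the first and last candidate wave
    zc <- unique(c(1L, zc, length(seg)))
    if (length(zc) < 2) next
    for (k in seq_len(length(zc) - 1)) {
      a <- zc[k]; b <- zc[k + 1]
      period <- (b - a) / rate
      if (period < period_range[1] || period > period_range[2]) next
      w <- seg[a:b]
      amp <- max(w) - min(w)
      if (amp < amp_threshold) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        channel = channel,
        onset_s = (ii[1] - 1 + a - 1) / rate,
        duration_s = period,
        amplitude_uV = amp,
        kind = "slow_wave",
        epoch = e)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(channel = character(), onset_s = double(),
                   duration_s = double(), amplitude_uV = double(),
                   kind = character(), epoch = integer())
  out$stage <- if (!is.null(hyp) && nrow(out)) stage_at(hyp, out$onset_s)
  else rep(NA_character_, nrow(out))
  attr(out, "n_valid_epochs") <- n_valid
  out
}

#' Per-channel slow-wave statistics
#'
#' For each artifact-free 6-s epoch the mean amplitude, wave count and
#' summation (count x mean amplitude) are computed, with empty epochs
#' contributing (0, 0, 0); each is then averaged over the valid epochs.
#' Density is the average count per 6-s epoch.
#'
#' @param events event table from [detect_slow_waves()] (one channel).
#' @param n_valid_epochs number of artifact-free epochs evaluated.
#' @return tibble with `mean_amplitude`, `density`, `summation`.
#' @export
slow_wave_stats <- function(events, n_valid_epochs) {
  if (n_valid_epochs < 1) {
    abort("zero valid epochs; subject unusable for slow-wave analysis.")
  }
  per_epoch <- dplyr::summarise(
    dplyr::group_by(events, .data$epoch),
    m = mean(.data$amplitude_uV), k = dplyr::n(),
    s = dplyr::n() * mean(.data$amplitude_uV), .groups = "drop")
  tibble::tibble(
    mean_amplitude = sum(per_epoch$m) / n_valid_epochs,
    density = sum(per_epoch$k) / n_valid_epochs,
    summation = sum(per_epoch$s) / n_valid_epochs)
}

# A7-style sliding-window features for one channel.
a7_features <- function(x, rate, window_s = 0.3, step_s = 0.1,
                        sigma_band = c(11, 16), broad_band = c(0.5, 30)) {
  sig <- butter_filtfilt(x, rate, sigma_band[1], sigma_band[2], order = 4)
  broad <- butter_filtfilt(x, rate, broad_band[1], broad_band[2], order = 4)
  wlen <- round(window_s * rate)
  step <- round(step_s * rate)
  starts <- seq(1, length(x) - wlen + 1, by = step)
  f <- matrix(NA_real_, length(starts), 4,
              dimnames = list(NULL, c("abs_pow", "rel_pow", "cov", "corr")))
  for (i in seq_along(starts)) {
    ii <- starts[i]:(starts[i] + wlen - 1)
    s <- sig[ii]; b <- broad[ii]
    ps <- mean(s^2); pb <- mean(b^2)
    f[i, "abs_pow"] <- log10(max(ps, 1e-12))
    f[i, "rel_pow"] <- log10(max(ps, 1e-12) / max(pb, 1e-12))
    cv <- stats::cov(s, b)
    f[i, "cov"] <- log10(max(cv, 1e-12))
    f[i, "corr"] <- suppressWarnings(stats::cor(s, b))
  }
  f[, "rel_pow"] <- robust_z(f[, "rel_pow"])
  f[, "cov"] <- robust_z(f[, "cov"])
  list(starts = starts, wlen = wlen, features = f)
}

robust_z <- function(v) {
  s <- sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(v * 0)
  (v - mean(v, na.rm = TRUE)) / s
}

#' A7-style spindle detection
#'
#' On 0.3-s windows stepped by 0.1 s, four features are computed: absolute
#' sigma (11-16 Hz) power (log10 uV^2), relative sigma power (z-scored
#' log-ratio to broadband power), sigma covariance (z-scored log covariance
#' of the sigma-filtered and broadband signals), and sigma correlation.
#' Windows where all four exceed their thresholds are merged into events;
#' events must last 0.3-2.5 s, must not intersect artifact flags, and only
#' events whose onset epoch matches the requested stage are kept.
#'
#' @param x raw signal (one channel).
#' @param rate sampling rate (>= 100 Hz).
#' @param mask logical artifact flags for this channel (or `NULL`).
#' @param hyp a [hypnogram()] (or `NULL` to skip stage gating).
#' @param stage stage to keep events in (`"N2"` or `"SWS"`).
#' @param channel channel label for the output.
#' @param thresholds named numeric: `abs_pow` (log10 uV^2), `rel_pow` (z),
#'   `cov` (z), `corr`.
#' @param duration_range event duration bounds in seconds.
#' @return tibble event table (`channel`, `onset_s`, `duration_s`,
#'   `amplitude_uV`, `kind`, `stage`).
#' @export
detect_spindles_a7 <- function(x, rate, mask = NULL, hyp = NULL,
                               stage = "N2", channel = "ch",
                               thresholds = c(abs_pow = 1.25, rel_pow = 1.6,
                                              cov = 1.3, corr = 0.69),
                               duration_range = c(0.3, 2.5)) {
  stopifnot(rate >= 100)
  ft <- a7_features(x, rate)
  hit <- ft$features[, "abs_pow"] > thresholds["abs_pow"] &
    ft$features[, "rel_pow"] > thresholds["rel_pow"] &
    ft$features[, "cov"] > thresholds["cov"] &
    ft$features[, "corr"] > thresholds["corr"]
  hit[is.na(hit)] <- FALSE
  rows <- list()
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts_run <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- ft$starts[starts_run[k]]
      i1 <- ft$starts[ends[k]] + ft$wlen - 1
      dur <- (i1 - i0 + 1) / rate
      if (dur < duration_range[1] || dur > duration_range[2]) next
      if (!is.null(mask) && any(mask[i0:i1])) next
      onset <- (i0 - 1) / rate
      if (!is.null(hyp)) {
        st <- stage_at(hyp, onset)
        if (is.na(st) || st != stage) next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        channel = channel, onset_s = onset, duration_s = dur,
        amplitude_uV = max(x[i0:i1]) - min(x[i0:i1]),
        kind = "spindle", stage = stage)
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(channel = character(), onset_s = double(),
                   duration_s = double(), amplitude_uV = double(),
                   kind = character(), stage = character())
}

#' Per-channel spindle statistics with zero-spindle rules
#'
#' Per channel: spindle count and mean duration within the requested stage.
#' Channels without events report 0 for both; a subject with no events on
#' any channel is excluded from that stage's analysis (inclusion flag
#' `FALSE`).
#'
#' @param events stage-filtered spindle event table.
#' @param channels all channel labels analyzed.
#' @return list with `stats` (tibble: channel, count, mean_duration_s) and
#'   `included` (logical).
#' @export
spindle_stats <- function(events, channels) {
  per_ch <- dplyr::summarise(
    dplyr::group_by(events, .data$channel),
    count = dplyr::n(), mean_duration_s = mean(.data$duration_s),
    .groups = "drop")
  stats <- tibble::tibble(channel = channels) |>
    dplyr::left_join(per_ch, by = "channel") |>
    tidyr::replace_na(list(count = 0L, mean_duration_s = 0))
  list(stats = stats, included = nrow(events) > 0)
}

#' Slow-wave summary for one recording
#'
#' Runs [slow_wave_filter()], [detect_slow_waves()] and [slow_wave_stats()]
#' per channel.
#'
#' @param rec cleaned [nap_recording()].
#' @param mask an [artifact_mask()] or `NULL`.
#' @param hyp a [hypnogram()] or `NULL`.
#' @param ... passed to [detect_slow_waves()].
#' @return tibble with one row per channel: `channel`, `mean_amplitude`,
#'   `density`, `summation`, `n_valid_epochs`.
#' @export
slow_wave_table <- function(rec, mask = NULL, hyp = NULL, ...) {
  rows <- lapply(seq_len(nrow(rec$data)), function(ci) {
    flt <- slow_wave_filter(rec$data[ci, ], rec$sampling_rate)
    m <- if (is.null(mask)) NULL else mask$bad_samples[rec$channel_names[ci], ]
    ev <- detect_slow_waves(flt, rec$sampling_rate, m, hyp,
                            channel = rec$channel_names[ci], ...)
    st <- slow_wave_stats(ev, attr(ev, "n_valid_epochs"))
    st$channel <- rec$channel_names[ci]
    st$n_valid_epochs <- attr(ev, "n_valid_epochs")
    st
  })
  dplyr::bind_rows(rows)[, c("channel", "mean_amplitude", "density",
                             "summation", "n_valid_epochs")]
}
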