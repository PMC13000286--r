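#' Preprocessing configuration
#'
#' Constants of the ten-step EEG cleaning pipeline: broadband 1-250 Hz,
#' 60 Hz line frequency, bad-channel scoring over 1-125 Hz at 3 sd with two
#' passes, ocular-component probability threshold 0.5, 100 uV amplitude
#' threshold with a 0.2-s dilation margin, 2-s power epochs at 3 sd,
#' 20% channel-drop fraction, and a 40 Hz final low-pass.
#'
#' @param broadband numeric length-2, bandpass edges in Hz.
#' @param line_freq line frequency in Hz.
#' @param harmonics line harmonics to remove (default just the fundamental).
#' @param badchan_band band for bad-channel log power, Hz.
#' @param badchan_z z threshold for bad channels (two-sided).
#' @param badchan_passes number of detection passes.
#' @param ocular_prob_threshold pseudo-probability above which an ICA
#'   component is removed as ocular.
#' @param amp_threshold amplitude artifact threshold, microvolts (strict >).
#' @param amp_margin dilation margin around amplitude artifacts, seconds.
#' @param epoch_len power-criterion epoch length, seconds.
#' @param epoch_z z threshold for power epochs (one-sided high).
#' @param channel_drop_fraction amplitude-flag fraction above which a
#'   channel is dropped (strict >).
#' @param badchan_min_sd absolute floor (log10 uV^2) on the across-channel
#'   sd used in bad-channel z-scoring, so sub-2x power differences are
#'   never flagged however homogeneous the montage.
#' @param lowpass final low-pass cutoff, Hz.
#' @param log_power_floor floor for log power of flat channels, uV^2.
#' @param ica_seed seed for the FastICA initialization.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(broadband = c(1, 250), line_freq = 60,
                              harmonics = 60,
                              badchan_band = c(1, 125), badchan_z = 3,
                              badchan_passes = 2,
                              ocular_prob_threshold = 0.5,
                              amp_threshold = 100, amp_margin = 0.2,
                              epoch_len = 2, epoch_z = 3,
                              channel_drop_fraction = 0.2, lowpass = 40,
                              badchan_min_sd = 0.2,
                              log_power_floor = 1e-12, ica_seed = 42L) {
  stopifnot(all(broadband > 0), broadband[1] < broadband[2],
            line_freq > 0, badchan_z > 0, amp_threshold > 0,
            amp_margin >= 0, epoch_len > 0, epoch_z > 0,
            channel_drop_fraction > 0, lowpass > 0,
            lowpass < broadband[2])
  structure(as.list(environment()), class = "preprocess_config")
}

#' Re-reference to the channel average, reconstructing the original reference
#'
#' Each channel becomes its value minus the across-channel mean, and the
#' former reference electrode is added back as a data channel equal to minus
#' that mean, so the output has one more channel than the input and a zero
#' column mean at every sample.
#'
#' @param rec a [nap_recording()].
#' @param reference_label label of the original reference (e.g. `"FCz"`).
#' @return a `nap_recording` with `n + 1` channels.
#' @export
rereference_average <- function(rec, reference_label = "FCz") {
  if (reference_label %in% rec$channel_names) {
    abort(paste0("reference label '", reference_label,
                 "' duplicates an existing data channel."))
  }
  avg <- colMeans(rec$data)
  newdata <- rbind(sweep(rec$data, 2, avg), -avg)
  nap_recording(newdata, c(rec$channel_names, reference_label),
                rec$sampling_rate, rec$block)
}

#' Remove power-line interference by sliding sinusoid regression
#'
#' Deterministic line removal: in 4-s windows with 50% overlap, a sine and
#' cosine at each target frequency are fitted by least squares and the
#' fitted sinusoid is subtracted, with Hann cross-fading between windows.
#' Narrowband by construction: frequencies 2 Hz or more away are essentially
#' untouched.
#'
#' @param rec a [nap_recording()].
#' @param line_freq frequencies to remove, Hz (default 60).
#' @param window_s regression window length in seconds.
#' @return a `nap_recording` with line components removed.
#' @export
remove_line_noise <- function(rec, line_freq = 60, window_s = 4) {
  rate <- rec$sampling_rate
  if (any(line_freq >= rate / 2)) {
    abort("line frequency must be below Nyquist.")
  }
  n <- ncol(rec$data)
  wlen <- min(n, round(window_s * rate))
  step <- max(1, floor(wlen / 2))
  starts <- unique(c(seq(1, max(1, n - wlen + 1), by = step), n - wlen + 1))
  out <- rec
  for (ci in seq_len(nrow(rec$data))) {
    x <- rec$data[ci, ]
    est <- numeric(n); wsum <- numeric(n)
    for (s in starts) {
      ii <- s:(s + wlen - 1)
      tt <- (ii - 1) / rate
      X <- do.call(cbind, lapply(line_freq, function(f) {
        cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
      }))
      fit <- stats::lm.fit(X, x[ii])
      w <- hann_window(wlen) + 1e-6
      est[ii] <- est[ii] + (x[ii] - fit$residuals) * w
      wsum[ii] <- wsum[ii] + w
    }
    out$data[ci, ] <- x - est / wsum
  }
  out
}

# Per-channel log total power in a band (periodogram sum), floored for
# flatlines so dead channels appear as low outliers.
channel_log_power <- function(rec, band, floor_uv2 = 1e-12) {
  vapply(seq_len(nrow(rec$data)), function(ci) {
    p <- periodogram_psd(rec$data[ci, ] - mean(rec$data[ci, ]),
                         rec$sampling_rate,
                         taper = rep(1, ncol(rec$data)))
    bp <- integrate_band(p$freq, p$psd, band[1], min(band[2],
                                                     rec$sampling_rate / 2))
    log10(max(bp, floor_uv2))
  }, numeric(1))
}

#' Two-pass bad-channel detection from broadband log power
#'
#' Per pass, each channel's log total power in `badchan_band` is compared
#' against the across-channel distribution; channels beyond `badchan_z` sd
#' from the center on either side are flagged and removed, and the
#' procedure repeats on the survivors. The center is the across-channel
#' median and the scale is the sd of the other channels (leave-one-out),
#' floored at `badchan_min_sd`: a plain pooled z is bounded near
#' sqrt(n - 1) and can never flag a lone extreme channel in a small
#' montage, while the leave-one-out scale keeps the pass-1 masking
#' behavior (an extreme channel inflating the scale for the others) that
#' motivates the second pass. With zero across-channel spread nothing is
#' flagged. Errors if every channel ends up flagged.
#'
#' @param rec a [nap_recording()].
#' @param config a [preprocess_config()].
#' @return tibble with columns `channel`, `pass`, `z`.
#' @export
detect_bad_channels <- function(rec, config = preprocess_config()) {
  if (nrow(rec$data) < 4) abort("need at least 4 channels.")
  survivors <- rec$channel_names
  out <- list()
  for (p in seq_len(config$badchan_passes)) {
    sub <- select_channels(rec, survivors)
    lp <- channel_log_power(sub, config$badchan_band, config$log_power_floor)
    ctr <- median(lp)
    z <- vapply(seq_along(lp), function(i) {
      s <- sd(lp[-i])               # scale excludes the channel under test
      if (!is.finite(s)) return(0)
      if (s == 0 && config$badchan_min_sd == 0) return(0)
      (lp[i] - ctr) / max(s, config$badchan_min_sd)
    }, numeric(1))
    flagged <- abs(z) > config$badchan_z
    if (!any(flagged)) break
    out[[p]] <- tibble::tibble(channel = survivors[flagged], pass = p,
                               z = z[flagged])
    survivors <- survivors[!flagged]
    if (!length(survivors)) {
      abort("all channels flagged as bad; recording unusable.")
    }
  }
  if (!length(out)) {
    return(tibble::tibble(channel = character(), pass = integer(),
                          z = double()))
  }
  dplyr::bind_rows(out)
}

# Ocular pseudo-probability of an ICA component: half frontal concentration
# of its mixing column, half low-frequency (< 5 Hz) power fraction.
ocular_score <- function(mix_col, comp, channel_names, rate) {
  frontal <- grepl("^(Fp|AF)", channel_names)
  if (!any(frontal)) frontal <- grepl("^F", channel_names)
  w2 <- mix_col^2
  conc <- if (sum(w2) > 0) sum(w2[frontal]) / sum(w2) else 0
  conc_scaled <- min(1, conc / max(mean(frontal), 1e-9) / 4)  # 4x enrichment -> 1
  p <- periodogram_psd(comp - mean(comp), rate,
                       taper = rep(1, length(comp)))
  tot <- integrate_band(p$freq, p$psd, 0.1, min(45, rate / 2 * 0.99))
  low <- integrate_band(p$freq, p$psd, 0.1, 5)
  lowfrac <- if (tot > 0) low / tot else 0
  0.5 * conc_scaled + 0.5 * lowfrac
}

#' Remove ocular ICA components
#'
#' FastICA decomposition followed by a documented ocular heuristic: each
#' component receives a pseudo-probability in [0, 1] that averages (a) the
#' frontal concentration of its mixing column over Fp/AF-proximal channels
#' and (b) the fraction of its power below 5 Hz. Components scoring above
#' `ocular_prob_threshold` are zeroed before reconstruction.
#'
#' @param rec a [nap_recording()] (already line-filtered).
#' @param config a [preprocess_config()].
#' @param scorer optional replacement scoring function with signature
#'   `(mixing_column, component, channel_names, rate) -> [0,1]`.
#' @return list with `recording` and `components` (tibble: component,
#'   score, removed).
#' @export
remove_ocular_components <- function(rec, config = preprocess_config(),
                                     scorer = ocular_score) {
  if (ncol(rec$data) <= nrow(rec$data)) {
    abort("need more samples than channels for ICA.")
  }
  dec <- fastica_decompose(rec$data, seed = config$ica_seed)
  scores <- vapply(seq_len(nrow(dec$S)), function(k) {
    scorer(dec$A[, k], dec$S[k, ], rec$channel_names, rec$sampling_rate)
  }, numeric(1))
  drop <- which(scores > config$ocular_prob_threshold)
  recon <- fastica_reconstruct(dec, drop)
  out <- rec
  out$data <- recon
  rownames(out$data) <- rec$channel_names
  list(recording = out,
       components = tibble::tibble(component = seq_along(scores),
                                   score = scores,
                                   removed = seq_along(scores) %in% drop))
}

#' Amplitude artifact mask
#'
#' A sample is flagged iff its absolute amplitude strictly exceeds
#' `amp_threshold` (so a sample at exactly the threshold is clean); flagged
#' samples are dilated by `amp_margin` seconds on both sides, clipped at the
#' record edges.
#'
#' @param rec a [nap_recording()].
#' @param config a [preprocess_config()].
#' @return logical matrix, channels x samples.
#' @export
mark_amplitude_artifacts <- function(rec, config = preprocess_config()) {
  margin <- round(config$amp_margin * rec$sampling_rate)
  n <- ncol(rec$data)
  out <- matrix(FALSE, nrow(rec$data), n,
                dimnames = list(rec$channel_names, NULL))
  for (ci in seq_len(nrow(rec$data))) {
    hits <- which(abs(rec$data[ci, ]) > config$amp_threshold)
    if (!length(hits)) next
    flags <- logical(n)
    for (h in hits) {
      flags[max(1, h - margin):min(n, h + margin)] <- TRUE
    }
    out[ci, ] <- flags
  }
  out
}

#' Normalized-power (2-s epoch) artifact mask
#'
#' Per channel, the log power of each non-overlapping `epoch_len`-second
#' epoch is z-scored across that channel's epochs; epochs more than
#' `epoch_z` sd above the channel mean are flagged (one-sided high). A
#' trailing partial epoch is always flagged as unusable. Zero across-epoch
#' sd flags nothing.
#'
#' @param rec a [nap_recording()].
#' @param config a [preprocess_config()].
#' @return logical matrix, channels x samples (epoch flags expanded).
#' @export
mark_power_artifacts <- function(rec, config = preprocess_config()) {
  rate <- rec$sampling_rate
  n <- ncol(rec$data)
  elen <- round(config$epoch_len * rate)
  n_ep <- floor(n / elen)
  if (n_ep < 2) abort("record must cover at least 2 power epochs.")
  out <- matrix(FALSE, nrow(rec$data), n,
                dimnames = list(rec$channel_names, NULL))
  for (ci in seq_len(nrow(rec$data))) {
    pw <- vapply(seq_len(n_ep), function(e) {
      seg <- rec$data[ci, ((e - 1) * elen + 1):(e * elen)]
      log10(max(mean(seg^2), config$log_power_floor))
    }, numeric(1))
    s <- sd(pw)
    flags_ep <- if (s == 0 || !is.finite(s)) rep(FALSE, n_ep) else
      (pw - mean(pw)) / s > config$epoch_z
    for (e in which(flags_ep)) {
      out[ci, ((e - 1) * elen + 1):(e * elen)] <- TRUE
    }
    if (n_ep * elen < n) out[ci, (n_ep * elen + 1):n] <- TRUE
  }
  out
}

#' Drop channels saturated by amplitude artifacts and recompute masks
#'
#' Channels whose amplitude-flagged fraction strictly exceeds
#' `channel_drop_fraction` are added to the bad set; both artifact criteria
#' are then recomputed on the survivors to produce the final mask.
#'
#' @param rec a [nap_recording()].
#' @param amp_mask logical matrix from [mark_amplitude_artifacts()].
#' @param config a [preprocess_config()].
#' @return list with `dropped` (labels), `recording` (survivors only) and
#'   `mask` (an [artifact_mask()] recomputed on the survivors).
#' @export
drop_saturated_channels <- function(rec, amp_mask,
                                    config = preprocess_config()) {
  frac <- rowMeans(amp_mask)
  dropped <- rec$channel_names[frac > config$channel_drop_fraction]
  keep <- setdiff(rec$channel_names, dropped)
  if (!length(keep)) abort("every channel saturated; recording unusable.")
  sub <- select_channels(rec, keep)
  amp2 <- mark_amplitude_artifacts(sub, config)
  pow2 <- mark_power_artifacts(sub, config)
  mask <- artifact_mask(
    amp2 | pow2,
    bad_channels = tibble::tibble(channel = dropped,
                                  reason = "amplitude_saturation",
                                  pass = NA_integer_),
    criteria_log = tibble::tibble(
      criterion = c("amplitude", "power", "union"),
      fraction = c(mean(amp2), mean(pow2), mean(amp2 | pow2)))
  )
  list(dropped = dropped, recording = sub, mask = mask)
}

#' Run the full ten-step cleaning pipeline
#'
#' Executes, in order: channel subset to the montage, average re-reference
#' (re-adding the original reference), 1-250 Hz bandpass, line-noise
#' removal, two-pass bad-channel rejection, FastICA ocular removal,
#' amplitude + normalized-power artifact masking, saturated-channel drop
#' with mask recomputation, spherical-spline interpolation of all rejected
#' channels, and a final 40 Hz low-pass. Returns the cleaned recording, the
#' final artifact mask and a QC report of per-step counts and fractions.
#'
#' @param rec raw [nap_recording()] (data channels only, original reference
#'   not included).
#' @param config a [preprocess_config()].
#' @param reference_label original reference electrode label.
#' @param montage optional channel subset to retain before re-referencing.
#' @param positions electrode positions for interpolation (default derived
#'   from the 10-10 labels).
#' @return list of class `preprocess_result`: `recording`, `mask`, `qc`,
#'   `components`.
#' @export
run_preprocessing <- function(rec, config = preprocess_config(),
                              reference_label = "FCz", montage = NULL,
                              positions = NULL) {
  if (!is.null(montage)) rec <- select_channels(rec, montage)
  qc <- list(n_channels_in = nrow(rec$data))

  reref <- rereference_average(rec, reference_label)
  bp <- bandpass_recording(reref, config$broadband[1], config$broadband[2])
  ln <- remove_line_noise(bp, config$harmonics)

  badch <- detect_bad_channels(ln, config)
  qc$bad_channels_power <- badch$channel
  good <- setdiff(ln$channel_names, badch$channel)
  work <- select_channels(ln, good)

  ica <- remove_ocular_components(work, config)
  work <- ica$recording
  qc$ocular_components_removed <- sum(ica$components$removed)

  amp1 <- mark_amplitude_artifacts(work, config)
  qc$amplitude_fraction_initial <- mean(amp1)
  dropres <- drop_saturated_channels(work, amp1, config)
  qc$channels_dropped_saturation <- dropres$dropped
  work <- dropres$recording
  mask <- dropres$mask
  qc$amplitude_fraction <- mask$criteria_log$fraction[1]
  qc$power_fraction <- mask$criteria_log$fraction[2]
  qc$union_fraction <- mask$criteria_log$fraction[3]

  all_bad <- union(badch$channel, dropres$dropped)
  qc$n_interpolated <- length(all_bad)
  if (length(all_bad)) {
    # re-insert bad channels as zero rows, then reconstruct them
    full <- matrix(0, length(ln$channel_names), ncol(work$data),
                   dimnames = list(ln$channel_names, NULL))
    full[work$channel_names, ] <- work$data
    full_rec <- nap_recording(full, ln$channel_names, ln$sampling_rate,
                              ln$block)
    work <- interpolate_channels(full_rec, all_bad, positions)
    # interpolated channels inherit the union mask of their neighbors
    bs <- matrix(FALSE, length(ln$channel_names), ncol(work$data),
                 dimnames = list(ln$channel_names, NULL))
    bs[rownames(mask$bad_samples), ] <- mask$bad_samples
    bs[all_bad, ] <- matrix(mask_any_channel(mask),
                            length(all_bad), ncol(work$data), byrow = TRUE)
    mask <- artifact_mask(bs,
                          bad_channels = tibble::tibble(
                            channel = all_bad,
                            reason = ifelse(all_bad %in% badch$channel,
                                            "log_power", "amplitude_saturation"),
                            pass = NA_integer_),
                          criteria_log = mask$criteria_log)
  }

  cleaned <- lowpass_recording(work, config$lowpass)
  qc$n_channels_out <- nrow(cleaned$data)
  structure(list(recording = cleaned, mask = mask, qc = qc,
                 components = ica$components),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  cat(sprintf("  channels: %d in -> %d out (%d interpolated)\n",
              x$qc$n_channels_in, x$qc$n_channels_out, x$qc$n_interpolated))
  cat(sprintf("  flagged: amplitude %.2f%%, power %.2f%%, union %.2f%%\n",
              100 * x$qc$amplitude_fraction, 100 * x$qc$power_fraction,
              100 * x$qc$union_fraction))
  invisible(x)
}
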