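#' Pan-Tompkins QRS detection
#'
#' The classic chain: 5-15 Hz bandpass, derivative, squaring, moving-window
#' integration (150 ms), adaptive dual thresholds on the integrated signal
#' with search-back for missed beats, and a 0.2-s refractory period. Beat
#' times are refined to the local maximum of the bandpassed signal.
#'
#' @param x single-channel ECG in microvolts.
#' @param rate sampling rate (>= 100 Hz).
#' @return tibble of class `beat_series`: `time_s`, `provenance`
#'   (`"detected"`).
#' @export
detect_beats <- function(x, rate) {
  stopifnot(rate >= 100)
  bp <- butter_filtfilt(x, rate, 5, 15, order = 2)
  der <- c(0, diff(bp)) * rate
  sq <- der^2
  wlen <- max(1, round(0.150 * rate))
  mwi <- stats::filter(sq, rep(1 / wlen, wlen), sides = 1)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refractory <- round(0.2 * rate)
  # initialize thresholds from the first 2 s
  init <- mwi[seq_len(min(length(mwi), 2 * rate))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  rr_avg <- rate  # running RR estimate in samples (start at 1 s)
  i <- 2
  n <- length(mwi)
  cand <- which(diff(sign(diff(mwi))) < 0) + 1   # local maxima
  for (p in cand) {
    v <- mwi[p]
    if (v > thr1) {
      if (p - last > refractory) {
        peaks <- c(peaks, p)
        if (length(peaks) > 1) {
          rr_avg <- 0.875 * rr_avg + 0.125 * (p - last)
        }
        last <- p
        spki <- 0.125 * v + 0.875 * spki
      } else if (v > mwi[last]) {
        peaks[length(peaks)] <- p   # better peak within refractory
        last <- p
        spki <- 0.125 * v + 0.875 * spki
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    # search-back: no beat for 1.66 * RR -> accept best peak above thr1/2
    if (length(peaks) && p - last > 1.66 * rr_avg) {
      win <- cand[cand > last + refractory & cand <= p]
      if (length(win)) {
        best <- win[which.max(mwi[win])]
        if (mwi[best] > thr1 / 2) {
          peaks <- sort(c(peaks, best))
          last <- max(peaks)
          spki <- 0.25 * mwi[best] + 0.75 * spki
        }
      }
    }
  }
  if (length(peaks) < 2) abort("fewer than 2 beats detected.")
  # refine to R peak on the bandpassed signal (MWI lags by ~ wlen)
  half <- round(0.1 * rate)
  rpeaks <- vapply(peaks, function(p) {
    ii <- max(1, p - wlen - half):min(length(bp), p)
    ii[which.max(bp[ii])]
  }, numeric(1))
  rpeaks <- sort(unique(rpeaks))
  # collapse peaks closer than the refractory period
  keep <- c(TRUE, diff(rpeaks) > refractory)
  rpeaks <- rpeaks[keep]
  out <- tibble::tibble(time_s = (rpeaks - 1) / rate,
                        provenance = "detected")
  class(out) <- c("beat_series", class(out))
  out
}

#' Automated inter-beat-interval cleaning
#'
#' Automated analogue of interactive extreme inspection with the same
#' removal semantics: repeatedly examine the current minimum and maximum
#' IBI; if it lies outside physiologic bounds or more than `k_mad` MADs from
#' the series median, remove it together with its two neighboring intervals.
#' Iterate until both extremes pass. Segments left with a single interval
#' are deleted; adjacent segments are bridged by inserting one
#' spline-interpolated IBI, yielding one continuous series.
#'
#' @param beats `beat_series` tibble from [detect_beats()].
#' @param bounds physiologic IBI bounds in seconds.
#' @param k_mad MAD multiplier for the outlier rule.
#' @param max_removed_frac error out when more IBIs than this fraction are
#'   removed.
#' @return list of class `ibi_series`: `ibi` (tibble: `ibi_s`,
#'   `provenance`), `n_removed`, `n_bridged`.
#' @export
clean_ibi <- function(beats, bounds = c(0.3, 2.0), k_mad = 5,
                      max_removed_frac = 0.5) {
  ibi <- diff(beats$time_s)
  if (length(ibi) < 4) abort("need at least 4 inter-beat intervals.")
  n0 <- length(ibi)
  seg_id <- rep(1L, length(ibi))
  is_bad <- function(v, ref) {
    md <- median(ref); madv <- stats::mad(ref)
    if (v < bounds[1] || v > bounds[2]) return(TRUE)
    # zero MAD (majority of intervals identical): any deviation is extreme
    if (madv == 0) return(abs(v - md) > 0)
    abs(v - md) > k_mad * madv
  }
  repeat {
    if (!length(ibi)) abort("all intervals removed; ECG unusable.")
    i_min <- which.min(ibi); i_max <- which.max(ibi)
    target <- NULL
    if (is_bad(ibi[i_min], ibi)) target <- i_min
    else if (is_bad(ibi[i_max], ibi)) target <- i_max
    if (is.null(target)) break
    rm_idx <- intersect((target - 1):(target + 1), seq_along(ibi))
    # removal splits the series: bump segment ids after the cut
    seg_id[seq_along(seg_id) > max(rm_idx)] <-
      seg_id[seq_along(seg_id) > max(rm_idx)] + 1L
    ibi <- ibi[-rm_idx]; seg_id <- seg_id[-rm_idx]
    if ((n0 - length(ibi)) / n0 > max_removed_frac) {
      abort("more than half of the inter-beat intervals removed; ECG unusable.")
    }
  }
  # drop 1-interval segments
  keep_segs <- names(which(table(seg_id) > 1))
  sel <- seg_id %in% as.integer(keep_segs)
  ibi <- ibi[sel]; seg_id <- seg_id[sel]
  if (!length(ibi)) abort("no usable segments after cleaning.")
  # bridge neighboring segments with one spline-interpolated point
  segs <- unique(seg_id)
  out_ibi <- numeric(0); prov <- character(0)
  n_bridged <- 0L
  for (k in seq_along(segs)) {
    seg_vals <- ibi[seg_id == segs[k]]
    if (k > 1) {
      prev_vals <- out_ibi[prov != "bridged"]
      xs <- c(seq_along(tail(prev_vals, 4)),
              length(tail(prev_vals, 4)) + 1 + seq_along(head(seg_vals, 4)))
      ys <- c(tail(prev_vals, 4), head(seg_vals, 4))
      mid <- length(tail(prev_vals, 4)) + 0.5 + 0.5
      br <- stats::spline(xs, ys, xout = length(tail(prev_vals, 4)) + 1)$y
      out_ibi <- c(out_ibi, br); prov <- c(prov, "bridged")
      n_bridged <- n_bridged + 1L
    }
    out_ibi <- c(out_ibi, seg_vals)
    prov <- c(prov, rep("detected", length(seg_vals)))
  }
  structure(list(
    ibi = tibble::tibble(ibi_s = out_ibi, provenance = prov),
    n_removed = n0 - sum(prov == "detected"),
    n_bridged = n_bridged), class = "ibi_series")
}

#' The 11 heart-rate metrics
#'
#' Time-domain metrics from the cleaned IBI series and the instantaneous
#' heart rate HR = 60/IBI: rangeIBI, meanIBI, medianIBI, sdIBI, RMSSD,
#' meanHR, sdHR, and the HRV triangular index (IBI count divided by the
#' modal count of the 1/128-s-bin histogram). Spectral metrics come from
#' the IBI series resampled at 4 Hz by cubic spline and a Hann-segment
#' Welch PSD: nLF and nHF are the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz)
#' powers normalized to their sum (nLF + nHF = 100), and LFHF their ratio.
#' When total LF+HF power is zero the spectral metrics are `NA`.
#'
#' @param series an `ibi_series` from [clean_ibi()], or a numeric vector of
#'   IBIs in seconds.
#' @param lf,hf band edges in Hz.
#' @param resample_rate IBI resampling rate in Hz.
#' @return one-row tibble with the 11 metrics.
#' @export
hrv_metrics <- function(series, lf = c(0.04, 0.15), hf = c(0.15, 0.4),
                        resample_rate = 4) {
  ibi <- if (inherits(series, "ibi_series")) series$ibi$ibi_s else
    as.numeric(series)
  if (length(ibi) < 10) abort("need at least 10 inter-beat intervals.")
  hr <- 60 / ibi
  # triangular index: N over the modal bin count of the 1/128 s histogram
  binw <- 1 / 128
  bins <- floor(ibi / binw)
  hrvti <- length(ibi) / max(table(bins))

  t_beats <- cumsum(c(0, ibi))[-1]
  out <- tibble::tibble(
    rangeIBI = max(ibi) - min(ibi),
    meanIBI = mean(ibi), medianIBI = median(ibi), sdIBI = sd_pop0(ibi),
    RMSSD = sqrt(mean(diff(ibi)^2)),
    meanHR = mean(hr), sdHR = sd_pop0(hr),
    HRVTi = hrvti,
    nLF = NA_real_, nHF = NA_real_, LFHF = NA_real_)
  # spectral metrics on the evenly resampled IBI series
  tt <- seq(t_beats[1], t_beats[length(t_beats)], by = 1 / resample_rate)
  if (length(tt) >= 32) {
    ri <- stats::spline(t_beats, ibi, xout = tt)$y
    w <- welch_psd(ri, resample_rate,
                   seg_len = min(length(ri), 256))
    lfp <- integrate_band(w$freq, w$psd, lf[1], lf[2])
    hfp <- integrate_band(w$freq, w$psd, hf[1], hf[2])
    if (lfp + hfp > 0) {
      out$nLF <- 100 * lfp / (lfp + hfp)
      out$nHF <- 100 * hfp / (lfp + hfp)
      out$LFHF <- if (hfp > 0) lfp / hfp else Inf
    }
  }
  out
}

# sd that returns 0 (not NA) for degenerate zero-variance input of length 1+
sd_pop0 <- function(x) if (length(x) < 2) 0 else sd(x)
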