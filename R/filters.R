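# Zero-phase filtering helpers shared across modules. Butterworth IIR
# (order 4 unless noted) run forward-backward via signal::filtfilt, so the
# effective magnitude response is squared and phase is zero.

butter_filtfilt <- function(x, rate, low = NULL, high = NULL, order = 4) {
  nyq <- rate / 2
  if (!is.null(high) && high >= nyq) high <- NULL   # unreachable edge: drop
  if (is.null(low) && is.null(high)) return(x)
  flt <- if (!is.null(low) && !is.null(high)) {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(low)) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, high / nyq, type = "low")
  }
  signal::filtfilt(flt, x)
}

filter_recording <- function(rec, low = NULL, high = NULL, order = 4) {
  out <- rec
  out$data <- t(apply(rec$data, 1, butter_filtfilt, rate = rec$sampling_rate,
                      low = low, high = high, order = order))
  if (nrow(rec$data) == 1) out$data <- matrix(out$data, nrow = 1)
  rownames(out$data) <- rec$channel_names
  out
}

#' Broadband bandpass filter
#'
#' Zero-phase order-4 Butterworth bandpass. When the upper edge is at or
#' above Nyquist (e.g. a 250 Hz edge on a 250 Hz recording) only the
#' high-pass section is applied.
#'
#' @param rec a [nap_recording()].
#' @param low,high band edges in Hz.
#' @return filtered `nap_recording`.
#' @export
bandpass_recording <- function(rec, low = 1, high = 250) {
  filter_recording(rec, low = low, high = high)
}

#' Low-pass filter
#'
#' @param rec a [nap_recording()].
#' @param high cutoff in Hz (default 40).
#' @return filtered `nap_recording`.
#' @export
lowpass_recording <- function(rec, high = 40) {
  filter_recording(rec, high = high)
}

# Hann window (periodic-symmetric as used for PSD tapers)
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# One-sided periodogram of a (tapered) segment; returns power density in
# units^2/Hz at frequencies k * rate / n, k = 0..floor(n/2).
periodogram_psd <- function(x, rate, taper = hann_window(length(x))) {
  n <- length(x)
  xw <- x * taper
  u <- sum(taper^2)                      # taper power normalization
  sp <- abs(fft(xw))^2 / (u * rate)
  keep <- 1:(floor(n / 2) + 1)
  psd <- sp[keep]
  # fold in the negative frequencies (all bins except DC and Nyquist)
  inner <- 2:(length(keep) - if (n %% 2 == 0) 1 else 0)
  psd[inner] <- 2 * psd[inner]
  list(freq = (keep - 1) * rate / n, psd = psd)
}

# Welch PSD: Hann-tapered segments with 50% overlap, averaged periodograms.
welch_psd <- function(x, rate, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  taper <- hann_window(seg_len)
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- seg - mean(seg)
    p <- periodogram_psd(seg, rate, taper)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  list(freq = p$freq, psd = acc / length(starts))
}

# Least-squares sinusoid power spectrum (Lomb-Scargle-style) for unevenly
# sampled series; returns, per frequency, the variance explained by a fitted
# sine+cosine pair.
lsq_spectrum <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
    fit <- stats::lm.fit(X, y)
    (sum(y^2) - sum(fit$residuals^2)) / length(y)
  }, numeric(1))
}

# Band power from a one-sided PSD by trapezoidal integration over [lo, hi].
integrate_band <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (sum(sel) < 2) return(sum(psd[sel]) * if (length(freq) > 1) diff(freq[1:2]) else 1)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}
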