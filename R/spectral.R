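#' Band schemes
#'
#' The primary scheme: Delta (0.5-3.5), Theta (3.5-7.5), Alpha (7.5-12.5),
#' Sigma (12.5-16.5) and Beta (14.5-30.5) Hz — note the intentional
#' Sigma/Beta overlap. The alternative scheme splits Delta into Delta1
#' (0.5-2.5) and Delta2 (2.5-4.5) with Theta at 4.5-7.5.
#'
#' @param scheme `"primary"` or `"delta_split"`.
#' @return tibble with columns `band`, `low`, `high`.
#' @export
band_scheme <- function(scheme = c("primary", "delta_split")) {
  scheme <- match.arg(scheme)
  out <- if (scheme == "primary") {
    tibble::tibble(
      band = c("Delta", "Theta", "Alpha", "Sigma", "Beta"),
      low = c(0.5, 3.5, 7.5, 12.5, 14.5),
      high = c(3.5, 7.5, 12.5, 16.5, 30.5))
  } else {
    tibble::tibble(
      band = c("Delta1", "Delta2", "Theta"),
      low = c(0.5, 2.5, 4.5),
      high = c(2.5, 4.5, 7.5))
  }
  stopifnot(all(out$low < out$high))
  out
}

#' Artifact-free 2-s segment windows
#'
#' Non-overlapping `seg_len`-second windows from the block start; a window
#' survives only if no sample of any channel is flagged anywhere inside it
#' (the any-channel rule).
#'
#' @param rec a [nap_recording()].
#' @param mask an [artifact_mask()] aligned to `rec` (or `NULL` for none).
#' @param seg_len segment length in seconds (default 2).
#' @return tibble with columns `segment`, `start_sample`, `end_sample`,
#'   `valid`.
#' @export
valid_segments <- function(rec, mask = NULL, seg_len = 2) {
  n <- ncol(rec$data)
  slen <- round(seg_len * rec$sampling_rate)
  n_seg <- floor(n / slen)
  any_flag <- if (is.null(mask)) rep(FALSE, n) else mask_any_channel(mask)
  segs <- tibble::tibble(
    segment = seq_len(n_seg),
    start_sample = (seq_len(n_seg) - 1) * slen + 1,
    end_sample = seq_len(n_seg) * slen
  )
  segs$valid <- vapply(seq_len(n_seg), function(i) {
    !any(any_flag[segs$start_sample[i]:segs$end_sample[i]])
  }, logical(1))
  if (!any(segs$valid)) {
    abort("no artifact-free segments; subject unusable for spectra.")
  }
  segs
}

#' Mean PSD over valid segments at 1 Hz resolution
#'
#' Per valid segment and channel, a Hann-tapered periodogram is computed;
#' the two native 0.5 Hz bins around each integer frequency are aggregated
#' into integer-centered 1 Hz bins, and linear PSDs are averaged across
#' segments before any dB conversion.
#'
#' @param rec a [nap_recording()].
#' @param segments tibble from [valid_segments()].
#' @return tibble with columns `channel`, `freq` (integer Hz), `psd`
#'   (uV^2/Hz), and attribute `n_segments`.
#' @export
segment_psd <- function(rec, segments) {
  use <- segments[segments$valid, , drop = FALSE]
  if (!nrow(use)) abort("no valid segments.")
  rate <- rec$sampling_rate
  slen <- use$end_sample[1] - use$start_sample[1] + 1
  taper <- hann_window(slen)
  freqs_native <- (0:(floor(slen / 2))) * rate / slen
  # native bins at b - 0.5 and b aggregate into the integer-centered bin b
  int_bin <- as.integer(floor(freqs_native + 0.5 - 1e-9))
  keep <- int_bin >= 1 & abs(freqs_native - int_bin) <= 0.5
  out <- list()
  for (ci in seq_len(nrow(rec$data))) {
    acc <- NULL
    for (si in seq_len(nrow(use))) {
      seg <- rec$data[ci, use$start_sample[si]:use$end_sample[si]]
      p <- periodogram_psd(seg - mean(seg), rate, taper)
      acc <- if (is.null(acc)) p$psd else acc + p$psd
    }
    acc <- acc / nrow(use)
    agg <- tapply(acc[keep], int_bin[keep], mean)
    out[[ci]] <- tibble::tibble(channel = rec$channel_names[ci],
                                freq = as.integer(names(agg)),
                                psd = as.numeric(agg))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_segments") <- nrow(use)
  res
}

#' Band power in decibels
#'
#' Band power is `10 * log10(sum of the PSD at the integer bins assigned to
#' the band + floor)`. A band with half-integer edges `(l, h)` collects the
#' integer bins `b` with `l < b <= h`, so Delta = \{1,2,3\}, Theta =
#' \{4..7\}, Alpha = \{8..12\}, Sigma = \{13..16\}, Beta = \{15..30\}
#' (bins 15 and 16 are shared between Sigma and Beta).
#'
#' @param psd tibble from [segment_psd()].
#' @param scheme tibble from [band_scheme()].
#' @param floor_uv2 additive floor keeping dB finite on silent channels.
#' @return tibble with columns `channel`, `band`, `power_db`.
#' @export
band_power_db <- function(psd, scheme = band_scheme(), floor_uv2 = 1e-12) {
  rows <- list()
  for (bi in seq_len(nrow(scheme))) {
    bins <- psd$freq > scheme$low[bi] & psd$freq <= scheme$high[bi]
    sub <- psd[bins, , drop = FALSE]
    agg <- dplyr::summarise(dplyr::group_by(sub, .data$channel),
                            power_db = 10 * log10(sum(.data$psd) + floor_uv2),
                            .groups = "drop")
    agg$band <- scheme$band[bi]
    rows[[bi]] <- agg
  }
  dplyr::bind_rows(rows)[, c("channel", "band", "power_db")]
}

#' Band-power table for one subject
#'
#' Convenience wrapper chaining [valid_segments()], [segment_psd()] and
#' [band_power_db()].
#'
#' @param rec cleaned [nap_recording()].
#' @param mask an [artifact_mask()] or `NULL`.
#' @param scheme tibble from [band_scheme()].
#' @param seg_len segment length in seconds.
#' @return tibble with `channel`, `band`, `power_db`, `n_segments`.
#' @export
band_power_table <- function(rec, mask = NULL, scheme = band_scheme(),
                             seg_len = 2) {
  segs <- valid_segments(rec, mask, seg_len)
  psd <- segment_psd(rec, segs)
  bp <- band_power_db(psd, scheme)
  bp$n_segments <- attr(psd, "n_segments")
  bp
}
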