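#' Multichannel recording container
#'
#' A `nap_recording` holds a channels-by-samples matrix in microvolts together
#' with channel labels, the sampling rate and the experimental block the
#' signal belongs to (`round1`, `nap` or `round2`). All signal-level
#' operators in the package take and return this container; tabular products
#' derived from it are tibbles.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_names character vector of unique channel labels, one per row.
#' @param sampling_rate sampling rate in Hz.
#' @param block recording block label: `"round1"`, `"nap"` or `"round2"`.
#' @return An object of class `nap_recording`.
#' @examples
#' rec <- nap_recording(matrix(rnorm(500), 2), c("Cz", "Oz"), 250)
#' n_samples(rec)
#' @export
nap_recording <- function(data, channel_names, sampling_rate,
                          block = c("nap", "round1", "round2")) {
  block <- match.arg(block)
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` must have one label per data row.")
  }
  if (anyDuplicated(channel_names)) {
    abort("channel names must be unique.")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number.")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, channel_names = channel_names,
         sampling_rate = sampling_rate, block = block),
    class = "nap_recording"
  )
}

#' @export
print.nap_recording <- function(x, ...) {
  cat(sprintf("<nap_recording> %d channel(s) x %d samples @ %g Hz [%s, %.1f s]\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$block,
              ncol(x$data) / x$sampling_rate))
  cat("channels:", paste(utils::head(x$channel_names, 10), collapse = ", "),
      if (length(x$channel_names) > 10) "..." else "", "\n")
  invisible(x)
}

#' @rdname nap_recording
#' @param x a `nap_recording`.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname nap_recording
#' @export
duration_s <- function(x) ncol(x$data) / x$sampling_rate

#' Subset a recording to a set of channels
#'
#' @param x a `nap_recording`.
#' @param channels channel labels to keep (order preserved as given).
#' @return a `nap_recording` with the requested channels.
#' @export
select_channels <- function(x, channels) {
  missing_ch <- setdiff(channels, x$channel_names)
  if (length(missing_ch)) {
    abort(paste0("unknown channel(s): ", paste(missing_ch, collapse = ", ")))
  }
  nap_recording(x$data[channels, , drop = FALSE], channels,
                x$sampling_rate, x$block)
}

#' Hypnogram construction
#'
#' A hypnogram is the sequence of 30-s sleep-stage labels over the nap
#' interval, stored as a tibble with one row per epoch and attributes for the
#' lights-off/lights-on bounds. Stages use the five-label alphabet
#' W, N1, N2, SWS, REM.
#'
#' @param stages character vector of per-epoch stage labels.
#' @param epoch_len epoch length in seconds (30 by convention).
#' @param lights_off start of the nap interval in seconds (default 0).
#' @return tibble of class `hypnogram` with columns `epoch`, `onset_s`, `stage`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2"))
#' stage_percentages(h)
#' @export
hypnogram <- function(stages, epoch_len = 30, lights_off = 0) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), sleep_stages())
  if (length(bad)) {
    abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  if (!length(stages)) abort("hypnogram needs at least one epoch.")
  out <- tibble::tibble(
    epoch = seq_along(stages),
    onset_s = lights_off + (seq_along(stages) - 1) * epoch_len,
    stage = stages
  )
  attr(out, "epoch_len") <- epoch_len
  attr(out, "lights_off") <- lights_off
  attr(out, "lights_on") <- lights_off + length(stages) * epoch_len
  class(out) <- c("hypnogram", class(out))
  out
}

#' @rdname hypnogram
#' @export
sleep_stages <- function() c("W", "N1", "N2", "SWS", "REM")

#' Stage label at given times
#'
#' @param hyp a [hypnogram()].
#' @param times_s numeric vector of times in seconds.
#' @return character vector of stage labels (`NA` outside the nap interval).
#' @export
stage_at <- function(hyp, times_s) {
  epoch_len <- attr(hyp, "epoch_len")
  lights_off <- attr(hyp, "lights_off")
  idx <- floor((times_s - lights_off) / epoch_len) + 1
  out <- rep(NA_character_, length(times_s))
  ok <- idx >= 1 & idx <= nrow(hyp)
  out[ok] <- hyp$stage[idx[ok]]
  out
}

#' Percentage of nap time spent in each stage
#'
#' Stage percentages are computed over the lights-off to lights-on interval,
#' i.e. over all scored epochs of the nap opportunity.
#'
#' @param hyp a [hypnogram()].
#' @return tibble with columns `stage` and `percent`; percentages sum to 100.
#' @export
stage_percentages <- function(hyp) {
  counts <- table(factor(hyp$stage, levels = sleep_stages()))
  tibble::tibble(
    stage = names(counts),
    percent = 100 * as.numeric(counts) / nrow(hyp)
  )
}

#' Artifact mask container
#'
#' Per-channel boolean sample masks plus the set of rejected channels; the
#' contract consumed by every downstream "artifact-free" selection.
#'
#' @param bad_samples logical matrix, channels x samples; `TRUE` = artifact.
#' @param bad_channels tibble with columns `channel`, `reason`, `pass`.
#' @param criteria_log tibble with per-criterion flagged fractions.
#' @return object of class `artifact_mask`.
#' @export
artifact_mask <- function(bad_samples, bad_channels = NULL, criteria_log = NULL) {
  stopifnot(is.matrix(bad_samples), is.logical(bad_samples))
  if (is.null(bad_channels)) {
    bad_channels <- tibble::tibble(channel = character(), reason = character(),
                                   pass = integer())
  }
  if (is.null(criteria_log)) {
    criteria_log <- tibble::tibble(criterion = character(), fraction = double())
  }
  structure(list(bad_samples = bad_samples, bad_channels = bad_channels,
                 criteria_log = criteria_log),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d channel(s), %.2f%% samples flagged, %d bad channel(s)\n",
              nrow(x$bad_samples), 100 * mean(x$bad_samples),
              nrow(x$bad_channels)))
  invisible(x)
}

#' Union of per-channel masks across channels
#'
#' @param mask an [artifact_mask()].
#' @return logical vector, `TRUE` where any channel is flagged.
#' @export
mask_any_channel <- function(mask) {
  apply(mask$bad_samples, 2, any)
}
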