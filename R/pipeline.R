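#' Pipeline run configuration
#'
#' Paths and settings for the staged pipeline: where artifacts live, the
#' synthetic-cohort spec used by the `simulate` stage, preprocessing
#' constants, band scheme, permutation settings and the covariate set for
#' the `correlate` stage.
#'
#' @param out_dir artifact directory (created if absent).
#' @param spec a [cohort_spec()] for simulation.
#' @param preprocess a [preprocess_config()].
#' @param scheme band scheme name for [band_scheme()].
#' @param n_permutations permutation count for the correlate stage.
#' @param covariate_set one of `"none"`, `"R1"`, `"Exp"`, `"R1+Exp"`.
#' @param seed integer master seed.
#' @param ecg_duration_s simulated round-1 ECG length.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, spec = cohort_spec(),
                            preprocess = preprocess_config(),
                            scheme = "primary", n_permutations = 1000,
                            covariate_set = c("none", "R1", "Exp", "R1+Exp"),
                            seed = 1L, ecg_duration_s = 60) {
  covariate_set <- match.arg(covariate_set)
  structure(list(out_dir = out_dir, spec = spec, preprocess = preprocess,
                 scheme = scheme, n_permutations = n_permutations,
                 covariate_set = covariate_set, seed = as.integer(seed),
                 ecg_duration_s = ecg_duration_s),
            class = "pipeline_config")
}

art_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

need_artifact <- function(cfg, rel, producer) {
  p <- art_path(cfg, rel)
  if (!file.exists(p)) {
    abort(paste0("missing artifact '", rel, "'; run the '", producer,
                 "' stage first."))
  }
  p
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

mask_to_intervals <- function(mask, rate) {
  rows <- list()
  for (ch in rownames(mask$bad_samples)) {
    r <- rle(mask$bad_samples[ch, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        channel = ch, start_s = (starts[k] - 1) / rate,
        end_s = ends[k] / rate, criterion = "union")
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(channel = character(), start_s = double(),
                   end_s = double(), criterion = character())
}

intervals_to_mask <- function(intervals, channel_names, rate, n) {
  bs <- matrix(FALSE, length(channel_names), n,
               dimnames = list(channel_names, NULL))
  for (i in seq_len(nrow(intervals))) {
    i0 <- floor(intervals$start_s[i] * rate) + 1
    i1 <- min(n, round(intervals$end_s[i] * rate))
    bs[intervals$channel[i], i0:i1] <- TRUE
  }
  artifact_mask(bs)
}

stage_simulate <- function(cfg) {
  dir.create(art_path(cfg, "raw"), recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(cfg$spec, ecg_duration_s = cfg$ecg_duration_s,
                         seed = cfg$seed)
  for (s in coh$subjects) {
    write_edf(s$eeg, art_path(cfg, "raw", paste0(s$subject, "_nap.edf")))
    write_edf(s$ecg, art_path(cfg, "raw", paste0(s$subject, "_ecg_round1.edf")))
    write_csv_plain(
      tibble::tibble(epoch_index = s$hypnogram$epoch, stage = s$hypnogram$stage),
      art_path(cfg, "raw", paste0(s$subject, "_hypnogram.csv")))
    jsonlite::write_json(
      list(subject = s$subject, role = s$role,
           events = s$truth$events, bad_channels = s$truth$bad_channels,
           artifacts = s$truth$artifacts, beat_times = s$beat_times),
      art_path(cfg, "raw", paste0(s$subject, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_csv_plain(coh$ratings, art_path(cfg, "ratings.csv"))
  write_csv_plain(coh$counts, art_path(cfg, "counts.csv"))
  write_csv_plain(coh$experience, art_path(cfg, "experience.csv"))
  write_csv_plain(coh$physiology, art_path(cfg, "physiology.csv"))
  write_csv_plain(tibble::tibble(subject = vapply(coh$subjects, `[[`, "",
                                                  "subject"),
                                 role = vapply(coh$subjects, `[[`, "", "role")),
                  art_path(cfg, "subjects.csv"))
  invisible(coh)
}

pipeline_subjects <- function(cfg) {
  p <- need_artifact(cfg, "subjects.csv", "simulate")
  utils::read.csv(p, stringsAsFactors = FALSE)
}

stage_preprocess <- function(cfg) {
  subs <- pipeline_subjects(cfg)
  dir.create(art_path(cfg, "clean"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(subs))) {
    sid <- subs$subject[i]
    raw <- read_edf(need_artifact(cfg, file.path("raw", paste0(sid, "_nap.edf")),
                                  "simulate"))
    res <- run_preprocessing(raw, cfg$preprocess)
    write_edf(res$recording, art_path(cfg, "clean", paste0(sid, "_nap.edf")))
    write_csv_plain(mask_to_intervals(res$mask, res$recording$sampling_rate),
                    art_path(cfg, "clean", paste0(sid, "_mask.csv")))
    jsonlite::write_json(res$qc,
                         art_path(cfg, "clean", paste0(sid, "_qc.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

read_clean <- function(cfg, sid) {
  rec <- read_edf(need_artifact(cfg, file.path("clean", paste0(sid, "_nap.edf")),
                                "preprocess"))
  iv <- utils::read.csv(need_artifact(cfg,
                                      file.path("clean", paste0(sid, "_mask.csv")),
                                      "preprocess"), stringsAsFactors = FALSE)
  mask <- intervals_to_mask(iv, rec$channel_names, rec$sampling_rate,
                            ncol(rec$data))
  list(recording = rec, mask = mask)
}

read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hypnogram(df$stage)
}

stage_spectra <- function(cfg) {
  subs <- pipeline_subjects(cfg)
  rows <- list()
  for (sid in subs$subject) {
    cl <- read_clean(cfg, sid)
    bp <- band_power_table(cl$recording, cl$mask, band_scheme(cfg$scheme))
    bp$subject <- sid
    rows[[sid]] <- bp
  }
  write_csv_plain(dplyr::bind_rows(rows), art_path(cfg, "band_power.csv"))
}

stage_events <- function(cfg) {
  subs <- pipeline_subjects(cfg)
  sw_rows <- list(); sp_rows <- list()
  for (sid in subs$subject) {
    cl <- read_clean(cfg, sid)
    hyp <- read_hypnogram_csv(
      need_artifact(cfg, file.path("raw", paste0(sid, "_hypnogram.csv")),
                    "simulate"))
    sw <- slow_wave_table(cl$recording, cl$mask, hyp)
    sw$subject <- sid
    sw_rows[[sid]] <- sw
    for (stg in c("N2", "SWS")) {
      ev <- dplyr::bind_rows(lapply(seq_len(nrow(cl$recording$data)),
        function(ci) {
          detect_spindles_a7(cl$recording$data[ci, ],
                             cl$recording$sampling_rate,
                             cl$mask$bad_samples[ci, ], hyp, stg,
                             channel = cl$recording$channel_names[ci])
        }))
      st <- spindle_stats(ev, cl$recording$channel_names)
      st$stats$subject <- sid
      st$stats$stage <- stg
      st$stats$included <- st$included
      sp_rows[[paste(sid, stg)]] <- st$stats
    }
  }
  write_csv_plain(dplyr::bind_rows(sw_rows), art_path(cfg, "slow_waves.csv"))
  write_csv_plain(dplyr::bind_rows(sp_rows), art_path(cfg, "spindles.csv"))
}

stage_hrv <- function(cfg) {
  subs <- pipeline_subjects(cfg)
  rows <- list()
  for (sid in subs$subject) {
    ecg <- read_edf(need_artifact(cfg,
                                  file.path("raw", paste0(sid, "_ecg_round1.edf")),
                                  "simulate"))
    beats <- detect_beats(ecg$data[1, ], ecg$sampling_rate)
    cleaned <- clean_ibi(beats)
    m <- hrv_metrics(cleaned)
    m$subject <- sid
    rows[[sid]] <- m
  }
  write_csv_plain(dplyr::bind_rows(rows), art_path(cfg, "hrv.csv"))
}

stage_reports <- function(cfg) {
  p <- need_artifact(cfg, "ratings.csv", "simulate")
  ratings <- tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  filled <- fill_blanks(ratings)
  cons <- consensus(filled)
  write_csv_plain(cons, art_path(cfg, "consensus.csv"))
  icc <- dplyr::bind_rows(lapply(paste0("s", 1:7), function(s) {
    tryCatch(icc_agreement(filled, s), error = function(e) {
      tibble::tibble(statement = s, icc = NA_real_, label = NA_character_,
                     form = "single",
                     n_reports = length(unique(filled$report_id)),
                     n_raters = length(unique(filled$rater)))
    })
  }))
  write_csv_plain(icc, art_path(cfg, "icc.csv"))
}

stage_scores <- function(cfg) {
  counts <- tibble::as_tibble(
    utils::read.csv(need_artifact(cfg, "counts.csv", "simulate"),
                    stringsAsFactors = FALSE))
  scores <- compute_scores(counts)
  write_csv_plain(scores, art_path(cfg, "scores.csv"))
  exp_answers <- tibble::as_tibble(
    utils::read.csv(need_artifact(cfg, "experience.csv", "simulate"),
                    stringsAsFactors = FALSE))
  write_csv_plain(experience_metric(exp_answers), art_path(cfg, "exp.csv"))
}

stage_correlate <- function(cfg) {
  bp <- utils::read.csv(need_artifact(cfg, "band_power.csv", "spectra"),
                        stringsAsFactors = FALSE)
  scores <- utils::read.csv(need_artifact(cfg, "scores.csv", "scores"),
                            stringsAsFactors = FALSE)
  subs <- pipeline_subjects(cfg)
  rows <- list()
  # per-role families need n >= 3; tiny cohorts fall back to a pooled family
  groups <- split(subs$subject, subs$role)
  if (all(lengths(groups) < 3)) groups <- list(all = subs$subject)
  groups <- groups[lengths(groups) >= 3]
  for (role in names(groups)) {
    ids <- groups[[role]]
    sc <- scores[match(ids, scores$subject), ]
    for (band in unique(bp$band)) {
      sub <- bp[bp$band == band & bp$subject %in% ids, ]
      wide <- tidyr::pivot_wider(sub[, c("subject", "channel", "power_db")],
                                 names_from = "subject",
                                 values_from = "power_db")
      feats <- as.matrix(wide[, ids, drop = FALSE])
      rownames(feats) <- wide$channel
      topo <- permutation_adjusted(feats, sc$gain,
                                   n_permutations = cfg$n_permutations,
                                   seed = cfg$seed,
                                   family = paste(role, band, sep = "_"))
      rows[[paste(role, band)]] <- tidy(topo)
    }
  }
  out <- dplyr::bind_rows(rows)
  write_csv_plain(out, art_path(cfg, "topography.csv"))
  jsonlite::write_json(
    list(seed = cfg$seed, n_permutations = cfg$n_permutations,
         covariate_set = cfg$covariate_set, scheme = cfg$scheme,
         families = unique(out$family)),
    art_path(cfg, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run pipeline stages
#'
#' Stages: `simulate`, `preprocess`, `spectra`, `events`, `hrv`, `reports`,
#' `scores`, `correlate`, or `run-all` for the full chain. Each stage
#' writes CSV/JSON artifacts under the configured output directory; a stage
#' whose upstream artifact is missing errors with a message naming the
#' producing stage.
#'
#' @param cfg a [pipeline_config()].
#' @param stages character vector of stage names.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(cfg, stages = "run-all") {
  all_stages <- c("simulate", "preprocess", "spectra", "events", "hrv",
                  "reports", "scores", "correlate")
  if (identical(stages, "run-all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in all_stages[all_stages %in% stages]) {
    switch(st,
           simulate = stage_simulate(cfg),
           preprocess = stage_preprocess(cfg),
           spectra = stage_spectra(cfg),
           events = stage_events(cfg),
           hrv = stage_hrv(cfg),
           reports = stage_reports(cfg),
           scores = stage_scores(cfg),
           correlate = stage_correlate(cfg))
  }
  invisible(cfg$out_dir)
}
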