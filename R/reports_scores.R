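#' Fill blank rater answers with 3.5
#'
#' Raters who disagreed that the participant dreamed (statement-1 answer of
#' 3 or less) leave statements 2-7 blank; those blanks are replaced by 3.5,
#' the middle of the agreement scale. Statement 1 is never filled — a blank
#' there is an error. A blank next to a statement-1 answer above 3 is
#' unexpected: it triggers a warning but is still filled.
#'
#' @param ratings tibble with columns `report_id`, `rater`, `s1`..`s7`
#'   (blanks as `NA`).
#' @return same shape with all `s2`..`s7` blanks replaced by 3.5.
#' @export
fill_blanks <- function(ratings) {
  stmt <- paste0("s", 2:7)
  if (any(is.na(ratings$s1))) {
    bad <- ratings[is.na(ratings$s1), c("report_id", "rater")]
    abort(paste0("blank statement-1 answer for report ", bad$report_id[1],
                 ", rater ", bad$rater[1]))
  }
  has_blank <- apply(is.na(ratings[stmt]), 1, any)
  unexpected <- has_blank & ratings$s1 > 3
  if (any(unexpected)) {
    warn(sprintf(
      "%d rating(s) have blanks although the rater agreed the participant dreamed (statement 1 > 3); filling anyway.",
      sum(unexpected)))
  }
  out <- ratings
  for (s in stmt) out[[s]][is.na(out[[s]])] <- 3.5
  out
}

#' Rater consensus per report
#'
#' Per statement, the consensus is the median across raters (an even rater
#' count averages the middle two). A report is flagged as a dream when the
#' statement-1 median is at least 3.5.
#'
#' @param ratings_filled tibble from [fill_blanks()].
#' @return tibble with `report_id`, medians `s1`..`s7`, and `dream`.
#' @export
consensus <- function(ratings_filled) {
  out <- dplyr::summarise(
    dplyr::group_by(ratings_filled, .data$report_id),
    dplyr::across(dplyr::all_of(paste0("s", 1:7)), ~ median(.x)),
    .groups = "drop")
  out$dream <- out$s1 >= 3.5
  out
}

#' Intraclass correlation for one statement
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC (the A,1
#' form) computed from the mean-squares decomposition of the complete
#' report x rater matrix:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`.
#' The qualitative label follows the conventional bins — below 0.50 poor,
#' 0.50-0.75 moderate, 0.75-0.90 good, above 0.90 excellent — with exact
#' boundaries assigned to the upper bin.
#'
#' @param ratings tibble with `report_id`, `rater` and statement columns.
#' @param statement statement column name (e.g. `"s1"`).
#' @param form `"single"` (A,1) or `"average"` (A,k).
#' @return one-row tibble: `statement`, `icc`, `label`, `form`, `n_reports`,
#'   `n_raters` (`icc` is `NA` when between-report variance is zero).
#' @export
icc_agreement <- function(ratings, statement, form = c("single", "average")) {
  form <- match.arg(form)
  wide <- tidyr::pivot_wider(ratings[, c("report_id", "rater", statement)],
                             names_from = "rater",
                             values_from = dplyr::all_of(statement))
  M <- as.matrix(wide[, -1])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M); k <- ncol(M)
  if (n < 3 || k < 2) abort("need at least 3 complete reports and 2 raters.")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((M - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || (ssr == 0)) {
    return(tibble::tibble(statement = statement, icc = NA_real_,
                          label = NA_character_, form = form,
                          n_reports = n, n_raters = k))
  }
  icc <- if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  tibble::tibble(statement = statement, icc = icc, label = icc_label(icc),
                 form = form, n_reports = n, n_raters = k)
}

#' @rdname icc_agreement
#' @param icc numeric ICC value.
#' @export
icc_label <- function(icc) {
  dplyr::case_when(
    icc >= 0.90 ~ "excellent",
    icc >= 0.75 ~ "good",
    icc >= 0.50 ~ "moderate",
    TRUE ~ "poor")
}

#' Game scores and gains from event counts
#'
#' Prey score = collections - losses; predator score = wins - losses; the
#' gain is the round-2 score minus the round-1 score.
#'
#' @param counts tibble with `subject`, `role`, `round`, `wins`, `losses`,
#'   `collections` (rounds 1 and 2 per subject).
#' @return tibble with `subject`, `role`, `score_round1`, `score_round2`,
#'   `gain`.
#' @export
compute_scores <- function(counts) {
  if (any(counts$wins < 0 | counts$losses < 0 | counts$collections < 0)) {
    abort("negative game counts are not allowed.")
  }
  counts$score <- ifelse(counts$role == "prey",
                         counts$collections - counts$losses,
                         counts$wins - counts$losses)
  wide <- tidyr::pivot_wider(counts[, c("subject", "role", "round", "score")],
                             names_from = "round", values_from = "score",
                             names_prefix = "score_round")
  wide$gain <- wide$score_round2 - wide$score_round1
  wide
}

#' Previous video-game experience metric (Exp)
#'
#' Each of the five experience questions is z-scored within role and the
#' five z-scores are summed per subject. A question with zero variance
#' within a role contributes 0 for all subjects of that role.
#'
#' @param answers tibble with `subject`, `role` and five numeric question
#'   columns.
#' @param question_cols names of the five question columns.
#' @return tibble with `subject`, `role`, `Exp`.
#' @export
experience_metric <- function(answers,
                              question_cols = setdiff(names(answers),
                                                      c("subject", "role"))) {
  dplyr::group_by(answers, .data$role) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) abort("need at least 2 subjects per role.")
      zsum <- rowSums(vapply(question_cols, function(q) {
        v <- df[[q]]
        s <- sd(v)
        if (s == 0 || !is.finite(s)) rep(0, length(v)) else (v - mean(v)) / s
      }, numeric(nrow(df))))
      tibble::tibble(subject = df$subject, Exp = zsum)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("subject", "role", "Exp")
}
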