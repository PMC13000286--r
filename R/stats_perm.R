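#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); equals
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` in the tie-free case. Undefined (NA)
#' when either variable has zero rank variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Spearman's rho, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(x) - 1) * sd(rx) * sd(ry))
}

# standardize mid-ranks to zero mean / unit norm so correlations become
# inner products (rows of the returned matrix have unit L2 norm)
standardize_ranks <- function(M) {
  R <- t(apply(M, 1, rank))
  R <- R - rowMeans(R)
  nrm <- sqrt(rowSums(R^2))
  ok <- nrm > 0
  R[ok, ] <- R[ok, , drop = FALSE] / nrm[ok]
  list(R = R, ok = ok)
}

#' Max-statistic permutation-adjusted correlation family
#'
#' Observed Spearman rho per feature against the outcome; the family-wise
#' null is built by permuting the outcome `n_permutations` times and
#' recording, per permutation, the maximum |rho| over all features. The
#' adjusted p for feature f is `(1 + #permutations with max |rho| >=
#' |rho_f|) / (n_permutations + 1)` (add-one convention, so p is never 0
#' and is floored at `1/(P+1)`). Subjects with a missing value in any row
#' are removed listwise; features whose rho is undefined are excluded and
#' reported. Rank correlations take discrete values, so the comparison
#' includes permutations tied with the observed |rho| (a 1e-12 tolerance
#' guards against floating-point representation differences).
#'
#' @param features numeric matrix, features x subjects (row names label the
#'   features), or a data frame of feature columns which is transposed.
#' @param outcome numeric outcome vector (e.g. score gains).
#' @param n_permutations permutation count P (study-scale default 1e5).
#' @param seed integer seed for the permutation stream.
#' @param family label carried into the output.
#' @param alpha significance level for the flag.
#' @return object of class `perm_topography`.
#' @export
permutation_adjusted <- function(features, outcome, n_permutations = 1e5,
                                 seed = 1L, family = "family",
                                 alpha = 0.05) {
  if (is.data.frame(features)) features <- t(as.matrix(features))
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("f", seq_len(nrow(features)))
  }
  stopifnot(ncol(features) == length(outcome))
  cc <- stats::complete.cases(t(features)) & !is.na(outcome)
  features <- features[, cc, drop = FALSE]
  outcome <- outcome[cc]
  n <- length(outcome)
  if (n < 3) abort("need at least 3 complete subjects.")

  sr <- standardize_ranks(features)
  ry <- rank(outcome)
  ry <- ry - mean(ry)
  nrm <- sqrt(sum(ry^2))
  if (nrm == 0) abort("outcome has zero rank variance.")
  ry <- ry / nrm
  rho <- as.numeric(sr$R %*% ry)
  rho[!sr$ok] <- NA_real_

  P <- as.integer(n_permutations)
  set.seed(seed)
  # permutation matrix of standardized outcome ranks: P x n
  perm_idx <- vapply(seq_len(P), function(i) sample.int(n), integer(n))
  Yp <- matrix(ry[perm_idx], nrow = n)          # n x P
  Rok <- sr$R[sr$ok, , drop = FALSE]
  null_rho <- abs(Rok %*% Yp)                   # features x P
  max_null <- apply(null_rho, 2, max)
  p_adj <- vapply(rho, function(r) {
    if (is.na(r)) NA_real_ else
      (1 + sum(max_null >= abs(r) - 1e-12)) / (P + 1)
  }, numeric(1))

  res <- tibble::tibble(
    family = family,
    feature = rownames(features),
    n = n,
    rho = rho,
    p_adj = p_adj,
    flag = !is.na(p_adj) & p_adj < alpha)
  structure(list(result = res, excluded = rownames(features)[!sr$ok],
                 n_permutations = P, seed = seed, alpha = alpha,
                 covariates = character(0)),
            class = "perm_topography")
}

#' Partial Spearman correlations with Freedman-Lane permutation adjustment
#'
#' All variables are rank-transformed; the partial correlation of a feature
#' with the outcome given covariates is the correlation of their residuals
#' after least-squares projection on the ranked covariates (plus
#' intercept). The null is built by Freedman-Lane residual permutation:
#' outcome-rank residuals from the reduced (covariate-only) model are
#' permuted, added back to the reduced fit, and the full partial
#' correlation is recomputed, with the same max-|rho| family correction.
#' An empty covariate set reduces exactly to [permutation_adjusted()].
#'
#' @param features features x subjects matrix (or data frame of columns).
#' @param outcome numeric outcome vector.
#' @param covariates numeric matrix/data frame of covariate columns
#'   (subjects x covariates), or `NULL`/zero columns for none.
#' @param n_permutations permutation count.
#' @param seed integer seed.
#' @param family label carried into the output.
#' @param alpha significance level.
#' @return object of class `perm_topography`.
#' @export
partial_spearman_adjusted <- function(features, outcome, covariates = NULL,
                                      n_permutations = 1e5, seed = 1L,
                                      family = "family", alpha = 0.05) {
  if (is.null(covariates) ||
      (!is.null(dim(covariates)) && ncol(as.matrix(covariates)) == 0)) {
    return(permutation_adjusted(features, outcome, n_permutations, seed,
                                family, alpha))
  }
  if (is.data.frame(features)) features <- t(as.matrix(features))
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("f", seq_len(nrow(features)))
  }
  Z <- as.matrix(covariates)
  stopifnot(ncol(features) == length(outcome), nrow(Z) == length(outcome))
  cc <- stats::complete.cases(t(features)) & !is.na(outcome) &
    stats::complete.cases(Z)
  features <- features[, cc, drop = FALSE]
  outcome <- outcome[cc]
  Z <- Z[cc, , drop = FALSE]
  n <- length(outcome)
  if (n <= ncol(Z) + 2) abort("too few subjects for the covariate set.")

  Zr <- cbind(1, apply(Z, 2, rank))
  qrz <- qr(Zr)
  if (qrz$rank < ncol(Zr)) {
    abort(paste0("collinear covariates: ",
                 paste(colnames(Z)[qrz$pivot[seq_len(ncol(Zr) - qrz$rank)]],
                       collapse = ", ")))
  }
  resid_on_z <- function(v) qr.resid(qrz, v)
  Xr <- t(apply(features, 1, rank))
  Ex <- t(apply(Xr, 1, resid_on_z))             # feature rank residuals
  nrmx <- sqrt(rowSums(Ex^2))
  ok <- nrmx > 1e-12
  Ex[ok, ] <- Ex[ok, , drop = FALSE] / nrmx[ok]

  yr <- rank(outcome)
  yhat <- qr.fitted(qrz, yr)
  ey <- yr - yhat
  partial_rho_of <- function(yvec) {
    e <- resid_on_z(yvec)
    nv <- sqrt(sum(e^2))
    if (nv < 1e-12) return(rep(0, nrow(Ex)))
    as.numeric(Ex %*% (e / nv))
  }
  rho <- partial_rho_of(yr)
  rho[!ok] <- NA_real_

  P <- as.integer(n_permutations)
  set.seed(seed)
  max_null <- vapply(seq_len(P), function(i) {
    ystar <- yhat + ey[sample.int(n)]
    max(abs(partial_rho_of(ystar)[ok]))
  }, numeric(1))
  p_adj <- vapply(rho, function(r) {
    if (is.na(r)) NA_real_ else
      (1 + sum(max_null >= abs(r) - 1e-12)) / (P + 1)
  }, numeric(1))

  res <- tibble::tibble(
    family = family, feature = rownames(features), n = n,
    rho = rho, p_adj = p_adj,
    flag = !is.na(p_adj) & p_adj < alpha)
  structure(list(result = res, excluded = rownames(features)[!ok],
                 n_permutations = P, seed = seed, alpha = alpha,
                 covariates = colnames(Z) %||% paste0("z", seq_len(ncol(Z)))),
            class = "perm_topography")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uncorrected two-group comparison for a priori checks
#'
#' Mann-Whitney U for continuous variables, chi-square on the contingency
#' table for categorical ones. No permutation correction is applied;
#' marginal significance is annotated at p < 0.1.
#'
#' @param a,b the two groups: numeric vectors (continuous) or vectors of
#'   category labels (categorical).
#' @param kind `"continuous"` or `"categorical"`.
#' @return one-row tibble: `kind`, `statistic`, `p_value`, `marginal`.
#' @export
group_compare <- function(a, b, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!length(a) || !length(b)) abort("both groups must be non-empty.")
  if (kind == "continuous") {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    tab <- table(factor(c(rep("a", length(a)), rep("b", length(b))),
                        levels = c("a", "b")),
                 c(as.character(a), as.character(b)))
    if (all(tab == 0)) abort("empty contingency table.")
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(kind = kind, statistic = stat, p_value = p,
                 marginal = p < 0.1)
}

#' @export
print.perm_topography <- function(x, ...) {
  cat(sprintf("<perm_topography> family '%s', %d feature(s), n = %d, P = %d",
              x$result$family[1], nrow(x$result), x$result$n[1],
              x$n_permutations))
  if (length(x$covariates)) {
    cat(", covariates:", paste(x$covariates, collapse = ", "))
  }
  cat(sprintf("\n  %d feature(s) significant at adjusted p < %g\n",
              sum(x$result$flag), x$alpha))
  invisible(x)
}

#' @rdname permutation_adjusted
#' @param x a `perm_topography`.
#' @param ... unused.
#' @export
tidy.perm_topography <- function(x, ...) x$result

#' @rdname permutation_adjusted
#' @export
glance.perm_topography <- function(x, ...) {
  tibble::tibble(
    family = x$result$family[1],
    n_features = nrow(x$result),
    n = x$result$n[1],
    n_permutations = x$n_permutations,
    n_significant = sum(x$result$flag, na.rm = TRUE),
    min_p_adj = min(x$result$p_adj, na.rm = TRUE),
    covariates = paste(x$covariates, collapse = "+"))
}

#' Plot a correlation topography as a scalp map
#'
#' Channels are placed by azimuthal-equidistant projection of their 10-10
#' positions; fill encodes rho and significant channels are outlined.
#'
#' @param object a `perm_topography` whose features are channel labels.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.perm_topography <- function(object, ...) {
  res <- object$result
  pos <- montage_positions(res$feature)
  # flatten: arc distance from vertex as radius
  r <- acos(pmin(1, pos$z))
  az <- atan2(pos$y, pos$x)
  df <- dplyr::mutate(res, px = r * cos(az), py = r * sin(az))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$rho,
                                     shape = .data$flag), size = 6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 22)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature), size = 2.5,
                       vjust = -1.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "rho", shape = paste0("adj p < ", object$alpha),
                  title = res$family[1])
}
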