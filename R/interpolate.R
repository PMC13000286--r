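# Spherical-spline scalp interpolation (order m = 4 splines).
# g(cos(angle)) is the spline kernel built from Legendre polynomials:
#   g(x) = (1 / 4pi) * sum_{n=1..N} (2n + 1) / (n^m (n + 1)^m) * P_n(x)

legendre_eval <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (nmax >= 3) {
    for (n in 3:nmax) {
      P[, n] <- ((2 * n - 1) * x * P[, n - 1] - (n - 1) * P[, n - 2]) / n
    }
  }
  P
}

spline_g <- function(x, m = 4, nmax = 50) {
  P <- legendre_eval(x, nmax)
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  as.numeric(P %*% coef) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs each bad channel from all good channels using order-4
#' spherical splines on the unit sphere: solve for spline weights on the
#' good electrodes (with the usual zero-sum constraint and constant term),
#' then evaluate the interpolant at the bad electrode positions. Good
#' channels are returned untouched.
#'
#' @param rec a [nap_recording()].
#' @param bad_channels labels of channels to reconstruct.
#' @param positions tibble from [montage_positions()] covering all channels.
#' @param stiffness spline order m (default 4).
#' @return a `nap_recording` with bad channels replaced by interpolants.
#' @export
interpolate_channels <- function(rec, bad_channels, positions = NULL,
                                 stiffness = 4) {
  if (!length(bad_channels)) return(rec)
  if (is.null(positions)) positions <- montage_positions(rec$channel_names)
  miss <- setdiff(rec$channel_names, positions$channel)
  if (length(miss)) {
    abort(paste0("no montage position for channel(s): ",
                 paste(miss, collapse = ", ")))
  }
  good <- setdiff(rec$channel_names, bad_channels)
  if (length(good) < 4) abort("need at least 4 good channels to interpolate.")
  pos <- as.matrix(positions[match(rec$channel_names, positions$channel),
                             c("x", "y", "z")])
  rownames(pos) <- rec$channel_names
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad_channels, , drop = FALSE]
  Ggg <- matrix(spline_g(pmin(1, pmax(-1, pg %*% t(pg))), m = stiffness),
                nrow(pg))
  Gbg <- matrix(spline_g(pmin(1, pmax(-1, pb %*% t(pg))), m = stiffness),
                nrow(pb))
  ng <- length(good)
  # constrained system: [G 1; 1' 0] [c; c0] = [V; 0]
  Amat <- rbind(cbind(Ggg, 1), c(rep(1, ng), 0))
  V <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(Amat, V)
  interp <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(pb), ncol(rec$data), byrow = TRUE)
  out <- rec
  out$data[bad_channels, ] <- interp
  out
}
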