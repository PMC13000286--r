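#' The 55-channel 10-10 montage
#'
#' Channel labels of the 55-channel subset of the extended 10-10 system used
#' throughout the package: the scalp rows AF through O plus the reconstructed
#' former reference FCz.
#'
#' @return character vector of 55 channel labels.
#' @export
montage_55 <- function() {
  c("AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}

#' Default 8-channel test montage
#'
#' A small frontal-to-occipital subset used as the generator default so the
#' test suite stays fast; the full 55-channel montage is available through
#' [montage_55()].
#'
#' @return character vector of 8 channel labels.
#' @export
montage_8 <- function() c("AF3", "F3", "FC1", "Cz", "CP2", "Pz", "O1", "O2")

# Flattened 10-10 grid indices for a label: anterior-posterior row index
# (positive anterior) and lateral index (positive right, odd numbers left).
montage_grid_index <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)(z|[0-9]+)$", label))[[1]]
  if (!length(m)) return(NULL)
  row <- m[2]; num <- m[3]
  ap <- switch(row,
               "Fp" = 4, "AF" = 3, "F" = 2, "FT" = 1, "FC" = 1,
               "T" = 0, "C" = 0, "TP" = -1, "CP" = -1,
               "P" = -2, "PO" = -3, "O" = -4, NULL)
  if (is.null(ap)) return(NULL)
  if (num == "z") {
    lat <- 0
  } else {
    k <- as.integer(num)
    # 1,2 -> +/-1; 3,4 -> +/-2; 5,6 -> +/-3; 7,8 -> +/-4 (T7/T8, FT7/8 at +/-4)
    lat <- ceiling(k / 2) * ifelse(k %% 2 == 1, -1, 1)
    if (row %in% c("T", "FT", "TP")) lat <- sign(lat) * 4
  }
  c(ap = ap, lat = lat)
}

#' Unit-sphere positions for 10-10 channel labels
#'
#' Scalp positions on the unit sphere, derived from the flattened 10-10 grid
#' by azimuthal-equidistant inverse projection from the vertex (Cz): 10% of
#' the nasion-inion arc corresponds to 18 degrees of arc from Cz. Adequate
#' for spherical-spline interpolation, which depends only on inter-electrode
#' angles.
#'
#' @param channels character vector of 10-10 labels.
#' @return tibble with columns `channel`, `x`, `y`, `z` (unit vectors;
#'   +x right, +y anterior, +z vertex).
#' @export
montage_positions <- function(channels = montage_55()) {
  step <- 18 * pi / 180
  rows <- lapply(channels, function(ch) {
    g <- montage_grid_index(ch)
    if (is.null(g)) abort(paste0("no montage position known for channel ", ch))
    d <- step * sqrt(g[["ap"]]^2 + g[["lat"]]^2)
    az <- atan2(g[["ap"]], g[["lat"]])  # direction in the tangent plane
    tibble::tibble(channel = ch,
                   x = sin(d) * cos(az),
                   y = sin(d) * sin(az),
                   z = cos(d))
  })
  dplyr::bind_rows(rows)
}
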