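# PS-OCT relative retardance: per-voxel retardance from the amplitude ratio
# of the two polarization channels, per-A-scan slope by ordinary least
# squares along depth, ROI averaging.

#' Depth-resolved retardance profile at one lateral position
#'
#' The retardance at each depth voxel is the four-quadrant arctangent of
#' `channel1 / channel2` in degrees, which is invariant to a common positive
#' scaling of both channels and lies in \[0, 90\] for noiseless data in the
#' supported (unwrapped) regime. Under noise, values near 0 deg may dip
#' slightly negative; they are retained as-is so that slope fitting stays
#' unbiased (clamping happens only on the fitted slope). Voxels where both
#' channels are zero carry no polarization information and are returned as
#' `NA`, to be excluded from fitting.
#'
#' @param volume a [polarization_volume()].
#' @param y,x lateral pixel indices (1-based).
#' @return numeric vector of retardance angles in degrees, one per depth
#'   voxel; `NA` where undefined.
#' @export
retardance_profile <- function(volume, y, x) {
  stopifnot(inherits(volume, "psoct_volume"))
  d <- dim(volume$channel1)
  if (y < 1 || y > d[1] || x < 1 || x > d[2])
    stop("(y, x) out of bounds", call. = FALSE)
  a1 <- volume$channel1[y, x, ]
  a2 <- volume$channel2[y, x, ]
  phi <- atan2(a1, a2) * 180 / pi
  phi[a1 == 0 & a2 == 0] <- NA_real_
  phi
}

#' Fit the retardance slope of one A-scan
#'
#' Ordinary least-squares line through (depth in um, retardance in degrees)
#' over a fit window, after skipping the topmost voxels (surface specular
#' artifact). A negative fitted slope is clamped to 0: retardance cannot
#' decrease with depth in this model, so negative fits are noise.
#'
#' @param profile retardance angles in degrees (may contain `NA`).
#' @param dz axial voxel size, micrometers.
#' @param skip_top number of surface voxels to exclude from the fit.
#' @param window number of voxels to fit after skipping; `NULL` means the
#'   rest of the A-scan.
#' @return named numeric `c(slope, r_squared)`: slope in deg/um and the R^2
#'   of the (unclamped) fit. Both `NA` if fewer than 3 valid points remain.
#' @examples
#' phi <- 0.5 * (0:19) * 3  # perfectly linear, 0.5 deg/um at dz = 3 um
#' fit_slope(phi, dz = 3, skip_top = 0)
#' @export
fit_slope <- function(profile, dz, skip_top = 3L, window = NULL) {
  stopifnot(dz > 0, skip_top >= 0)
  n <- length(profile)
  lo <- skip_top + 1L
  hi <- if (is.null(window)) n else min(n, skip_top + window)
  if (lo > hi) return(c(slope = NA_real_, r_squared = NA_real_))
  idx <- lo:hi
  phi <- profile[idx]
  depth <- (idx - 1) * dz
  ok <- is.finite(phi)
  if (sum(ok) < 3) return(c(slope = NA_real_, r_squared = NA_real_))
  phi <- phi[ok]; depth <- depth[ok]
  dm <- depth - mean(depth); pm <- phi - mean(phi)
  sxx <- sum(dm^2); sxy <- sum(dm * pm); syy <- sum(pm^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
  c(slope = max(slope, 0), r_squared = r2)
}

#' Per-pixel retardance slope map of a tile
#'
#' Applies the [fit_slope()] contract at every lateral position of the
#' volume, vectorized over the tile.
#'
#' @inheritParams fit_slope
#' @param volume a [polarization_volume()].
#' @param tile_origin `(y, x)` offset of this tile in the stitched mosaic,
#'   pixels.
#' @return an object of class `retardance_map`: list with `slope` and
#'   `r_squared` matrices `(y, x)`, `pixel_pitch` (lateral um/px) and
#'   `tile_origin`.
#' @export
retardance_map <- function(volume, skip_top = 3L, window = NULL,
                           tile_origin = c(0, 0)) {
  stopifnot(inherits(volume, "psoct_volume"))
  d <- dim(volume$channel1)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  dz <- volume$voxel_pitch[["dz"]]
  lo <- skip_top + 1L
  hi <- if (is.null(window)) nz else min(nz, skip_top + window)
  if (hi - lo + 1 < 3)
    stop("fit window has fewer than 3 depth voxels", call. = FALSE)
  idx <- lo:hi
  a1 <- volume$channel1[, , idx, drop = FALSE]
  a2 <- volume$channel2[, , idx, drop = FALSE]
  phi <- atan2(a1, a2) * 180 / pi
  phi[a1 == 0 & a2 == 0] <- NA_real_

  npix <- ny * nx; nk <- length(idx)
  pm <- matrix(phi, nrow = npix, ncol = nk)      # pixels x depths
  depth <- (idx - 1) * dz
  valid <- is.finite(pm)
  nv <- rowSums(valid)
  dmat <- matrix(depth, nrow = npix, ncol = nk, byrow = TRUE)
  dmat[!valid] <- NA
  pv <- pm; pv[!valid] <- NA
  dbar <- rowMeans(dmat, na.rm = TRUE)
  pbar <- rowMeans(pv, na.rm = TRUE)
  dc <- dmat - dbar; pc <- pv - pbar
  sxx <- rowSums(dc^2, na.rm = TRUE)
  sxy <- rowSums(dc * pc, na.rm = TRUE)
  syy <- rowSums(pc^2, na.rm = TRUE)
  slope <- sxy / sxx
  r2 <- ifelse(syy == 0, 1, sxy^2 / (sxx * syy))
  bad <- nv < 3
  slope[bad] <- NA_real_; r2[bad] <- NA_real_
  slope <- pmax(slope, 0)

  structure(
    list(slope = matrix(slope, ny, nx), r_squared = matrix(r2, ny, nx),
         pixel_pitch = unname(volume$voxel_pitch[["dx"]]),
         tile_origin = tile_origin),
    class = "retardance_map")
}

#' @export
print.retardance_map <- function(x, ...) {
  cat(sprintf("<retardance_map> %d x %d px at origin (%g, %g); slope %.3f-%.3f deg/um\n",
              nrow(x$slope), ncol(x$slope), x$tile_origin[1], x$tile_origin[2],
              min(x$slope, na.rm = TRUE), max(x$slope, na.rm = TRUE)))
  invisible(x)
}

#' Mean retardance over an ROI mask
#'
#' @param map a slope matrix or a `retardance_map`.
#' @param mask logical matrix of the same shape; must select at least one
#'   pixel.
#' @param min_r_squared optional fit-quality floor: when `map` is a
#'   `retardance_map`, pixels with R^2 below this are excluded (default
#'   `NULL` keeps all pixels; whether low-quality fits belong in ROI means is
#'   a reporting choice, so both behaviours are exposed).
#' @return mean slope in deg/um over valid masked pixels.
#' @export
roi_mean <- function(map, mask, min_r_squared = NULL) {
  if (inherits(map, "retardance_map")) {
    vals <- map$slope
    if (!is.null(min_r_squared))
      vals[!is.na(map$r_squared) & map$r_squared < min_r_squared] <- NA
  } else vals <- map
  mask <- as.logical(mask)
  if (length(mask) != length(vals))
    stop("mask and map must have the same shape", call. = FALSE)
  if (!any(mask, na.rm = TRUE)) stop("empty ROI mask", call. = FALSE)
  sel <- vals[mask]
  if (all(is.na(sel))) return(NA_real_)
  mean(sel, na.rm = TRUE)
}
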