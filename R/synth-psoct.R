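#' Construct a two-channel polarization volume
#'
#' Container for the raw PS-OCT signal: two co-registered amplitude channels
#' over `(y, x, z)` with voxel pitch metadata. Retardance at a voxel is
#' derived from the amplitude ratio of the two channels, so absolute units
#' are arbitrary.
#'
#' @param channel1,channel2 numeric arrays of identical dimension
#'   `c(ny, nx, nz)`.
#' @param voxel_pitch named numeric `c(dz, dy, dx)` in micrometers; `dz` is
#'   the axial (depth) step and must be > 0.
#' @return an object of class `psoct_volume`.
#' @export
polarization_volume <- function(channel1, channel2,
                                voxel_pitch = c(dz = 3, dy = 10, dx = 10)) {
  channel1 <- as.array(channel1); channel2 <- as.array(channel2)
  if (!identical(dim(channel1), dim(channel2)))
    stop("channels must have identical dimensions", call. = FALSE)
  if (length(dim(channel1)) != 3)
    stop("channels must be (y, x, z) arrays", call. = FALSE)
  if (!all(is.finite(channel1)) || !all(is.finite(channel2)))
    stop("channel amplitudes must be finite", call. = FALSE)
  if (length(voxel_pitch) != 3 || voxel_pitch[1] <= 0)
    stop("`voxel_pitch` must be c(dz, dy, dx) with dz > 0", call. = FALSE)
  names(voxel_pitch) <- c("dz", "dy", "dx")
  structure(list(channel1 = channel1, channel2 = channel2,
                 voxel_pitch = voxel_pitch),
            class = "psoct_volume")
}

#' @export
print.psoct_volume <- function(x, ...) {
  d <- dim(x$channel1)
  cat(sprintf("<psoct_volume> %d x %d px, %d depth voxels (dz = %g um)\n",
              d[1], d[2], d[3], x$voxel_pitch["dz"]))
  invisible(x)
}

#' Simulate a PS-OCT volume from a known retardance-slope map
#'
#' Forward model for the two polarization channels: at lateral position
#' `(y, x)` the cumulative retardance grows linearly with depth,
#' `phi(z) = slope * z * dz` degrees (plane `i` is at depth `(i - 1) * dz`),
#' and the channels measure `amplitude * sin(phi)` and `amplitude * cos(phi)`
#' plus independent Gaussian noise. [retardance_map()] applied to the result
#' recovers `slope_map` exactly when `noise_sd = 0`.
#'
#' @param slope_map matrix `(y, x)` of retardance slopes, deg/um; finite and
#'   >= 0.
#' @param depth_px number of depth voxels per A-scan.
#' @param voxel_depth axial voxel size `dz`, micrometers.
#' @param amplitude signal amplitude, arbitrary units.
#' @param noise_sd SD of additive Gaussian noise on each channel.
#' @param seed integer seed.
#' @param voxel_xy lateral voxel size, micrometers.
#' @return a [polarization_volume()].
#' @examples
#' vol <- simulate_psoct_volume(matrix(0.5, 4, 4), depth_px = 20, voxel_depth = 3)
#' retardance_profile(vol, 1, 1)[11]  # 0.5 deg/um * 10 planes * 3 um = 15 deg
#' @export
simulate_psoct_volume <- function(slope_map, depth_px, voxel_depth = 3,
                                  amplitude = 1, noise_sd = 0, seed = NULL,
                                  voxel_xy = 10) {
  slope_map <- as.matrix(slope_map)
  if (!all(is.finite(slope_map)) || any(slope_map < 0))
    stop("`slope_map` must be finite and >= 0", call. = FALSE)
  stopifnot(depth_px >= 1, voxel_depth > 0)
  ny <- nrow(slope_map); nx <- ncol(slope_map)
  depth_um <- (seq_len(depth_px) - 1) * voxel_depth
  # phi[y, x, z] in radians
  phi <- outer(slope_map, depth_um) * pi / 180
  with_seed(seed, {
    ch1 <- amplitude * sin(phi)
    ch2 <- amplitude * cos(phi)
    if (noise_sd > 0) {
      ch1 <- ch1 + array(rnorm(length(ch1), sd = noise_sd), dim = dim(ch1))
      ch2 <- ch2 + array(rnorm(length(ch2), sd = noise_sd), dim = dim(ch2))
    }
    polarization_volume(ch1, ch2,
                        c(dz = voxel_depth, dy = voxel_xy, dx = voxel_xy))
  })
}
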