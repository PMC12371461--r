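#' Stitch retardance tiles into one mosaic with feathered overlaps
#'
#' Tiles are placed at their grid origins; where tiles overlap, values are
#' blended with linear feather ramps (each tile's weight falls off linearly
#' across its margin, and contributions are renormalized). Pixels covered by
#' a single tile pass through unchanged, and blending conserves constants:
#' stitching tiles of one common value yields that value everywhere.
#'
#' @param tiles list of `retardance_map` objects (or plain matrices) of
#'   identical shape.
#' @param origins optional integer matrix with columns `(y, x)`: top-left
#'   pixel offsets of each tile in the mosaic (0-based offsets). Defaults to
#'   each tile's `tile_origin`. Origins must be consistent with a grid at the
#'   given overlap.
#' @param overlap_fraction nominal fractional overlap between adjacent tiles
#'   (the acquisition protocol uses 15%); sets the feather-ramp width.
#' @return list with `slope` (the stitched matrix) and `weight` (the summed
#'   blend weight, > 0 wherever any tile contributed).
#' @examples
#' t1 <- matrix(0.4, 20, 20); t2 <- matrix(0.4, 20, 20)
#' s <- stitch_tiles(list(t1, t2), origins = rbind(c(0, 0), c(0, 17)))
#' unique(as.vector(s$slope))
#' @export
stitch_tiles <- function(tiles, origins = NULL, overlap_fraction = 0.15) {
  stopifnot(length(tiles) >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  mats <- lapply(tiles, function(t)
    if (inherits(t, "retardance_map")) t$slope else as.matrix(t))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all tiles must have the same shape", call. = FALSE)
  ty <- dims[1, 1]; tx <- dims[2, 1]
  if (is.null(origins))
    origins <- t(vapply(tiles, function(t) {
      if (!inherits(t, "retardance_map"))
        stop("`origins` required for plain-matrix tiles", call. = FALSE)
      as.numeric(t$tile_origin)
    }, numeric(2)))
  origins <- matrix(as.numeric(origins), ncol = 2)
  if (nrow(origins) != length(tiles))
    stop("one origin per tile required", call. = FALSE)
  step_y <- round(ty * (1 - overlap_fraction))
  step_x <- round(tx * (1 - overlap_fraction))
  off_grid <- (origins[, 1] %% step_y != 0) | (origins[, 2] %% step_x != 0)
  if (length(tiles) > 1 && any(off_grid))
    stop("tile ", which(off_grid)[1],
         " origin is inconsistent with the stitching grid", call. = FALSE)

  margin_y <- ty - step_y; margin_x <- tx - step_x
  out_ny <- max(origins[, 1]) + ty
  out_nx <- max(origins[, 2]) + tx
  acc <- matrix(0, out_ny, out_nx)
  wsum <- matrix(0, out_ny, out_nx)
  w_tile <- outer(feather_ramp(ty, margin_y), feather_ramp(tx, margin_x))
  for (i in seq_along(mats)) {
    ys <- origins[i, 1] + seq_len(ty)
    xs <- origins[i, 2] + seq_len(tx)
    m <- mats[[i]]
    w <- w_tile
    w[is.na(m)] <- 0
    m[is.na(m)] <- 0
    acc[ys, xs] <- acc[ys, xs] + w * m
    wsum[ys, xs] <- wsum[ys, xs] + w
  }
  slope <- acc / wsum
  slope[wsum == 0] <- NA_real_
  list(slope = slope, weight = wsum)
}

# linear feather: weight rises from 1/(margin + 1) at the tile edge to 1 in
# the interior over `margin` pixels; strictly positive so lone tiles pass
# through unchanged after normalization
feather_ramp <- function(n, margin) {
  if (margin <= 0) return(rep(1, n))
  r <- pmin(seq_len(n), rev(seq_len(n)), margin + 1) / (margin + 1)
  r
}
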