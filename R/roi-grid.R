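# Blinded randomized grid sampling of annotation ROIs: polygon -> mask ->
# grid crops -> ~1/3 random selection with opaque sub-image names.

#' Rasterize an ROI polygon to a binary mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Coordinates are in pixel units with the pixel at row
#' `r`, column `c` (1-based) centered at `(x, y) = (c - 0.5, r - 0.5)`, so an
#' axis-aligned square from (0, 0) to (10, 10) covers exactly 100 pixels.
#'
#' @param vertices numeric matrix with columns `x`, `y` (pixels), at least 3
#'   vertices of a simple polygon. Vertices may extend past the image; the
#'   mask is clipped to `shape`.
#' @param shape integer `c(ny, nx)` of the target mask.
#' @return logical matrix `(ny, nx)`.
#' @examples
#' m <- polygon_to_mask(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), c(20, 20))
#' sum(m)  # 100
#' @export
polygon_to_mask <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("polygon needs >= 3 (x, y) vertices", call. = FALSE)
  if (abs(polygon_area(vertices)) < .Machine$double.eps)
    stop("degenerate polygon (zero area)", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]
  # restrict the point-in-polygon test to the polygon's bounding box
  cmin <- pmax(floor(min(vertices[, 1])), 0); cmax <- pmin(ceiling(max(vertices[, 1])), nx)
  rmin <- pmax(floor(min(vertices[, 2])), 0); rmax <- pmin(ceiling(max(vertices[, 2])), ny)
  mask <- matrix(FALSE, ny, nx)
  if (cmin >= cmax || rmin >= rmax) return(mask)
  cols <- (cmin + 1):cmax; rows <- (rmin + 1):rmax
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  bnd <- rbind(vertices, vertices[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
  mask
}

#' Shoelace area of a polygon
#'
#' @param vertices numeric matrix with columns `x`, `y`.
#' @return signed area in squared input units (positive for counter-clockwise
#'   vertex order).
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  x <- v[, 1]; y <- v[, 2]
  i <- seq_len(nrow(v)); j <- c(2:nrow(v), 1)
  sum(x[i] * y[j] - x[j] * y[i]) / 2
}

#' Candidate fixed-size crops of a mask on a randomized grid
#'
#' Lays a square grid of `tile_px` cells over the mask's bounding box with a
#' seed-randomized global offset, and retains every in-bounds cell in which
#' at least `min_inside_fraction` of the pixels belong to the mask.
#'
#' @param mask logical matrix (from [polygon_to_mask()]); must be nonempty.
#' @param tile_px crop side length in pixels (annotation sub-images are
#'   600 px, about 195 um at the default BRM pitch).
#' @param min_inside_fraction minimum fraction of a crop that must lie inside
#'   the mask for it to be retained. Border crops are mostly background;
#'   0.5 keeps crops that are at least half tissue ROI.
#' @param seed integer seed for the grid offset.
#' @param offset optional explicit `(y, x)` grid offset in `[0, tile_px)`,
#'   overriding the randomized one.
#' @return data.frame of retained crops: `y`, `x` (0-based top-left corner),
#'   `tile_px`, `inside_fraction`, ordered row-major.
#' @export
grid_crops <- function(mask, tile_px = 600L, min_inside_fraction = 0.5,
                       seed = NULL, offset = NULL) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  stop_if_not_scalar_prob(min_inside_fraction, "min_inside_fraction")
  tile_px <- as.integer(tile_px)
  ny <- nrow(mask); nx <- ncol(mask)
  if (is.null(offset))
    offset <- with_seed(seed, sample.int(tile_px, 2) - 1L)
  stopifnot(length(offset) == 2, all(offset >= 0), all(offset < tile_px))

  rs <- range(which(rowSums(mask) > 0)); cs <- range(which(colSums(mask) > 0))
  bb_y <- rs[1] - 1; bb_x <- cs[1] - 1              # 0-based bbox corner
  start_y <- bb_y - ((bb_y - offset[1]) %% tile_px)
  start_x <- bb_x - ((bb_x - offset[2]) %% tile_px)
  ys <- seq(start_y, rs[2] - 1, by = tile_px)
  xs <- seq(start_x, cs[2] - 1, by = tile_px)
  out <- list()
  for (y0 in ys) for (x0 in xs) {
    if (y0 < 0 || x0 < 0 || y0 + tile_px > ny || x0 + tile_px > nx) next
    frac <- mean(mask[(y0 + 1):(y0 + tile_px), (x0 + 1):(x0 + tile_px)])
    if (frac >= min_inside_fraction)
      out[[length(out) + 1]] <- data.frame(y = y0, x = x0, tile_px = tile_px,
                                           inside_fraction = frac)
  }
  if (!length(out))
    return(data.frame(y = integer(), x = integer(), tile_px = integer(),
                      inside_fraction = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select a blinded subset of candidate crops
#'
#' Selects `round(fraction * N)` crops uniformly without replacement
#' (rounding half-up, so "approximately one third" is exact and
#' reproducible), assigns each an opaque pseudorandom hexadecimal token as
#' its blinded id, and shuffles the output order. The mapping from blinded id
#' back to source crop (and any subject metadata in `source_info`) is
#' returned only in the sealed `key` table, which callers should write to a
#' restricted location; the `subimages` table itself carries nothing that
#' identifies subject, group or slice.
#'
#' @param crops data.frame from [grid_crops()].
#' @param fraction fraction of crops to select, in (0, 1\]; default 1/3.
#' @param seed integer seed: same seed, same selection and same blinded ids.
#' @param pixel_pitch um/px used to derive each sub-image's area in mm^2.
#' @param source_info optional one-row data.frame (e.g. `subject_id`,
#'   `slice_index`) replicated into the key table only.
#' @param key_file optional path; when given, the key table is written there
#'   as JSON with a warning banner field.
#' @return list with `subimages` (blinded_id, tile_px, area_mm2) and `key`
#'   (blinded_id, crop origin, source_info columns).
#' @examples
#' crops <- data.frame(y = rep(0:2, 3) * 600, x = rep(0:2, each = 3) * 600,
#'                     tile_px = 600, inside_fraction = 1)
#' sel <- select_blinded(crops, fraction = 1/3, seed = 7)
#' nrow(sel$subimages)  # 3
#' @export
select_blinded <- function(crops, fraction = 1/3, seed = NULL,
                           pixel_pitch = 0.325, source_info = NULL,
                           key_file = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  n <- nrow(crops)
  if (n == 0) stop("no candidate crops", call. = FALSE)
  n_sel <- max(1L, as.integer(floor(fraction * n + 0.5)))
  with_seed(seed, {
    pick <- sample.int(n, n_sel)
    ids <- random_tokens(n_sel)
    ord <- sample.int(n_sel)        # shuffle presentation order
    sel <- crops[pick[ord], , drop = FALSE]
    ids <- ids[ord]
    area_mm2 <- (sel$tile_px * pixel_pitch / 1000)^2
    subimages <- data.frame(blinded_id = ids, tile_px = sel$tile_px,
                            area_mm2 = area_mm2)
    key <- data.frame(blinded_id = ids, y = sel$y, x = sel$x,
                      tile_px = sel$tile_px)
    if (!is.null(source_info))
      key <- cbind(key, source_info[rep(1, nrow(key)), , drop = FALSE])
    rownames(subimages) <- rownames(key) <- NULL
    if (!is.null(key_file))
      jsonlite::write_json(
        list(warning = "UNBLINDING KEY - do not open before annotation is complete",
             key = key),
        key_file, auto_unbox = TRUE, digits = NA)
    list(subimages = subimages, key = key)
  })
}

# opaque 12-hex-digit tokens from the current RNG stream
random_tokens <- function(n) {
  repeat {
    toks <- vapply(seq_len(n), function(i)
      paste(sample(c(0:9, letters[1:6]), 12, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(toks)) return(toks)
  }
}
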