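# Synthetic birefringence-microscopy (BRM) z-stacks.
#
# Fibers are stylized: two parallel bright curves at the sheath spacing,
# rendered with bilinear splatting so sub-pixel geometry is smooth. Defects
# perturb the local rendering with geometric primitives; the goal is that the
# downstream annotation/consensus statistics are realistic, not the optics.

#' Render a synthetic BRM z-stack with known defect ground truth
#'
#' Draws each fiber as two parallel bright curves on every z-plane and
#' superimposes its defects: a `swelling` adds a bright filled ellipse between
#' the intact lines; `delamination_blebbing` locally erases the sheath and
#' scatters bright fragments; a `vesicle` draws a small bright ring present in
#' exactly `z_span` planes. Gaussian pixel noise is added last.
#'
#' @param fibers list of [fiber_spec()] objects.
#' @param shape integer `c(ny, nx, nz)`: stack dimensions in pixels / planes.
#' @param pixel_pitch lateral pixel size, micrometers per pixel. The default
#'   0.325 um/px makes a 600-px crop span about 195 um.
#' @param noise_sd SD of additive Gaussian pixel noise (arbitrary units).
#' @param seed integer seed; identical inputs and seed give a bit-identical
#'   stack.
#' @return a list with `stack` (numeric array `(y, x, z)`), `truth` (a
#'   data.frame of drawn defects: `class`, `x`, `y`, `w`, `h` as a pixel
#'   bounding box, `z` focal plane, `z_span`, plus the generating `x_um`,
#'   `y_um` center), and `pixel_pitch`.
#' @examples
#' f <- fiber_spec(rbind(c(5, 30), c(180, 30)), sheath_spacing = 2,
#'                 defects = list(defect_spec("vesicle", c(90, 45, 5), c(3, 3))))
#' out <- render_brm_stack(list(f), shape = c(192, 192, 10), pixel_pitch = 1,
#'                         seed = 1)
#' nrow(out$truth)
#' @export
render_brm_stack <- function(fibers, shape, pixel_pitch = 0.325,
                             noise_sd = 0, seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1), pixel_pitch > 0)
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  stopifnot(all(vapply(fibers, inherits, logical(1), "fiber_spec")))

  defects <- unlist(lapply(fibers, `[[`, "defects"), recursive = FALSE)
  for (d in defects) {
    px <- d$center[1] / pixel_pitch; py <- d$center[2] / pixel_pitch
    if (px < 0 || px > nx || py < 0 || py > ny ||
        d$center[3] < 1 || d$center[3] + d$z_span - 1 > nz)
      stop(sprintf("defect center (%.1f um, %.1f um, z %d) outside stack bounds",
                   d$center[1], d$center[2], as.integer(d$center[3])),
           call. = FALSE)
  }

  with_seed(seed, {
    stack <- array(0, dim = c(ny, nx, nz))
    plane <- matrix(0, ny, nx)
    for (f in fibers)
      plane <- plane + draw_fiber(f, ny, nx, pixel_pitch)
    for (k in seq_len(nz)) stack[, , k] <- plane

    for (d in defects)
      stack <- draw_defect(stack, d, pixel_pitch)
    truth <- do.call(rbind, lapply(defects, defect_truth_row, pixel_pitch))
    if (is.null(truth))
      truth <- data.frame(class = character(), x = numeric(), y = numeric(),
                          w = numeric(), h = numeric(), z = integer(),
                          z_span = integer(), x_um = numeric(), y_um = numeric())

    if (noise_sd > 0)
      stack <- stack + array(rnorm(length(stack), sd = noise_sd), dim = dim(stack))
    list(stack = stack, truth = truth, pixel_pitch = pixel_pitch)
  })
}

# one truth record per drawn defect; bounding box in pixel coordinates
defect_truth_row <- function(d, pitch) {
  w <- d$extent[1] / pitch; h <- d$extent[2] / pitch
  data.frame(class = d$kind,
             x = d$center[1] / pitch - w / 2, y = d$center[2] / pitch - h / 2,
             w = w, h = h, z = as.integer(d$center[3]), z_span = d$z_span,
             x_um = d$center[1], y_um = d$center[2])
}

# rasterize the two sheath lines of one fiber into a (ny, nx) plane
draw_fiber <- function(f, ny, nx, pitch) {
  plane <- matrix(0, ny, nx)
  cl <- f$centerline / pitch            # now in px
  half <- f$sheath_spacing / (2 * pitch)
  for (i in seq_len(nrow(cl) - 1)) {
    p0 <- cl[i, ]; p1 <- cl[i + 1, ]
    seg <- p1 - p0
    len <- sqrt(sum(seg^2))
    if (len == 0) next
    u <- seg / len
    nrm <- c(-u[2], u[1])               # unit normal
    ts <- seq(0, len, by = 0.4)
    for (side in c(-1, 1)) {
      pts_x <- p0[1] + ts * u[1] + side * half * nrm[1]
      pts_y <- p0[2] + ts * u[2] + side * half * nrm[2]
      plane <- splat(plane, pts_x, pts_y, f$intensity * 0.4)
    }
  }
  pmin(plane, f$intensity)              # saturate overlapping stamps
}

# bilinear splatting of point samples (px coordinates, pixel centers at i-0.5)
splat <- function(plane, xs, ys, value) {
  ny <- nrow(plane); nx <- ncol(plane)
  cx <- xs + 0.5; cy <- ys + 0.5       # continuous 1-based index space
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  for (dy in 0:1) for (dx in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & wgt > 0
    if (any(ok)) {
      idx <- cbind(iy[ok], ix[ok])
      plane[idx] <- plane[idx] + value * wgt[ok]
    }
  }
  plane
}

# pixel-center coordinate grids (px units, 0-based physical convention)
pixel_centers <- function(ny, nx) {
  list(x = matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx),
       y = matrix(rep(seq_len(ny) - 0.5, nx), ny, nx))
}

draw_defect <- function(stack, d, pitch) {
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  ctr <- pixel_centers(ny, nx)
  cx <- d$center[1] / pitch; cy <- d$center[2] / pitch
  a <- d$extent[1] / (2 * pitch); b <- d$extent[2] / (2 * pitch)
  planes <- seq(d$center[3], length.out = d$z_span)
  r2 <- ((ctr$x - cx) / a)^2 + ((ctr$y - cy) / b)^2
  if (d$kind == "swelling") {
    bump <- 0.9 * exp(-r2 * 2)
    bump[r2 > 1] <- 0
    for (k in planes) stack[, , k] <- stack[, , k] + bump
  } else if (d$kind == "vesicle") {
    # thin bright ring at the ellipse boundary, only in these planes
    ring <- exp(-((sqrt(r2) - 1) / (0.6 / max(a, b)))^2)
    ring[abs(sqrt(r2) - 1) > 1.5 / max(a, b)] <- 0
    for (k in planes) stack[, , k] <- stack[, , k] + 0.9 * ring
  } else { # delamination_blebbing: erase the sheath locally, add fragments
    inside <- r2 <= 1
    nfrag <- 3 + rpois(1, 2)
    fx <- cx + runif(nfrag, -a, a) * 0.7
    fy <- cy + runif(nfrag, -b, b) * 0.7
    fr <- runif(nfrag, 0.8, 1.8)
    for (k in planes) {
      pl <- stack[, , k]
      pl[inside] <- 0
      for (j in seq_len(nfrag)) {
        d2 <- (ctr$x - fx[j])^2 + (ctr$y - fy[j])^2
        pl <- pl + 0.8 * exp(-d2 / (2 * fr[j]^2)) * (d2 < (3 * fr[j])^2)
      }
      stack[, , k] <- pl
    }
  }
  stack
}
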