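# DAB chromogen percent-area quantification: Beer-Lambert optical density,
# H-DAB stain unmixing, threshold on the DAB concentration channel.

#' H-DAB stain configuration
#'
#' Reference optical-density vectors for hematoxylin and DAB (the standard
#' H-DAB color-deconvolution pair, unit-normalized) and the DAB concentration
#' threshold above which a pixel counts as positive.
#'
#' @param dab_od,hema_od length-3 non-negative RGB optical-density vectors;
#'   normalized to unit length internally.
#' @param dab_threshold DAB concentration cutoff (OD units along `dab_od`),
#'   > 0. The default 0.3 sits well above the hematoxylin-only background
#'   and well below typical chromogen densities.
#' @return an object of class `stain_config`.
#' @export
stain_config <- function(dab_od = c(0.268, 0.570, 0.776),
                         hema_od = c(0.650, 0.704, 0.286),
                         dab_threshold = 0.3) {
  stopifnot(length(dab_od) == 3, length(hema_od) == 3,
            all(dab_od >= 0), all(hema_od >= 0), dab_threshold > 0)
  structure(list(dab_od = dab_od / sqrt(sum(dab_od^2)),
                 hema_od = hema_od / sqrt(sum(hema_od^2)),
                 dab_threshold = dab_threshold),
            class = "stain_config")
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert: `OD = -log10((I + eps) / white_point)` per channel, with
#' `eps = 1/255` guarding zero intensities. `white_point = "auto"` estimates
#' the white point as the per-channel 99th percentile, which makes the OD
#' (and everything downstream) invariant to uniform illumination scaling.
#'
#' @param rgb array `(y, x, 3)` of intensities; 8-bit input is rescaled to
#'   \[0, 1\].
#' @param white_point per-channel white intensity: a scalar, a length-3
#'   vector, or `"auto"`.
#' @return array `(y, x, 3)` of optical densities (>= 0, clamped).
#' @export
optical_density <- function(rgb, white_point = 1) {
  rgb <- as.array(rgb)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("`rgb` must be a (y, x, 3) array", call. = FALSE)
  if (max(rgb) > 1) rgb <- rgb / 255
  eps <- 1 / 255
  if (identical(white_point, "auto"))
    white_point <- apply(rgb, 3, quantile, probs = 0.99, names = FALSE)
  white_point <- rep_len(white_point, 3)
  od <- rgb
  for (ch in 1:3)
    od[, , ch] <- pmax(-log10((rgb[, , ch] + eps) / (white_point[ch] + eps)), 0)
  od
}

#' DAB-positive percent area of an ROI
#'
#' Unmixes each pixel's optical density into DAB and hematoxylin
#' concentrations by least squares against the two reference vectors, then
#' reports the percentage of ROI pixels whose DAB concentration reaches the
#' threshold.
#'
#' @param od array `(y, x, 3)` from [optical_density()].
#' @param mask logical ROI matrix `(y, x)`; must select at least one pixel.
#' @param config a [stain_config()].
#' @param mode `"unmix"` (default, device-independent color deconvolution) or
#'   `"rgb_threshold"` (simple brown-dominance rule on raw OD, closer to an
#'   interactive color-threshold workflow).
#' @return percent of ROI pixels positive for DAB, in \[0, 100\].
#' @examples
#' img <- render_stain_image(c(60, 60), 0.3, seed = 2)
#' od <- optical_density(img$rgb)
#' dab_fraction(od, matrix(TRUE, 60, 60))
#' @export
dab_fraction <- function(od, mask, config = stain_config(),
                         mode = c("unmix", "rgb_threshold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "stain_config"))
  mask <- as.logical(mask)
  d <- dim(od)
  if (length(d) != 3 || d[3] != 3)
    stop("`od` must be a (y, x, 3) array", call. = FALSE)
  if (length(mask) != d[1] * d[2])
    stop("mask shape must match the image", call. = FALSE)
  n_roi <- sum(mask, na.rm = TRUE)
  if (n_roi == 0) stop("empty ROI mask", call. = FALSE)

  odm <- matrix(od, ncol = 3)[which(mask), , drop = FALSE]
  if (mode == "unmix") {
    M <- cbind(dab = config$dab_od, hema = config$hema_od)
    if (abs(sum(config$dab_od * config$hema_od)) > 0.995)
      stop("stain vectors are nearly collinear; unmixing is ill-conditioned",
           call. = FALSE)
    conc <- odm %*% M %*% solve(crossprod(M))   # least-squares concentrations
    positive <- conc[, 1] >= config$dab_threshold
  } else {
    # brown dominance: strong absorbance weighted toward the DAB hue
    proj_dab <- odm %*% config$dab_od
    proj_hema <- odm %*% config$hema_od
    positive <- proj_dab >= config$dab_threshold & proj_dab > proj_hema
  }
  100 * sum(positive) / n_roi
}
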