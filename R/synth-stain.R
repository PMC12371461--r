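#' Render a synthetic H-DAB stained image with known positive mask
#'
#' Generates a smooth random blob field, thresholds it so that exactly
#' `round(positive_fraction * n_pixels)` pixels are positive, and renders the
#' image through Beer-Lambert absorbance: positive pixels carry DAB (brown
#' chromogen) on top of a light hematoxylin counterstain, background carries
#' hematoxylin only. The returned truth mask makes the image a round-trip
#' oracle for [dab_fraction()].
#'
#' @param shape integer `c(ny, nx)` in pixels.
#' @param positive_fraction target DAB-positive area fraction in \[0, 1\];
#'   the rendered mask matches it to well within 0.5% of pixels.
#' @param dab_od,hema_od unit-norm optical-density vectors per RGB channel;
#'   defaults are the standard H-DAB reference vectors (see [stain_config()]).
#' @param seed integer seed.
#' @param dab_conc mean DAB concentration of positive pixels (OD units along
#'   `dab_od`).
#' @param hema_conc hematoxylin concentration applied everywhere.
#' @param conc_noise SD of per-pixel concentration variation.
#' @return list with `rgb` (array `(y, x, 3)` of transmittances in \[0, 1\]),
#'   `mask` (logical matrix, the ground-truth positive region) and
#'   `positive_fraction` (the exact rendered fraction).
#' @examples
#' img <- render_stain_image(c(80, 80), 0.3, seed = 1)
#' mean(img$mask)
#' @export
render_stain_image <- function(shape, positive_fraction,
                               dab_od = stain_config()$dab_od,
                               hema_od = stain_config()$hema_od,
                               seed = NULL, dab_conc = 0.9, hema_conc = 0.25,
                               conc_noise = 0.05) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  stop_if_not_scalar_prob(positive_fraction, "positive_fraction")
  ny <- shape[1]; nx <- shape[2]
  n <- ny * nx
  n_pos <- round(positive_fraction * n)

  with_seed(seed, {
    mask <- matrix(FALSE, ny, nx)
    if (n_pos > 0) {
      # smooth blob field: mixture of random Gaussian bumps
      ctr <- pixel_centers(ny, nx)
      k <- 12L
      bx <- runif(k, 0, nx); by <- runif(k, 0, ny)
      amp <- runif(k, 0.5, 1)
      sig <- runif(k, 0.1, 0.3) * max(ny, nx)
      field <- matrix(0, ny, nx)
      for (j in seq_len(k))
        field <- field + amp[j] *
          exp(-((ctr$x - bx[j])^2 + (ctr$y - by[j])^2) / (2 * sig[j]^2))
      field <- field + matrix(rnorm(n, sd = 1e-9), ny, nx)  # break exact ties
      mask[order(field, decreasing = TRUE)[seq_len(n_pos)]] <- TRUE
    }
    c_dab <- matrix(0, ny, nx)
    c_dab[mask] <- pmax(dab_conc + rnorm(n_pos, sd = conc_noise), 0.1)
    c_hema <- pmax(hema_conc + matrix(rnorm(n, sd = conc_noise), ny, nx), 0)
    rgb <- array(0, dim = c(ny, nx, 3))
    for (ch in 1:3) {
      od <- c_dab * dab_od[ch] + c_hema * hema_od[ch]
      rgb[, , ch] <- 10^(-od)
    }
    list(rgb = rgb, mask = mask, positive_fraction = n_pos / n)
  })
}
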