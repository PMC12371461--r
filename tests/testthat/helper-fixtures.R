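# shared fixture builders for the test suite

# a straight horizontal fiber with optional defects (coordinates in um)
straight_fiber <- function(y_um, x0 = 5, x1 = 180, spacing = 2,
                           defects = list()) {
  fiber_spec(rbind(c(x0, y_um), c(x1, y_um)), sheath_spacing = spacing,
             defects = defects)
}

# non-overlapping truth boxes laid out on a grid (pixel units), for
# annotator simulations where clusters must not merge across defects
grid_truth <- function(n, box_px = 20, gap_px = 60, classes = NULL,
                       z = NULL, ncol_grid = 10) {
  i <- seq_len(n) - 1
  data.frame(
    x = (i %% ncol_grid) * gap_px + 5,
    y = (i %/% ncol_grid) * gap_px + 5,
    w = box_px, h = box_px,
    z = if (is.null(z)) rep(5L, n) else z,
    class = if (is.null(classes))
      rep_len(c("swelling", "delamination_blebbing", "vesicle"), n)
    else classes)
}

# random annotation set for one sub-image: a few latent structures, each
# annotated by a random subset of 3 annotators with jittered boxes, plus
# occasional stray boxes -- sized so the exhaustive oracle stays tractable
random_annotation_instance <- function(max_structures = 4) {
  n_struct <- sample.int(max_structures, 1)
  rows <- list()
  for (s in seq_len(n_struct)) {
    cx <- runif(1, 30, 500); cy <- runif(1, 30, 500)
    sz <- runif(1, 15, 35); z0 <- sample.int(8, 1)
    for (a in c("A1", "A2", "A3")) {
      if (runif(1) < 0.7) {
        rows[[length(rows) + 1]] <- data.frame(
          annotator_id = a, subimage_id = "s1",
          x = cx + rnorm(1, sd = 4), y = cy + rnorm(1, sd = 4),
          w = sz * runif(1, 0.8, 1.2), h = sz * runif(1, 0.8, 1.2),
          z = z0 + sample(-1:1, 1),
          class = sample(c("swelling", "delamination_blebbing", "vesicle"), 1))
      }
    }
  }
  if (!length(rows)) return(random_annotation_instance(max_structures))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
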