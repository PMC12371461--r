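#' Simulate imperfect annotators over a set of true defects
#'
#' Each annotator independently detects every true defect with probability
#' `model$sensitivity`; detected boxes are jittered laterally by Gaussian
#' noise, the reported class is drawn from the confusion-matrix row of the
#' true class, and spurious annotations are added at a Poisson rate per
#' sub-image.
#'
#' @param truth data.frame of true defects with columns `x`, `y`, `w`, `h`
#'   (pixel bounding boxes), `z` (focal plane) and `class`, as returned in
#'   `render_brm_stack()$truth`.
#' @param model an [annotator_model()].
#' @param n_annotators number of independent annotators (the study design
#'   uses 3).
#' @param seed integer seed for reproducibility.
#' @param subimage_id id attached to every emitted annotation.
#' @param image_px sub-image side length in pixels (placement range for false
#'   positives).
#' @param n_planes number of z-planes (placement range for false positives).
#' @return a data.frame of annotations with columns `annotator_id`,
#'   `subimage_id`, `x`, `y`, `w`, `h`, `z`, `class`, ready for
#'   [cluster_annotations()]. With perfect sensitivity, zero jitter, identity
#'   confusion and no false positives, every annotator's rows equal `truth`.
#' @examples
#' truth <- data.frame(x = c(10, 100), y = c(10, 100), w = 20, h = 20,
#'                     z = c(3L, 7L), class = c("swelling", "vesicle"))
#' ann <- simulate_annotations(truth, annotator_model(sensitivity = 1), seed = 1)
#' table(ann$annotator_id)
#' @export
simulate_annotations <- function(truth, model, n_annotators = 3L, seed = NULL,
                                 subimage_id = "sub1", image_px = 600L,
                                 n_planes = 23L) {
  stopifnot(inherits(model, "annotator_model"), n_annotators >= 1)
  req <- c("x", "y", "w", "h", "z", "class")
  if (!all(req %in% names(truth)))
    stop("`truth` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  assert_defect_class(truth$class)

  with_seed(seed, {
    out <- vector("list", n_annotators)
    for (a in seq_len(n_annotators)) {
      rows <- list()
      n_true <- nrow(truth)
      if (n_true > 0) {
        hit <- runif(n_true) < model$sensitivity
        if (any(hit)) {
          det <- truth[hit, req, drop = FALSE]
          if (model$jitter_sd > 0) {
            det$x <- det$x + rnorm(nrow(det), sd = model$jitter_sd)
            det$y <- det$y + rnorm(nrow(det), sd = model$jitter_sd)
          }
          det$class <- vapply(det$class, function(cl) {
            sample(DEFECT_CLASSES, 1, prob = model$class_confusion[cl, ])
          }, character(1), USE.NAMES = FALSE)
          rows <- c(rows, list(det))
        }
      }
      n_fp <- if (model$false_positive_rate > 0)
        rpois(1, model$false_positive_rate) else 0L
      if (n_fp > 0) {
        sz <- runif(n_fp, 8, 40)
        fp <- data.frame(
          x = runif(n_fp, 0, image_px - sz), y = runif(n_fp, 0, image_px - sz),
          w = sz, h = sz,
          z = sample.int(n_planes, n_fp, replace = TRUE),
          class = sample(DEFECT_CLASSES, n_fp, replace = TRUE))
        rows <- c(rows, list(fp))
      }
      ann <- if (length(rows)) do.call(rbind, rows) else
        data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                   z = integer(), class = character())
      ann <- data.frame(annotator_id = rep(sprintf("A%d", a), nrow(ann)),
                        subimage_id = rep(subimage_id, nrow(ann)), ann)
      out[[a]] <- ann
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
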