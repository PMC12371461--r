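# File interfaces: multi-page TIFF stacks with JSON pitch sidecars,
# JSON-lines annotation files, consensus summary CSV.

#' Write a z-stack as a multi-page TIFF with a metadata sidecar
#'
#' @param stack numeric array `(y, x, z)`; values are written as 32-bit float
#'   after rescaling to \[0, 1\] (the scale factor is recorded in the
#'   sidecar).
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param pixel_pitch lateral um/px.
#' @param z_step axial step between planes, micrometers.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, pixel_pitch = 0.325, z_step = 1.3) {
  stopifnot(length(dim(stack)) == 3)
  mx <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_pitch_um = pixel_pitch, z_step_um = z_step,
         scale = mx, n_planes = dim(stack)[3]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF z-stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return list with `stack` (array `(y, x, z)`, original scale restored),
#'   `pixel_pitch` and `z_step`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]] * meta$scale
  list(stack = stack, pixel_pitch = meta$pixel_pitch_um,
       z_step = meta$z_step_um)
}

#' Write annotations as JSON lines (one annotation per line)
#'
#' @param annotations data.frame with columns `annotator_id`, `subimage_id`,
#'   `x`, `y`, `w`, `h`, `z`, `class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  req <- c("annotator_id", "subimage_id", "x", "y", "w", "h", "z", "class")
  if (!all(req %in% names(annotations)))
    stop("annotations must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  lines <- vapply(seq_len(nrow(annotations)), function(i)
    jsonlite::toJSON(as.list(annotations[i, req]), auto_unbox = TRUE,
                     digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines annotation file
#'
#' @param path file written by [write_annotations()] (or any JSONL with the
#'   same schema).
#' @return annotations data.frame.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$z <- as.integer(out$z)
  out
}
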