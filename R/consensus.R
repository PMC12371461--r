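# Multi-annotator consensus: IoU matching with z-plane tolerance, greedy
# clustering, majority-vote classification, density per mm^2.

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b numeric `c(x, y, w, h)` boxes (any units; positive `w`, `h`).
#' @return IoU in \[0, 1\]; 0 for disjoint boxes; symmetric.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
iou <- function(a, b) {
  stopifnot(length(a) == 4, length(b) == 4, a[3] > 0, a[4] > 0, b[3] > 0, b[4] > 0)
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Are two annotations claims of the same structure?
#'
#' True iff the boxes overlap with IoU at or above `iou_min` (the 20% floor
#' is inclusive) and the focal planes differ by at most `z_tol` (the +-1
#' plane tolerance absorbs annotators' differing perception of optimal
#' focus). Annotations by the same annotator are never compatible.
#'
#' @param a,b one-row data.frames (or lists) with `annotator_id`, `x`, `y`,
#'   `w`, `h`, `z`.
#' @param iou_min inclusive IoU threshold, default 0.20.
#' @param z_tol maximum focal-plane difference, default 1.
#' @return logical.
#' @export
compatible <- function(a, b, iou_min = 0.20, z_tol = 1L) {
  if (identical(a$annotator_id, b$annotator_id)) return(FALSE)
  if (abs(a$z - b$z) > z_tol) return(FALSE)
  iou(c(a$x, a$y, a$w, a$h), c(b$x, b$y, b$w, b$h)) >= iou_min
}

#' Cluster one sub-image's annotations into candidate structures
#'
#' Greedy agglomeration: all compatible cross-annotator pairs are sorted by
#' descending IoU (ties broken by annotator ids, then box position, so the
#' result does not depend on input order) and merged in turn; a merge is
#' accepted only if the combined cluster still has at most one annotation per
#' annotator and all member pairs are mutually compatible (which also caps
#' the chained z-spread). Unmatched annotations remain singletons.
#'
#' @param annotations data.frame with columns `annotator_id`, `x`, `y`, `w`,
#'   `h`, `z`, `class` — all annotations of one sub-image.
#' @inheritParams compatible
#' @return list of integer vectors, each the row indices of `annotations`
#'   forming one cluster, in a canonical order.
#' @export
cluster_annotations <- function(annotations, iou_min = 0.20, z_tol = 1L) {
  n <- nrow(annotations)
  if (n == 0) return(list())
  assert_defect_class(annotations$class)
  if (any(annotations$w <= 0 | annotations$h <= 0))
    stop("annotation boxes must have positive width and height", call. = FALSE)
  if (length(unique(annotations$subimage_id %||% "s")) > 1)
    stop("cluster_annotations() operates on a single sub-image", call. = FALSE)

  boxes <- as.matrix(annotations[, c("x", "y", "w", "h")])
  pairs <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (identical(annotations$annotator_id[i], annotations$annotator_id[j]))
        next
      if (abs(annotations$z[i] - annotations$z[j]) > z_tol) next
      v <- iou(boxes[i, ], boxes[j, ])
      if (v >= iou_min) pairs[[length(pairs) + 1]] <- c(i, j, v)
    }
  }
  cluster_of <- seq_len(n)
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    # content-based deterministic order: IoU desc, then annotator ids, then geometry
    key_a <- pmin(annotations$annotator_id[pm[, 1]], annotations$annotator_id[pm[, 2]])
    key_b <- pmax(annotations$annotator_id[pm[, 1]], annotations$annotator_id[pm[, 2]])
    geo <- boxes[pm[, 1], 1] + boxes[pm[, 2], 1] +
           boxes[pm[, 1], 2] + boxes[pm[, 2], 2]
    ord <- order(-pm[, 3], key_a, key_b, geo, pm[, 1], pm[, 2])
    for (r in ord) {
      i <- pm[r, 1]; j <- pm[r, 2]
      ci <- cluster_of[i]; cj <- cluster_of[j]
      if (ci == cj) next
      members <- which(cluster_of == ci | cluster_of == cj)
      if (anyDuplicated(annotations$annotator_id[members])) next
      ok <- TRUE
      for (p in seq_along(members)) {
        for (q in seq_len(p - 1L)) {
          mi <- members[p]; mj <- members[q]
          if (abs(annotations$z[mi] - annotations$z[mj]) > z_tol ||
              iou(boxes[mi, ], boxes[mj, ]) < iou_min) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) cluster_of[members] <- min(ci, cj)
    }
  }
  ids <- unique(cluster_of)
  clusters <- lapply(ids, function(cid) sort(which(cluster_of == cid)))
  # canonical output order: by top-left of the cluster's first box
  ord <- order(vapply(clusters, function(m) min(boxes[m, 1]), numeric(1)),
               vapply(clusters, function(m) min(boxes[m, 2]), numeric(1)),
               vapply(clusters, function(m) min(annotations$z[m]), numeric(1)))
  clusters[ord]
}

#' Consensus defects from annotation clusters
#'
#' Clusters supported by at least `min_votes` annotators become true-positive
#' defects. The consensus class is the members' unanimous class when they
#' agree, the strict-majority class when one exists, and `"mixed"` otherwise
#' (in particular, any two-member cluster whose classes differ).
#' The representative box is the member average; the focal plane is the
#' member median.
#'
#' @param clusters list from [cluster_annotations()].
#' @param annotations the data.frame the clusters index into.
#' @param min_votes minimum number of annotators, default 2.
#' @return data.frame with one row per consensus defect: `x`, `y`, `w`, `h`,
#'   `z`, `vote_count`, `consensus_class`, `members` (comma-separated
#'   annotator ids).
#' @export
consensus_defects <- function(clusters, annotations, min_votes = 2L) {
  keep <- clusters[vapply(clusters, length, integer(1)) >= min_votes]
  if (!length(keep))
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), z = numeric(), vote_count = integer(),
                      consensus_class = character(), members = character()))
  rows <- lapply(keep, function(m) {
    cls <- annotations$class[m]
    tab <- sort(table(cls), decreasing = TRUE)
    consensus <- if (length(tab) == 1) names(tab)[1]
      else if (tab[1] > tab[2]) names(tab)[1]
      else "mixed"
    data.frame(x = mean(annotations$x[m]), y = mean(annotations$y[m]),
               w = mean(annotations$w[m]), h = mean(annotations$h[m]),
               z = median(annotations$z[m]), vote_count = length(m),
               consensus_class = consensus,
               members = paste(sort(annotations$annotator_id[m]), collapse = ","))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Defect counts and density for one sub-image
#'
#' @param defects data.frame from [consensus_defects()].
#' @param area_mm2 sub-image area in mm^2 (> 0); a 600-px crop at
#'   0.325 um/px covers 0.038025 mm^2.
#' @param subimage_id,subject_id optional identifiers carried into the
#'   record.
#' @return one-row data.frame: ids, `n_defects`, per-class counts (including
#'   `n_mixed`), `area_mm2`, `density` in defects/mm^2.
#' @export
defect_density <- function(defects, area_mm2, subimage_id = NA_character_,
                           subject_id = NA_character_) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("`area_mm2` must be > 0", call. = FALSE)
  n <- nrow(defects)
  cls <- defects$consensus_class
  data.frame(subject_id = subject_id, subimage_id = subimage_id,
             n_defects = n,
             n_swelling = sum(cls == "swelling"),
             n_delamination_blebbing = sum(cls == "delamination_blebbing"),
             n_vesicle = sum(cls == "vesicle"),
             n_mixed = sum(cls == "mixed"),
             area_mm2 = area_mm2,
             density = n / area_mm2)
}

#' Full consensus pipeline for one sub-image
#'
#' Convenience wrapper: cluster, vote, count.
#'
#' @inheritParams cluster_annotations
#' @inheritParams consensus_defects
#' @inheritParams defect_density
#' @return list with `defects` and `record` (the [defect_density()] row).
#' @export
consensus_pipeline <- function(annotations, area_mm2, iou_min = 0.20,
                               z_tol = 1L, min_votes = 2L,
                               subimage_id = NA_character_,
                               subject_id = NA_character_) {
  cl <- cluster_annotations(annotations, iou_min = iou_min, z_tol = z_tol)
  def <- consensus_defects(cl, annotations, min_votes = min_votes)
  list(defects = def,
       record = defect_density(def, area_mm2, subimage_id, subject_id))
}
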