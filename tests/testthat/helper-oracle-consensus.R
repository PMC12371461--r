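# Exhaustive clustering oracle, independent of the package's greedy
# algorithm: enumerates every partition of the annotations into clusters
# with <= 1 annotation per annotator and all member pairs compatible
# (IoU >= iou_min, |dz| <= z_tol), and returns the partition maximizing the
# total within-cluster IoU. Tractable for the <= 12-annotation instances the
# equivalence check uses.

oracle_cluster <- function(ann, iou_min = 0.2, z_tol = 1) {
  n <- nrow(ann)
  if (n == 0) return(list())
  boxes <- as.matrix(ann[, c("x", "y", "w", "h")])
  iou_mat <- matrix(0, n, n)
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- iou(boxes[i, ], boxes[j, ])
    iou_mat[i, j] <- v
    compat[i, j] <- !identical(ann$annotator_id[i], ann$annotator_id[j]) &&
      abs(ann$z[i] - ann$z[j]) <= z_tol && v >= iou_min
  }
  best <- list(score = -1, clusters = NULL)
  recurse <- function(i, clusters, score) {
    if (i > n) {
      if (score > best$score + 1e-12)
        best <<- list(score = score, clusters = clusters)
      return(invisible())
    }
    for (k in seq_along(clusters)) {
      m <- clusters[[k]]
      if (all(compat[i, m])) {
        cl2 <- clusters
        cl2[[k]] <- c(m, i)
        recurse(i + 1, cl2, score + sum(iou_mat[i, m]))
      }
    }
    recurse(i + 1, c(clusters, list(i)), score)
  }
  recurse(1L, list(), 0)
  lapply(best$clusters, sort)
}

# canonical form for comparing partitions
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(m) sort(as.integer(m)))
  ord <- order(vapply(cl, `[`, integer(1), 1))
  unname(cl[ord])
}
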