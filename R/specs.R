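#' Specify a myelinated fiber for synthetic rendering
#'
#' A fiber is drawn as two parallel bright lines (the cross-section of the
#' myelin sheath for fibers lying in the section plane) following a polyline
#' centerline, optionally carrying structural defects.
#'
#' @param centerline numeric matrix with columns `x`, `y` (micrometers), at
#'   least two vertices.
#' @param sheath_spacing gap between the two bright lines, micrometers (> 0).
#' @param intensity line brightness, arbitrary units.
#' @param defects list of [defect_spec()] objects attached to this fiber.
#' @return an object of class `fiber_spec`.
#' @seealso [render_brm_stack()]
#' @export
fiber_spec <- function(centerline, sheath_spacing = 1.5, intensity = 1,
                       defects = list()) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 2)
    stop("`centerline` needs >= 2 (x, y) vertices", call. = FALSE)
  if (!is.numeric(sheath_spacing) || sheath_spacing <= 0)
    stop("`sheath_spacing` must be > 0", call. = FALSE)
  stopifnot(all(vapply(defects, inherits, logical(1), "defect_spec")))
  structure(
    list(centerline = centerline, sheath_spacing = sheath_spacing,
         intensity = intensity, defects = defects),
    class = "fiber_spec")
}

#' Specify a single myelin defect
#'
#' Three morphological classes are modelled: `swelling` (a bulge between the
#' two intact sheath lines), `delamination_blebbing` (split / fragmented
#' sheath), and `vesicle` (a small detached birefringent ring visible in only
#' one to two z-planes).
#'
#' @param kind one of `"swelling"`, `"delamination_blebbing"`, `"vesicle"`.
#' @param center numeric `c(x, y, z)`: lateral position in micrometers and the
#'   focal z-plane index (1-based).
#' @param extent numeric `c(width, height)` in micrometers, strictly positive.
#' @param z_span number of consecutive z-planes in which the defect is drawn,
#'   starting at `center[3]`. Vesicles must have `z_span` 1 or 2.
#' @return an object of class `defect_spec`.
#' @export
defect_spec <- function(kind, center, extent, z_span = 1L) {
  kind <- match.arg(kind, DEFECT_CLASSES)
  stopifnot(length(center) == 3, length(extent) == 2)
  if (any(extent <= 0)) stop("`extent` must be strictly positive", call. = FALSE)
  z_span <- as.integer(z_span)
  if (z_span < 1) stop("`z_span` must be >= 1", call. = FALSE)
  if (kind == "vesicle" && !z_span %in% 1:2)
    stop("vesicles are visible in only 1-2 z-planes: `z_span` must be 1 or 2",
         call. = FALSE)
  structure(
    list(kind = kind, center = as.numeric(center), extent = as.numeric(extent),
         z_span = z_span),
    class = "defect_spec")
}

#' Specify a simulated annotator
#'
#' Imperfection model for a human annotator marking defects on sub-images:
#' misses (sensitivity < 1), localization jitter, class confusion, and
#' spurious annotations.
#'
#' @param sensitivity probability of detecting a true defect, in \[0, 1\].
#' @param jitter_sd SD of Gaussian localization noise added to box positions,
#'   pixels.
#' @param class_confusion 3x3 row-stochastic matrix over
#'   (swelling, delamination_blebbing, vesicle); row = true class, column =
#'   reported class. Default: identity (no confusion).
#' @param false_positive_rate expected number of spurious annotations per
#'   sub-image (Poisson).
#' @return an object of class `annotator_model`.
#' @seealso [simulate_annotations()]
#' @export
annotator_model <- function(sensitivity = 0.8, jitter_sd = 0,
                            class_confusion = diag(3),
                            false_positive_rate = 0) {
  stop_if_not_scalar_prob(sensitivity, "sensitivity")
  class_confusion <- as.matrix(class_confusion)
  if (!all(dim(class_confusion) == c(3, 3)) || any(class_confusion < 0) ||
      any(abs(rowSums(class_confusion) - 1) > 1e-8))
    stop("`class_confusion` must be a 3x3 row-stochastic matrix", call. = FALSE)
  if (jitter_sd < 0 || false_positive_rate < 0)
    stop("`jitter_sd` and `false_positive_rate` must be >= 0", call. = FALSE)
  dimnames(class_confusion) <- list(DEFECT_CLASSES, DEFECT_CLASSES)
  structure(
    list(sensitivity = sensitivity, jitter_sd = jitter_sd,
         class_confusion = class_confusion,
         false_positive_rate = false_positive_rate),
    class = "annotator_model")
}

#' Specify a synthetic cohort
#'
#' Defines group sizes, demographics and the generative model for per-subject
#' repeated defect-density measurements. Defaults mirror the study cohort this
#' pipeline was designed around: 4 normal controls (NC), 5 chronic traumatic
#' encephalopathy (CTE) and 5 Alzheimer's disease (AD) donors, with controls
#' deliberately younger than the disease groups (ages about 64 vs 80 years),
#' so that age is confounded with group membership, and about 16 sub-image
#' measurements per subject.
#'
#' The measurement model is additive Gaussian, truncated at zero:
#' `density = baseline + group_effect + age_effect * (age - mean age) +
#' subject_intercept + residual`.
#'
#' @param n_per_group named integer vector `c(NC = , CTE = , AD = )`.
#' @param age_mean,age_sd per-group age distributions, years.
#' @param pmi_range per-group postmortem-interval ranges, hours (list of
#'   length-2 vectors; PMI is drawn uniformly).
#' @param baseline_density grand-mean defect density, defects/mm^2.
#' @param group_effects additive density shifts per group, defects/mm^2.
#' @param age_effect density change per year of age, defects/mm^2/year.
#' @param subject_sd SD of the per-subject random intercept.
#' @param residual_sd SD of the within-subject measurement noise.
#' @param measurements_per_subject repeated measurements (sub-images) per
#'   subject.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = c(NC = 4, CTE = 5, AD = 5),
                        age_mean = c(NC = 64, CTE = 81.8, AD = 78.8),
                        age_sd = c(NC = 4.8, CTE = 5.6, AD = 8.4),
                        pmi_range = list(NC = c(4, 14), CTE = c(7, 19),
                                         AD = c(3, 18)),
                        baseline_density = 60,
                        group_effects = c(NC = 0, CTE = 0, AD = 0),
                        age_effect = 0,
                        subject_sd = 10,
                        residual_sd = 20,
                        measurements_per_subject = 16L) {
  groups <- c("NC", "CTE", "AD")
  for (nm in c("n_per_group", "age_mean", "age_sd", "group_effects")) {
    v <- get(nm)
    if (!all(groups %in% names(v)))
      stop(sprintf("`%s` must be named with NC, CTE, AD", nm), call. = FALSE)
  }
  if (any(c(age_sd, subject_sd, residual_sd) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (measurements_per_subject < 1)
    stop("`measurements_per_subject` must be >= 1", call. = FALSE)
  structure(
    list(n_per_group = n_per_group[groups], age_mean = age_mean[groups],
         age_sd = age_sd[groups], pmi_range = pmi_range[groups],
         baseline_density = baseline_density,
         group_effects = group_effects[groups], age_effect = age_effect,
         subject_sd = subject_sd, residual_sd = residual_sd,
         measurements_per_subject = as.integer(measurements_per_subject)),
    class = "cohort_spec")
}
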