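#' Generate a synthetic cohort with repeated defect-density measurements
#'
#' Draws per-subject demographics (age, PMI, sex) from a [cohort_spec()] and
#' generates `measurements_per_subject` defect-density measurements per
#' subject from the additive model
#' `baseline + group_effect + age_effect * (age - mean age) + subject
#' intercept + residual`, truncated at 0. With the default spec, controls are
#' drawn about 16 years younger than the disease groups, reproducing the
#' age-by-group confounding that motivates the dual-covariate analysis in
#' [fit_lme()].
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param demographics optional data.frame with columns `subject_id`,
#'   `group`, `age_years`, `pmi_hours` (e.g. [study_demographics()]); when
#'   supplied, these subjects are used verbatim instead of sampling
#'   demographics, and only the density model is simulated.
#' @return a data.frame (class `cohort_table`) with one row per measurement:
#'   `subject_id`, `group` (factor NC/CTE/AD, NC reference), `sex`,
#'   `age_years`, `pmi_hours`, `measurement_id`, `density` (defects/mm^2).
#'   The generating spec is attached as attribute `"spec"`.
#' @examples
#' tab <- generate_cohort(cohort_spec(), seed = 1)
#' nrow(tab); length(unique(tab$subject_id))
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            demographics = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("NC", "CTE", "AD")
  with_seed(seed, {
    if (is.null(demographics)) {
      grp <- rep(groups, times = spec$n_per_group)
      n_sub <- length(grp)
      subjects <- data.frame(
        subject_id = sprintf("S%02d", seq_len(n_sub)),
        group = grp,
        sex = sample(c("M", "F"), n_sub, replace = TRUE, prob = c(0.75, 0.25)),
        age_years = rnorm(n_sub, spec$age_mean[grp], spec$age_sd[grp]),
        pmi_hours = vapply(grp, function(g)
          runif(1, spec$pmi_range[[g]][1], spec$pmi_range[[g]][2]), numeric(1)))
    } else {
      req <- c("subject_id", "group", "age_years", "pmi_hours")
      if (!all(req %in% names(demographics)))
        stop("`demographics` must have columns ", paste(req, collapse = ", "),
             call. = FALSE)
      subjects <- demographics[, intersect(c(req, "sex"), names(demographics))]
      if (is.null(subjects$sex)) subjects$sex <- NA_character_
    }
    n_sub <- nrow(subjects)
    age_c <- subjects$age_years - mean(subjects$age_years)
    b_sub <- rnorm(n_sub, sd = spec$subject_sd)
    m <- spec$measurements_per_subject
    rows <- subjects[rep(seq_len(n_sub), each = m), ]
    rows$measurement_id <- rep(seq_len(m), times = n_sub)
    mu <- spec$baseline_density +
      spec$group_effects[as.character(rows$group)] +
      spec$age_effect * rep(age_c, each = m) +
      rep(b_sub, each = m)
    rows$density <- pmax(mu + rnorm(nrow(rows), sd = spec$residual_sd), 0)
    rows$group <- factor(rows$group, levels = groups)
    rownames(rows) <- NULL
    structure(rows, spec = spec, class = c("cohort_table", "data.frame"))
  })
}

#' Demographics of the reference 14-donor cohort
#'
#' The demographic table of the ex vivo prefrontal-cortex cohort the pipeline
#' was designed around: 4 normal controls, 5 CTE and 5 AD donors with age,
#' sex, postmortem interval, neuropathological stage and available cognitive
#' scores. Controls are markedly younger (mean 64 years) than the pooled
#' disease groups (mean 80.3 years), which is the confounding structure the
#' dual-covariate mixed models address.
#'
#' @return a data.frame with columns `subject_id`, `group`, `sex`,
#'   `age_years`, `pmi_hours`, `stage`, `cds`, `cdr`.
#' @seealso [summarize_demographics()], [generate_cohort()]
#' @export
study_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "myelinquant", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
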