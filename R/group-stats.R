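# Covariate-controlled group statistics: LME with subject random intercepts
# under PMI-only vs PMI+age covariate models, Bonferroni pairwise contrasts,
# Spearman correlation, PMI-controlled standardized-beta regression,
# demographic summaries.

#' Per-group and pooled-disease demographic summaries
#'
#' Means and sample SDs (n - 1 denominator) of age and PMI per group, plus a
#' pooled `disease` row (CTE and AD combined) — the comparison that exposes
#' the age gap between controls and disease donors.
#'
#' @param cohort data.frame with columns `group`, `age_years`, `pmi_hours`
#'   and one row per subject (e.g. [study_demographics()]).
#' @return data.frame with rows NC, CTE, AD, disease: `n`, `age_mean`,
#'   `age_sd`, `pmi_mean`, `pmi_sd`. SDs of single-subject groups are `NA`.
#' @examples
#' summarize_demographics(study_demographics())
#' @export
summarize_demographics <- function(cohort) {
  req <- c("group", "age_years", "pmi_hours")
  if (!all(req %in% names(cohort)))
    stop("`cohort` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  grp <- as.character(cohort$group)
  one <- function(sel, label) {
    data.frame(group = label, n = sum(sel),
               age_mean = mean(cohort$age_years[sel]),
               age_sd = if (sum(sel) > 1) sd(cohort$age_years[sel]) else NA_real_,
               pmi_mean = mean(cohort$pmi_hours[sel]),
               pmi_sd = if (sum(sel) > 1) sd(cohort$pmi_hours[sel]) else NA_real_)
  }
  out <- rbind(one(grp == "NC", "NC"), one(grp == "CTE", "CTE"),
               one(grp == "AD", "AD"), one(grp %in% c("CTE", "AD"), "disease"))
  rownames(out) <- NULL
  out
}

#' Linear mixed-effects group comparison with covariate control
#'
#' Fits `response ~ group + pmi (+ age) + (1 | subject)` by restricted
#' maximum likelihood, with NC as the reference level. Fixed-effect tests use
#' Satterthwaite degrees of freedom; the overall group effect is a Type III
#' F test; pairwise group contrasts are Bonferroni-adjusted over the 3
#' pairs. Comparing `covariate_model = "pmi_only"` against `"pmi_age"` on an
#' age-confounded cohort shows how an apparent group effect can be absorbed
#' by age.
#'
#' @param table data.frame with columns `subject_id`, `group` (NC/CTE/AD),
#'   `age_years`, `pmi_hours` and a response column; one row per repeated
#'   measurement (see [generate_cohort()]).
#' @param covariate_model `"pmi_age"` (default) or `"pmi_only"`.
#' @param response name of the response column, default `"density"`.
#' @param pairwise compute Bonferroni-adjusted pairwise contrasts (default
#'   `TRUE`); skip for speed in large simulation loops where only the
#'   overall test is needed.
#' @return an object of class `lme_result`: list with `covariate_model`,
#'   `fixed` (estimate/SE/df/t/p per fixed effect), `group_p` (overall Type
#'   III p-value), `pairwise` (Bonferroni-adjusted contrasts), `varcomp`
#'   (subject and residual variances), `singular` flag, and the `model`
#'   itself.
#' @export
fit_lme <- function(table, covariate_model = c("pmi_age", "pmi_only"),
                    response = "density", pairwise = TRUE) {
  covariate_model <- match.arg(covariate_model)
  req <- c("subject_id", "group", "age_years", "pmi_hours", response)
  if (!all(req %in% names(table)))
    stop("`table` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  df <- as.data.frame(table)
  df$group <- factor(as.character(df$group), levels = c("NC", "CTE", "AD"))
  df$group <- droplevels(df$group)
  if (nlevels(df$group) < 2) stop("need >= 2 groups", call. = FALSE)
  df$.resp <- df[[response]]
  chk <- unique(df[, c("subject_id", "group", "age_years", "pmi_hours")])
  if (anyDuplicated(chk$subject_id))
    stop("group/age/pmi must be constant within subject", call. = FALSE)

  fml <- if (covariate_model == "pmi_age")
    .resp ~ group + pmi_hours + age_years + (1 | subject_id)
  else
    .resp ~ group + pmi_hours + (1 | subject_id)
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: subject variance estimated at zero; ",
            "fixed effects reduce to the pooled least-squares fit")

  sm <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
  rownames(fixed) <- NULL
  an <- anova(fit, type = 3)
  group_p <- an["group", "Pr(>F)"]

  pw <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, "group")
    pw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "bonferroni"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(subject = vc$vcov[vc$grp == "subject_id"],
               residual = vc$vcov[vc$grp == "Residual"])

  structure(list(covariate_model = covariate_model, fixed = fixed,
                 group_p = group_p, pairwise = pw, varcomp = varcomp,
                 singular = singular, model = fit),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> covariates: %s\n",
              if (x$covariate_model == "pmi_age") "PMI + age" else "PMI only"))
  cat(sprintf("overall group effect: p = %.4g%s\n", x$group_p,
              if (x$singular) "  (singular fit)" else ""))
  print(x$fixed, digits = 4)
  if (!is.null(x$pairwise)) {
    cat("Bonferroni pairwise contrasts:\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t approximation. Degenerate input (either variable constant) yields
#' `NA` with a warning.
#'
#' @param x,y paired numeric vectors, at least 3 complete pairs.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Standardized-beta regression of defect counts on chromogen area,
#' controlling for PMI
#'
#' All variables are z-scored and an ordinary least-squares model
#' `defects ~ chromogen + pmi` is fit, so the coefficients are standardized
#' betas giving the direction and strength of each predictor's association.
#'
#' @param defects numeric response (defect counts or densities).
#' @param chromogen_percent DAB percent-area predictor.
#' @param pmi postmortem interval covariate, hours.
#' @return data.frame with one row per predictor: `term`, `beta`, `se`, `p`.
#'   A zero-variance predictor gets `NA` with a warning.
#' @export
regression_controlled <- function(defects, chromogen_percent, pmi) {
  n <- length(defects)
  if (length(chromogen_percent) != n || length(pmi) != n)
    stop("inputs must have equal length", call. = FALSE)
  if (n < 4) stop("need >= 4 observations", call. = FALSE)
  zs <- function(v) if (sd(v) == 0) rep(NA_real_, length(v)) else
    (v - mean(v)) / sd(v)
  d <- zs(defects); ch <- zs(chromogen_percent); pm <- zs(pmi)
  if (anyNA(ch) || anyNA(pm) || anyNA(d))
    warning("zero-variance variable: its standardized beta is undefined")
  keep <- !c(chromogen = anyNA(ch), pmi = anyNA(pm))
  preds <- list(chromogen = ch, pmi = pm)[keep]
  out <- data.frame(term = c("chromogen", "pmi"), beta = NA_real_,
                    se = NA_real_, p = NA_real_)
  if (anyNA(d) || !length(preds)) return(out)
  X <- do.call(cbind, preds)
  fit <- lm(d ~ X)
  sm <- summary(fit)$coefficients
  for (i in seq_along(preds)) {
    r <- paste0("X", names(preds)[i])
    if (!r %in% rownames(sm)) r <- "X"   # single-predictor case
    out[out$term == names(preds)[i], c("beta", "se", "p")] <-
      sm[r, c("Estimate", "Std. Error", "Pr(>|t|)")]
  }
  out
}
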