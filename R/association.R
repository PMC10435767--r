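#' Per-cohort group-difference general linear model
#'
#' Ordinary least squares of a (typically rank-inverse-normal transformed)
#' trait on the case indicator with age and sex as covariates. The reported
#' effect is the group coefficient; with rank-INT inputs it is a
#' standardized effect comparable across cohorts. Co-morbidity subgroup
#' contrasts use the same operation on filtered data.
#'
#' @param data Data frame with the trait column, `group` (values `control` /
#'   `DS`; control is the reference) and the `adjust` covariates.
#' @param trait Name of the response column.
#' @param adjust Covariate names (default `age` and `sex`); covariates that
#'   are constant in `data` are dropped.
#' @param cohort Optional cohort label carried into the result.
#' @return A one-row tibble (class `effect_estimate`): `trait`, `cohort`,
#'   `beta`, `se`, `statistic`, `df`, `p`, `n`.
#' @export
fit_glm <- function(data, trait, adjust = c("age", "sex"), cohort = NA_character_) {
  if (!trait %in% names(data)) rlang::abort(paste0("No column ", trait, "."))
  if (length(unique(data$group)) < 2) {
    rlang::abort("Both groups must be present after filtering.")
  }
  df <- data.frame(
    y = data[[trait]],
    ds = as.numeric(data$group != "control")
  )
  keep <- character(0)
  for (v in adjust) {
    if (!v %in% names(data)) rlang::abort(paste0("No covariate ", v, "."))
    if (length(unique(data[[v]])) > 1) {
      df[[v]] <- data[[v]]
      keep <- c(keep, v)
    }
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p <- length(keep) + 2
  if (nrow(df) < p + 2) rlang::abort("Too few samples for the design.")
  fit <- stats::lm(stats::reformulate(c("ds", keep), response = "y"), data = df)
  if (any(is.na(stats::coef(fit)))) {
    rlang::abort("Design matrix is rank deficient.")
  }
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(
    trait = trait, cohort = cohort,
    beta = sm["ds", "Estimate"], se = sm["ds", "Std. Error"],
    statistic = sm["ds", "t value"], df = fit$df.residual,
    p = sm["ds", "Pr(>|t|)"], n = nrow(df)
  )
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Sibling-paired mixed model
#'
#' Linear mixed-effects model of a trait on group, age and sex with family
#' id as a random intercept, for sibling-pair designs. Fitted by REML
#' (lme4/lmerTest); zero between-family variance is allowed at the boundary,
#' where the fit collapses to ordinary least squares. Degrees of freedom and
#' p-value use the Satterthwaite approximation.
#'
#' @param data Data frame with the trait column, `group`, `family_id` and the
#'   `adjust` covariates. At least 5 families are required.
#' @param trait Name of the response column.
#' @param adjust Covariate names; constants are dropped. Use `NULL` for none.
#' @param cohort Optional cohort label.
#' @return A one-row `effect_estimate` tibble with additional columns
#'   `family_sd` and `resid_sd` (estimated variance components).
#' @export
fit_paired <- function(data, trait, adjust = c("age", "sex"),
                       cohort = NA_character_) {
  if (!"family_id" %in% names(data) || all(is.na(data$family_id))) {
    rlang::abort("fit_paired needs a family_id column.")
  }
  df <- data.frame(
    y = data[[trait]],
    ds = as.numeric(data$group != "control"),
    family_id = data$family_id
  )
  keep <- character(0)
  for (v in adjust) {
    if (length(unique(data[[v]])) > 1) {
      df[[v]] <- data[[v]]
      keep <- c(keep, v)
    }
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$family_id)) < 5) {
    rlang::abort("Need at least 5 families.")
  }
  fml <- stats::as.formula(paste(
    "y ~", paste(c("ds", keep), collapse = " + "), "+ (1 | family_id)"
  ))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = df, REML = TRUE)
  ))
  sm <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  fam_sd <- vc$sdcor[vc$grp == "family_id"]
  res_sd <- vc$sdcor[vc$grp == "Residual"]
  out <- tibble::tibble(
    trait = trait, cohort = cohort,
    beta = sm["ds", "Estimate"], se = sm["ds", "Std. Error"],
    statistic = sm["ds", "t value"], df = sm["ds", "df"],
    p = sm["ds", "Pr(>|t|)"], n = nrow(df),
    family_sd = fam_sd, resid_sd = res_sd
  )
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-cohort standardized effect estimates for one trait with weights
#' `1/se^2`: pooled beta is the weighted mean, pooled se is
#' `1/sqrt(sum(w))`, and a two-sided normal p-value is reported.
#'
#' @param estimates An `effect_estimate` tibble (rows = cohorts) or a list of
#'   them; all rows must concern the same trait and have `se > 0`.
#' @return A one-row tibble of class `meta_result`: `trait`, `beta`, `se`,
#'   `z`, `p`, `k` (number of studies). Per-cohort inputs are attached as
#'   attribute `"cohort_estimates"` (see [tidy.meta_result()]).
#' @export
meta_fixed <- function(estimates) {
  est <- if (inherits(estimates, "data.frame")) {
    tibble::as_tibble(estimates)
  } else {
    dplyr::bind_rows(estimates)
  }
  if (!nrow(est)) rlang::abort("Need at least one estimate.")
  if (length(unique(est$trait)) != 1) {
    rlang::abort("All estimates must concern the same trait.")
  }
  if (any(est$se <= 0)) rlang::abort("All standard errors must be positive.")
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  out <- tibble::tibble(
    trait = est$trait[1], beta = beta, se = se,
    z = z, p = 2 * stats::pnorm(-abs(z)), k = nrow(est)
  )
  attr(out, "cohort_estimates") <- est
  class(out) <- c("meta_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values via
#' `stats::p.adjust(method = "BH")`, with input validation: all p-values must
#' lie in (0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("p-values must lie in (0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-cohort association analysis with fixed-effects pooling
#'
#' For each cohort: rank-inverse-normal transforms each trait within the
#' cohort, fits the group GLM ([fit_glm()]) adjusting for age and sex, then
#' pools cohorts per trait with [meta_fixed()] and adjusts the pooled
#' p-values across traits with [bh_adjust()].
#'
#' @param traits Tibble of trait (or peak) values with `sample_id`.
#' @param meta Sample metadata (`sample_id`, `cohort`, `group`, `age`, `sex`,
#'   optionally `subcohort` - only `"main"` rows are used).
#' @param which_traits Trait columns to analyse; default all non-id columns.
#' @param adjust Covariates for the GLM.
#' @param rank_offset Offset of the rank-INT transform.
#' @return List with `by_cohort` (per-cohort effect tibble) and `meta`
#'   (pooled tibble with BH-adjusted `q`).
#' @export
associate_cohorts <- function(traits, meta, which_traits = NULL,
                              adjust = c("age", "sex"), rank_offset = 0.5) {
  which_traits <- which_traits %||% setdiff(names(traits), "sample_id")
  dat <- dplyr::inner_join(traits, meta, by = "sample_id")
  if ("subcohort" %in% names(dat)) {
    dat <- dplyr::filter(dat, .data$subcohort == "main")
  }
  by_cohort <- purrr::map_dfr(split(dat, dat$cohort), function(d) {
    purrr::map_dfr(which_traits, function(tr) {
      d[[tr]] <- rank_inverse_normal(d[[tr]], offset = rank_offset)
      fit_glm(d, tr, adjust = adjust, cohort = d$cohort[1])
    })
  })
  meta_tbl <- purrr::map_dfr(which_traits, function(tr) {
    meta_fixed(by_cohort[by_cohort$trait == tr, ])
  })
  meta_tbl$q <- bh_adjust(meta_tbl$p)
  list(by_cohort = by_cohort, meta = meta_tbl)
}
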