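#' Fit a linear age trend for one group
#'
#' OLS of a raw-scale (percentage) derived trait on age within one group.
#'
#' @param data Data frame with the trait column and `age`; if `group` is
#'   given, rows are filtered to that group first.
#' @param trait Name of the trait column.
#' @param group Optional group value to filter on (`data$group`).
#' @param cohort Optional cohort label carried into the result.
#' @return A `trend_fit` object: slope (% per year), intercept (%),
#'   coefficient covariance, n, residual SD and the observed age range.
#' @export
fit_trend <- function(data, trait, group = NULL, cohort = NA_character_) {
  if (!is.null(group)) data <- data[data$group == group, , drop = FALSE]
  y <- data[[trait]]
  age <- data$age
  ok <- stats::complete.cases(y, age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 3) rlang::abort("Need at least 3 subjects in the group.")
  if (length(unique(age)) < 2) rlang::abort("Degenerate ages: all equal.")
  fit <- stats::lm(y ~ age)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / fit$df.residual
  xtx_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(c("(Intercept)", "age"), c("(Intercept)", "age"))
  structure(list(
    trait = trait, cohort = cohort, group = group %||% NA_character_,
    slope = unname(stats::coef(fit)["age"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    vcov = vc, n = length(y),
    sigma = sqrt(sigma2),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    age_range = range(age)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit %s (%s%s): y = %.3f x + %.3f (n = %d, ages %.1f-%.1f)\n",
              x$trait, x$group,
              if (is.na(x$cohort)) "" else paste0(", ", x$cohort),
              x$slope, x$intercept, x$n, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Test equality of age slopes between groups
#'
#' Single-model OLS with group, age and their interaction. A non-significant
#' interaction means the case and control trend curves are parallel - the
#' rate of age-related change does not differ, contradicting models that
#' predict accelerating divergence with age ("amplified instability").
#'
#' @param data Data frame with the trait column, `group` and `age`.
#' @param trait Name of the trait column.
#' @param cohort Optional cohort label.
#' @return A one-row tibble: interaction `beta`, `se`, `statistic`, `p`, `n`.
#' @export
test_parallel_slopes <- function(data, trait, cohort = NA_character_) {
  if (length(unique(data$group)) < 2) {
    rlang::abort("Both groups must be present.")
  }
  df <- data.frame(y = data[[trait]],
                   ds = as.numeric(data$group != "control"),
                   age = data$age)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(y ~ ds * age, data = df)
  if (any(is.na(stats::coef(fit)))) {
    rlang::abort("Design matrix is rank deficient.")
  }
  sm <- summary(fit)$coefficients
  tibble::tibble(
    trait = trait, cohort = cohort,
    beta = sm["ds:age", "Estimate"], se = sm["ds:age", "Std. Error"],
    statistic = sm["ds:age", "t value"], p = sm["ds:age", "Pr(>|t|)"],
    n = nrow(df)
  )
}

#' Glycan-age shift between the case and control trend curves
#'
#' For each grid age x, the shift is the control age whose expected trait
#' level equals the case expectation at x, minus x:
#' `delta(x) = (a_DS * x + b_DS - b_ctrl) / a_ctrl - x`. For exactly parallel
#' lines this is the constant `(b_DS - b_ctrl) / a_ctrl`. The sign convention
#' makes delta positive when cases resemble biologically older controls,
#' for traits that rise with age and are elevated in cases as well as for
#' traits that fall with age and are reduced in cases.
#'
#' @param fit_ds,fit_ctrl [fit_trend()] results for the case and control
#'   groups (same trait). Slopes must share sign and the control slope must
#'   exceed `tol` in magnitude.
#' @param grid Age grid (years); default the integer ages spanning the
#'   intersection of the two observed age ranges.
#' @param tol Minimum admissible control slope magnitude.
#' @return An `age_shift` object: the per-age shift table and its min, max
#'   and mean.
#' @export
age_shift <- function(fit_ds, fit_ctrl, grid = NULL, tol = 1e-6) {
  stopifnot(inherits(fit_ds, "trend_fit"), inherits(fit_ctrl, "trend_fit"))
  if (!identical(fit_ds$trait, fit_ctrl$trait)) {
    rlang::abort("Both fits must concern the same trait.")
  }
  if (abs(fit_ctrl$slope) <= tol) {
    rlang::abort("Control slope is near zero: shift undefined.")
  }
  if (sign(fit_ds$slope) != sign(fit_ctrl$slope)) {
    rlang::abort("Slopes have opposite signs: shift undefined.")
  }
  if (is.null(grid)) {
    lo <- max(fit_ds$age_range[1], fit_ctrl$age_range[1])
    hi <- min(fit_ds$age_range[2], fit_ctrl$age_range[2])
    if (hi <= lo) rlang::abort("Age ranges do not overlap.")
    grid <- seq(ceiling(lo), floor(hi))
    if (!length(grid)) grid <- (lo + hi) / 2
  }
  delta <- (fit_ds$slope * grid + fit_ds$intercept - fit_ctrl$intercept) /
    fit_ctrl$slope - grid
  structure(list(
    trait = fit_ds$trait, cohort = fit_ds$cohort,
    grid = tibble::tibble(age = grid, shift = delta),
    min = min(delta), max = max(delta), mean = mean(delta),
    fit_ds = fit_ds, fit_ctrl = fit_ctrl
  ), class = "age_shift")
}

#' @export
print.age_shift <- function(x, ...) {
  cat(sprintf(
    "Glycan-age shift (%s%s): %.1f-%.1f years (average %.1f) over ages %g-%g\n",
    x$trait, if (is.na(x$cohort)) "" else paste0(", ", x$cohort),
    x$min, x$max, x$mean, min(x$grid$age), max(x$grid$age)))
  invisible(x)
}

#' Combine per-cohort glycan-age shifts
#'
#' The cross-cohort summary is the unweighted arithmetic mean of the
#' per-cohort average shifts.
#'
#' @param shifts A list of [age_shift()] objects (all the same trait) or a
#'   numeric vector of per-cohort average shifts.
#' @return The combined mean shift in years (scalar).
#' @export
combine_shifts <- function(shifts) {
  if (is.numeric(shifts)) {
    if (!length(shifts)) rlang::abort("Need at least one cohort.")
    return(mean(shifts))
  }
  if (inherits(shifts, "age_shift")) shifts <- list(shifts)
  if (!length(shifts)) rlang::abort("Need at least one cohort.")
  traits <- unique(purrr::map_chr(shifts, "trait"))
  if (length(traits) != 1) rlang::abort("Shifts mix different traits.")
  mean(purrr::map_dbl(shifts, "mean"))
}

#' Bootstrap confidence interval for the glycan-age shift
#'
#' Nonparametric bootstrap resampling subjects with replacement within group
#' (and within cohort when several are present); for each replicate the
#' per-cohort trend fits, average shifts and their cross-cohort combination
#' are recomputed. Percentile intervals are returned.
#'
#' @param data Data frame with the trait column, `group`, `age` and
#'   optionally `cohort`.
#' @param trait Name of the trait column.
#' @param B Number of bootstrap replicates (>= 200 recommended).
#' @param seed Integer seed (reproducible).
#' @param grid Age grid passed to [age_shift()]; default per-cohort
#'   intersection grid recomputed per replicate.
#' @param level Confidence level.
#' @return Tibble with one row per cohort plus `"combined"`: point estimate,
#'   `lower`, `upper`, `B_used` (replicates where all fits succeeded).
#' @export
bootstrap_shift_ci <- function(data, trait, B = 500, seed, grid = NULL,
                               level = 0.95) {
  if (!"cohort" %in% names(data)) data$cohort <- "cohort"
  split_groups <- split(seq_len(nrow(data)),
                        interaction(data$cohort, data$group, drop = TRUE))
  if (any(lengths(split_groups) < 3)) {
    rlang::abort("Each group within each cohort needs at least 3 subjects.")
  }
  cohorts <- unique(data$cohort)
  one_rep <- function(idx) {
    d <- data[idx, , drop = FALSE]
    per <- vapply(cohorts, function(ch) {
      dc <- d[d$cohort == ch, , drop = FALSE]
      fds <- fit_trend(dc, trait, group = "DS", cohort = ch)
      fct <- fit_trend(dc, trait, group = "control", cohort = ch)
      age_shift(fds, fct, grid = grid)$mean
    }, numeric(1))
    c(per, combined = mean(per))
  }
  point <- one_rep(seq_len(nrow(data)))
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- unlist(lapply(split_groups, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    reps[b, ] <- tryCatch(one_rep(idx), error = function(e)
      rep(NA_real_, length(point)))
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - level) / 2
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha))
  tibble::tibble(
    trait = trait,
    cohort = c(cohorts, "combined"),
    shift = unname(point),
    lower = unname(qs[1, ]), upper = unname(qs[2, ]),
    B_used = sum(ok)
  )
}

#' Full ageing-clock analysis for one trait
#'
#' Per cohort: linear trends per group, parallel-slopes (rate-of-ageing)
#' test, glycan-age shift; plus the cross-cohort combined shift and a
#' plot-ready table of fitted lines.
#'
#' @param data Data frame with the trait column, `cohort`, `group`, `age`.
#' @param trait Name of the trait column.
#' @param grid Optional common age grid for [age_shift()].
#' @param bootstrap_B If > 0, also compute [bootstrap_shift_ci()].
#' @param seed Seed for the bootstrap (required when `bootstrap_B > 0`).
#' @return A `clock_result` list: `report` (tibble per cohort), `combined`
#'   (mean shift, years), `shifts` (list of `age_shift`), `lines`
#'   (plot-ready fitted lines), optionally `ci`.
#' @export
clock_analysis <- function(data, trait, grid = NULL, bootstrap_B = 0,
                           seed = NULL) {
  if (!"cohort" %in% names(data)) data$cohort <- "cohort"
  cohorts <- unique(data$cohort)
  shifts <- list()
  report <- purrr::map_dfr(cohorts, function(ch) {
    dc <- data[data$cohort == ch, , drop = FALSE]
    fds <- fit_trend(dc, trait, group = "DS", cohort = ch)
    fct <- fit_trend(dc, trait, group = "control", cohort = ch)
    par <- test_parallel_slopes(dc, trait, cohort = ch)
    sh <- age_shift(fds, fct, grid = grid)
    shifts[[ch]] <<- sh
    tibble::tibble(
      trait = trait, cohort = ch,
      slope_control = fct$slope, intercept_control = fct$intercept,
      slope_ds = fds$slope, intercept_ds = fds$intercept,
      interaction_p = par$p,
      shift_min = sh$min, shift_max = sh$max, shift_mean = sh$mean,
      n_control = fct$n, n_ds = fds$n
    )
  })
  lines <- purrr::map_dfr(shifts, function(sh) {
    ages <- seq(sh$fit_ctrl$age_range[1], sh$fit_ds$age_range[2], length.out = 50)
    dplyr::bind_rows(
      tibble::tibble(trait = trait, cohort = sh$cohort, group = "control",
                     age = ages,
                     fitted = sh$fit_ctrl$slope * ages + sh$fit_ctrl$intercept),
      tibble::tibble(trait = trait, cohort = sh$cohort, group = "DS",
                     age = ages,
                     fitted = sh$fit_ds$slope * ages + sh$fit_ds$intercept)
    )
  })
  out <- list(report = report, combined = combine_shifts(shifts),
              shifts = shifts, lines = lines, trait = trait)
  if (bootstrap_B > 0) {
    if (is.null(seed)) rlang::abort("Provide a seed for the bootstrap.")
    out$ci <- bootstrap_shift_ci(data, trait, B = bootstrap_B, seed = seed,
                                 grid = grid)
  }
  structure(out, class = "clock_result")
}

#' @export
print.clock_result <- function(x, ...) {
  cat(sprintf("Glycan-age shift for %s: combined %.1f years\n",
              x$trait, x$combined))
  print(x$report[, c("cohort", "shift_min", "shift_max", "shift_mean",
                     "interaction_p")])
  invisible(x)
}
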