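#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted batch model
#'
#' @param x A `batch_model` from [batch_correct()].
#' @param ... Unused.
#' @return Long tibble: one row per batch x peak with the raw and shrunken
#'   location (`gamma`) and scale (`delta`) effects.
#' @method tidy batch_model
#' @export
tidy.batch_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, peak = x$peaks) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      delta_hat = as.vector(t(x$delta_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta_star = as.vector(t(x$delta_star))
    )
}

#' @rdname tidy.batch_model
#' @return `glance()`: one row per batch with the EB prior hyperparameters.
#' @method glance batch_model
#' @export
glance.batch_model <- function(x, ...) {
  tibble::tibble(
    batch = x$batches,
    gamma_bar = unname(x$gamma_bar), t2 = unname(x$t2),
    a_prior = unname(x$a_prior), b_prior = unname(x$b_prior),
    n_peaks = length(x$peaks)
  )
}

#' Tidy a trend fit
#'
#' @param x A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, cohort = x$cohort, group = x$group,
    term = c("intercept", "age"),
    estimate = c(x$intercept, x$slope),
    std.error = sqrt(diag(x$vcov))
  )
}

#' @rdname tidy.trend_fit
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, cohort = x$cohort, group = x$group,
    n = x$n, sigma = x$sigma, r.squared = x$r_squared,
    age_min = x$age_range[1], age_max = x$age_range[2]
  )
}

#' Tidy an age-shift estimate
#'
#' @param x An `age_shift` from [age_shift()].
#' @param ... Unused.
#' @return `tidy()`: the per-age shift table; `glance()`: one row with min,
#'   max and mean shift.
#' @method tidy age_shift
#' @export
tidy.age_shift <- function(x, ...) {
  dplyr::mutate(x$grid, trait = x$trait, cohort = x$cohort,
                .before = 1)
}

#' @rdname tidy.age_shift
#' @method glance age_shift
#' @export
glance.age_shift <- function(x, ...) {
  tibble::tibble(trait = x$trait, cohort = x$cohort,
                 shift_min = x$min, shift_max = x$max, shift_mean = x$mean)
}

#' Tidy a PCA model
#'
#' @param x A `glycan_pca` from [fit_pca()].
#' @param ... Unused.
#' @return `tidy()`: long loadings table (`variable`, `component`, `loading`);
#'   `glance()`: one row per component with its explained-variance fraction.
#' @method tidy glycan_pca
#' @export
tidy.glycan_pca <- function(x, ...) {
  tibble::as_tibble(x$rotation, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy.glycan_pca
#' @method glance glycan_pca
#' @export
glance.glycan_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$rotation),
                 sdev = x$sdev,
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' Tidy a fixed-effects meta-analysis result
#'
#' @param x A `meta_result` from [meta_fixed()].
#' @param ... Unused.
#' @return `tidy()`: the per-cohort input estimates; `glance()`: the pooled
#'   row.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  attr(x, "cohort_estimates")
}

#' @rdname tidy.meta_result
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  out <- x
  attr(out, "cohort_estimates") <- NULL
  class(out) <- setdiff(class(out), "meta_result")
  out
}
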