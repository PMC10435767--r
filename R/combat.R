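#' Empirical-Bayes batch (plate) correction of log-scale glycan peaks
#'
#' Removes plate effects from a log-transformed peak table using the
#' parametric empirical-Bayes location-scale procedure (the ComBat model):
#' per peak, measurements are standardized with a covariate model that keeps
#' the biological covariates in `preserve`; per-plate additive effects
#' (gamma) and multiplicative scale effects (delta) are estimated and shrunk
#' toward pooled priors via the standard EB moment equations; the shrunken
#' effects are then subtracted/rescaled.
#'
#' @param data A peak table at stage `"log"`.
#' @param meta Sample metadata with `sample_id`, `plate` and the `preserve`
#'   columns; every sample in `data` must appear.
#' @param preserve Covariates whose effects must survive the correction
#'   (default `group`, `age`, `sex`).
#' @param conv Convergence tolerance of the EB iteration.
#' @return The corrected table (stage `"batch_corrected"`) with the fitted
#'   [`batch_model`][tidy.batch_model] attached as attribute `"batch_model"`
#'   (retrieve with [batch_model()]).
#' @export
batch_correct <- function(data, meta, preserve = c("group", "age", "sex"),
                          conv = 1e-6) {
  stage <- peak_stage(data)
  if (is.null(stage) || stage != "log") {
    rlang::abort("batch_correct expects a log-stage peak table.")
  }
  pk <- peak_cols(data)
  if (!"sample_id" %in% names(data) || !"sample_id" %in% names(meta)) {
    rlang::abort("Both data and meta need a sample_id column.")
  }
  m <- meta[match(data$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) rlang::abort("Some samples are missing from meta.")
  if (!"plate" %in% names(m) || anyNA(m$plate)) {
    rlang::abort("Every sample needs a plate label.")
  }

  batch <- factor(m$plate)
  nb <- nlevels(batch)
  n_per <- table(batch)
  if (any(n_per < 2)) {
    rlang::abort("Every plate needs at least 2 samples.")
  }

  dat <- t(as.matrix(data[pk]))          # peaks x samples
  n <- ncol(dat)

  if (nb == 1L) {
    rlang::warn("Single batch: correction is the identity.")
    model <- structure(list(
      batches = levels(batch), peaks = pk,
      gamma_hat = matrix(0, 1, length(pk), dimnames = list(levels(batch), pk)),
      delta_hat = matrix(1, 1, length(pk), dimnames = list(levels(batch), pk)),
      gamma_star = matrix(0, 1, length(pk), dimnames = list(levels(batch), pk)),
      delta_star = matrix(1, 1, length(pk), dimnames = list(levels(batch), pk)),
      gamma_bar = 0, t2 = 0, a_prior = NA_real_, b_prior = NA_real_,
      var_pooled = rep(NA_real_, length(pk)), preserve = preserve
    ), class = "batch_model")
    out <- data
    peak_stage(out) <- "batch_corrected"
    attr(out, "batch_model") <- model
    return(out)
  }

  batchmod <- stats::model.matrix(~ -1 + batch)
  mod <- NULL
  if (length(preserve)) {
    missing <- setdiff(preserve, names(m))
    if (length(missing)) {
      rlang::abort(paste0("preserve covariate(s) absent from meta: ",
                          paste(missing, collapse = ", ")))
    }
    mod <- stats::model.matrix(
      stats::reformulate(preserve),
      data = as.data.frame(m)
    )[, -1, drop = FALSE]
  }
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design)) {
    rlang::abort(paste0(
      "Design is rank deficient: a plate is confounded with a preserve ",
      "covariate (", paste(preserve, collapse = ", "), ")."
    ))
  }

  # per-peak regression on [batch indicators, covariates]
  B_hat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand_mean <- crossprod(as.numeric(n_per) / n, B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- rowMeans((dat - t(design %*% B_hat))^2)
  if (any(var_pooled <= 0)) {
    rlang::abort("Zero residual variance for at least one peak.")
  }

  stand_mean <- matrix(grand_mean, nrow(dat), n,
                       dimnames = list(rownames(dat), colnames(dat)))
  if (!is.null(mod) && ncol(mod)) {
    stand_mean <- stand_mean +
      t(mod %*% B_hat[-seq_len(nb), , drop = FALSE])
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  # batches x peaks
  gamma_hat <- solve(crossprod(batchmod), crossprod(batchmod, t(s_data)))
  delta_hat <- matrix(NA_real_, nb, nrow(dat),
                      dimnames = list(levels(batch), rownames(dat)))
  for (i in seq_len(nb)) {
    idx <- which(batch == levels(batch)[i])
    delta_hat[i, ] <- apply(s_data[, idx, drop = FALSE], 1, stats::var)
  }
  dimnames(gamma_hat) <- dimnames(delta_hat)

  # EB hyperpriors (method of moments across peaks, per batch)
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  a_prior <- apply(delta_hat, 1, function(d) {
    mh <- mean(d); s2 <- stats::var(d); (2 * s2 + mh^2) / s2
  })
  b_prior <- apply(delta_hat, 1, function(d) {
    mh <- mean(d); s2 <- stats::var(d); (mh * s2 + mh^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    idx <- which(batch == levels(batch)[i])
    ni <- length(idx)
    sd_i <- s_data[, idx, drop = FALSE]
    g_new <- gamma_hat[i, ]
    d_new <- delta_hat[i, ]
    change <- 1
    while (change > conv) {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2[i] * ni * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (t2[i] * ni + d_old)
      sum2 <- rowSums((sd_i - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
    }
    gamma_star[i, ] <- g_new
    delta_star[i, ] <- d_new
  }

  bayes <- s_data
  for (i in seq_len(nb)) {
    idx <- which(batch == levels(batch)[i])
    bayes[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  corrected <- bayes * sqrt(var_pooled) + stand_mean

  model <- structure(list(
    batches = levels(batch), peaks = pk,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2,
    a_prior = a_prior, b_prior = b_prior,
    var_pooled = stats::setNames(var_pooled, pk),
    preserve = preserve
  ), class = "batch_model")

  out <- data
  out[pk] <- t(corrected)
  peak_stage(out) <- "batch_corrected"
  attr(out, "batch_model") <- model
  out
}

#' Retrieve the fitted batch model from a corrected peak table
#'
#' @param data A table returned by [batch_correct()].
#' @return The `batch_model` object.
#' @export
batch_model <- function(data) attr(data, "batch_model", exact = TRUE)

#' @export
print.batch_model <- function(x, ...) {
  cat("Empirical-Bayes batch model:", length(x$batches), "batch(es),",
      length(x$peaks), "peaks\n")
  invisible(x)
}
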