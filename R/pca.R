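#' Principal component analysis of glycan variables
#'
#' Eigen-decomposition (via SVD) of the correlation matrix (standardized
#' scale, the default) or covariance matrix of the selected columns, with a
#' deterministic sign convention: in each loading vector the entry of
#' largest magnitude is positive.
#'
#' @param data Tibble of samples; peak columns (`GPx`) are used by default.
#' @param cols Columns to use; default all peak columns, or all numeric
#'   non-id columns if no peak columns are present.
#' @param standardize Scale variables to unit SD (correlation PCA)?
#' @return A `glycan_pca` object: centering/scaling vectors, orthonormal
#'   loadings, explained-variance fractions and per-sample scores.
#' @export
fit_pca <- function(data, cols = NULL, standardize = TRUE) {
  if (is.null(cols)) {
    cols <- peak_cols(data)
    if (!length(cols)) {
      cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      "sample_id")
    }
  }
  if (length(cols) < 2 || nrow(data) < 2) {
    rlang::abort("Need at least 2 samples and 2 variables.")
  }
  mat <- as.matrix(data[cols])
  if (standardize) {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      rlang::abort(paste0("Zero-variance variable(s): ",
                          paste(cols[sds == 0], collapse = ", ")))
    }
  }
  pr <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  # deterministic signs: largest-magnitude loading positive
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  scores <- tibble::as_tibble(pr$x)
  if ("sample_id" %in% names(data)) {
    scores <- dplyr::bind_cols(data["sample_id"], scores)
  }
  structure(list(
    vars = cols,
    center = pr$center,
    scale = if (standardize) pr$scale else NULL,
    rotation = pr$rotation,
    sdev = pr$sdev,
    explained = pr$sdev^2 / sum(pr$sdev^2),
    scores = scores,
    standardize = standardize,
    n = nrow(mat)
  ), class = "glycan_pca")
}

#' @export
print.glycan_pca <- function(x, ...) {
  cat(sprintf("PCA of %d variables, %d samples; PC1-PC3 explain %.1f%%\n",
              length(x$vars), x$n,
              100 * sum(x$explained[seq_len(min(3, length(x$explained)))])))
  invisible(x)
}

#' Project new samples into a fitted PCA and assign to the nearest group
#'
#' Standardizes new samples with the model's means/SDs, projects them onto
#' the first `k` components and assigns each to the group whose centroid (in
#' the k-dimensional score space of the labelled training samples) is
#' nearest in Euclidean distance. Distances to every group centroid are
#' reported.
#'
#' @param model A [fit_pca()] result.
#' @param newdata Tibble (or named vector) with all model variables.
#' @param groups Group labels of the training samples, either a vector
#'   aligned with the model's score rows or a data frame with `sample_id`
#'   and `group`.
#' @param k Number of components used for the assignment (default 3).
#' @return Tibble with the projected scores, the assigned group and one
#'   `dist_<group>` column per group.
#' @export
project_and_assign <- function(model, newdata, groups, k = 3) {
  stopifnot(inherits(model, "glycan_pca"))
  if (k > ncol(model$rotation) || k < 1) {
    rlang::abort(sprintf("k must be between 1 and %d.", ncol(model$rotation)))
  }
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- tibble::as_tibble(as.list(newdata))
  }
  missing <- setdiff(model$vars, names(newdata))
  if (length(missing)) {
    rlang::abort(paste0("Missing variable(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(newdata[model$vars])
  x <- sweep(x, 2, model$center)
  if (!is.null(model$scale)) x <- sweep(x, 2, model$scale, "/")
  proj <- x %*% model$rotation[, seq_len(k), drop = FALSE]

  train <- as.matrix(model$scores[paste0("PC", seq_len(k))])
  if (is.data.frame(groups)) {
    lab <- groups$group[match(model$scores$sample_id, groups$sample_id)]
  } else {
    lab <- groups
  }
  if (length(lab) != nrow(train) || anyNA(lab)) {
    rlang::abort("groups must label every training sample.")
  }
  cent <- do.call(rbind, lapply(split(seq_along(lab), lab), function(ii)
    colMeans(train[ii, , drop = FALSE])))
  dists <- apply(cent, 1, function(cc)
    sqrt(rowSums(sweep(proj, 2, cc)^2)))
  dists <- matrix(dists, nrow = nrow(proj),
                  dimnames = list(NULL, rownames(cent)))
  out <- tibble::as_tibble(proj)
  if ("sample_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(newdata["sample_id"], out)
  }
  out$assigned <- rownames(cent)[apply(dists, 1, which.min)]
  for (g in rownames(cent)) out[[paste0("dist_", g)]] <- dists[, g]
  out
}
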