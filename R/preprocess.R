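#' @title Stage tag of a peak table
#' @description Peak tables carry a stage tag (`"raw"`, `"normalized"`,
#'   `"log"`, `"batch_corrected"`) as an attribute so downstream operations
#'   know which scale the values are on.
#' @param data A peak table.
#' @return The stage string, or `NULL` if untagged.
#' @export
peak_stage <- function(data) attr(data, "glycan_stage", exact = TRUE)

#' @rdname peak_stage
#' @param value Stage string to set.
#' @export
`peak_stage<-` <- function(data, value) {
  attr(data, "glycan_stage") <- value
  data
}

#' Total-area normalization of a glycan peak table
#'
#' Expresses every peak as a percentage of the total integrated area of its
#' chromatogram: each value becomes `100 * x / sum(x)` within the row. The
#' operation is idempotent.
#'
#' @param data A peak table (tibble with `GPx` columns; other columns pass
#'   through untouched).
#' @param on_nonpositive What to do with a nonpositive single peak value:
#'   `"reject"` (default, error naming the sample) or `"floor"` (replace with
#'   half the smallest positive value observed in that peak column).
#' @return The normalized table, stage `"normalized"`; rows sum to 100.
#' @export
normalize_total_area <- function(data, on_nonpositive = c("reject", "floor")) {
  on_nonpositive <- match.arg(on_nonpositive)
  pk <- peak_cols(data)
  if (!length(pk)) rlang::abort("No GP peak columns found.")
  mat <- as.matrix(data[pk])
  ids <- if ("sample_id" %in% names(data)) data$sample_id else seq_len(nrow(mat))

  if (any(mat <= 0, na.rm = TRUE)) {
    if (on_nonpositive == "reject") {
      bad <- ids[apply(mat <= 0, 1, any)]
      rlang::abort(paste0(
        "Nonpositive peak value(s) in sample(s): ",
        paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    for (j in seq_len(ncol(mat))) {
      nonpos <- mat[, j] <= 0
      if (any(nonpos)) {
        pos <- mat[, j][mat[, j] > 0]
        if (!length(pos)) {
          rlang::abort(paste0("Peak ", pk[j], " has no positive values."))
        }
        mat[nonpos, j] <- min(pos) / 2
      }
    }
  }
  tot <- rowSums(mat)
  if (any(tot <= 0)) {
    bad <- ids[tot <= 0]
    rlang::abort(paste0(
      "Nonpositive row total in sample(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  out <- data
  out[pk] <- mat * (100 / tot)
  peak_stage(out) <- "normalized"
  out
}

#' Natural-log transform of a peak table
#'
#' Glycan percentages are right-skewed and plate effects act multiplicatively,
#' so batch correction operates on the natural-log scale.
#'
#' @param data A peak table with strictly positive peak values.
#' @return The table with `log()` applied to peak columns, stage `"log"`.
#' @export
log_transform_peaks <- function(data) {
  pk <- peak_cols(data)
  mat <- as.matrix(data[pk])
  if (any(mat <= 0, na.rm = TRUE)) {
    rlang::abort("Log transform requires strictly positive peak values.")
  }
  out <- data
  out[pk] <- log(mat)
  peak_stage(out) <- "log"
  out
}

#' Return a corrected (log-scale) peak table to the percentage scale
#'
#' Exponentiates the peak columns of a `"log"` or `"batch_corrected"` table
#' elementwise, tagging the result `"normalized"`. Corrected values no
#' longer sum to exactly 100 (the correction acts per peak), which is
#' expected.
#'
#' @param data A peak table at stage `"log"` or `"batch_corrected"`.
#' @return The table on the percentage scale.
#' @export
as_percent_scale <- function(data) {
  stage <- peak_stage(data)
  if (is.null(stage) || !stage %in% c("log", "batch_corrected")) {
    rlang::abort("as_percent_scale expects a log-scale peak table.")
  }
  pk <- peak_cols(data)
  out <- data
  out[pk] <- exp(as.matrix(data[pk]))
  peak_stage(out) <- "normalized"
  attr(out, "batch_model") <- attr(data, "batch_model", exact = TRUE)
  out
}

#' Rank-based inverse-normal transformation
#'
#' Maps values through their (average, for ties) ranks to standard-normal
#' quantiles: `qnorm((rank - offset) / (n - 2 * offset + 1))`. With the
#' default `offset = 0.5` this is `qnorm((rank - 0.5) / n)`, giving a vector
#' with mean ~0 and SD ~1; `offset = 3/8` gives the Blom variant. The result
#' is invariant under any strictly increasing transform of the input.
#'
#' @param x Numeric vector with at least 3 non-missing values, not all equal.
#' @param offset Rank offset c in `(rank - c) / (n - 2c + 1)`.
#' @return Numeric vector of the same length; `NA`s are preserved.
#' @export
rank_inverse_normal <- function(x, offset = 0.5) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) rlang::abort("Need at least 3 non-missing values.")
  if (length(unique(x[ok])) == 1L) {
    rlang::abort("All values identical: ranks are degenerate.")
  }
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}
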