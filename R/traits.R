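#' Names of the 24 UHPLC glycan peaks
#'
#' IgG N-glycan chromatograms are integrated into 24 peaks, GP1 to GP24, each
#' expressed as a percentage of the total integrated area.
#'
#' @return Character vector `c("GP1", ..., "GP24")`.
#' @export
glycan_peak_names <- function() paste0("GP", 1:24)

#' Derived-trait peak membership
#'
#' Each derived IgG glycosylation trait is the sum of the glycan peaks that
#' share a structural feature:
#' * `G0` - glycans without galactose: GP1, GP2, GP3, GP4, GP6
#' * `G1` - glycans with one galactose: GP7-GP11
#' * `G2` - glycans with two galactoses: GP12-GP15
#' * `S`  - glycans with sialic acid(s): GP16-GP19, GP22, GP23, GP24
#' * `F`  - glycans with core fucose (14 peaks)
#' * `B`  - glycans with bisecting GlcNAc (9 peaks)
#'
#' GP5, GP20 and GP21 appear in no formula; GP20/GP21 are conventionally
#' excluded from analysis before traits are computed (see [exclude_peaks()]).
#'
#' @return Named list of character vectors of peak names.
#' @export
trait_formulas <- function() {
  gp <- function(i) paste0("GP", i)
  list(
    G0 = gp(c(1, 2, 3, 4, 6)),
    G1 = gp(7:11),
    G2 = gp(12:15),
    S  = gp(c(16, 17, 18, 19, 22, 23, 24)),
    F  = gp(c(1, 4, 6, 8, 9, 10, 11, 14, 15, 16, 18, 19, 23, 24)),
    B  = gp(c(3, 6, 10, 11, 13, 15, 19, 22, 24))
  )
}

# peak columns present in a table, in GP-number order
peak_cols <- function(data) {
  nm <- names(data)[grepl("^GP[0-9]+$", names(data))]
  nm[order(as.integer(sub("^GP", "", nm)))]
}

#' Drop glycan peaks from a peak table
#'
#' Removes peak columns (by default GP20 and GP21, which co-elute on some
#' plates and are therefore dropped from analysis and from derived-trait
#' calculation). No renormalization is performed: remaining values keep their
#' original percentage scale.
#'
#' @param data A peak table (tibble with `GPx` columns).
#' @param exclude Character vector of peak names to drop.
#' @return The table without the excluded columns; the stage tag is kept.
#' @export
exclude_peaks <- function(data, exclude = c("GP20", "GP21")) {
  pk <- peak_cols(data)
  if (length(exclude)) {
    unknown <- setdiff(exclude, pk)
    if (length(unknown)) {
      rlang::abort(paste0(
        "Unknown peak name(s): ", paste(unknown, collapse = ", ")
      ))
    }
  }
  keep <- setdiff(pk, exclude)
  if (!length(keep)) {
    rlang::abort("Excluding all peaks leaves no measured glycan variables.")
  }
  out <- dplyr::select(data, -dplyr::all_of(exclude))
  rlang::inform(sprintf(
    "peak exclusion: %d -> %d peak columns", length(pk), length(keep)
  ))
  peak_stage(out) <- peak_stage(data)
  out
}

#' Compute derived IgG glycosylation traits
#'
#' Sums glycan peak percentages into the six derived traits (G0, G1, G2, S,
#' F, B) using the standard formulas (see [trait_formulas()]). Tables on the
#' log scale (stage `"log"` or `"batch_corrected"`) are exponentiated back to
#' the percentage scale first, so that the sums remain dimensionally
#' meaningful.
#'
#' @param data A peak table containing all peak columns required by the
#'   formulas (GP20/GP21 are not required).
#' @return A tibble with `sample_id` (if present) and columns
#'   `G0, G1, G2, S, F, B` in percentage units.
#' @export
derived_traits <- function(data) {
  stage <- peak_stage(data)
  fml <- trait_formulas()
  needed <- unique(unlist(fml))
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    rlang::abort(paste0(
      "Missing required peak column(s): ", paste(missing, collapse = ", ")
    ))
  }
  mat <- as.matrix(data[needed])
  if (!is.null(stage) && stage %in% c("log", "batch_corrected")) {
    mat <- exp(mat)
  }
  out <- tibble::as_tibble(lapply(fml, function(members) {
    rowSums(mat[, members, drop = FALSE])
  }))
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(data["sample_id"], out)
  }
  attr(out, "glycan_stage") <- NULL
  out
}
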