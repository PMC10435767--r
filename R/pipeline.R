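#' Write / read a glycan peak table with its stage tag
#'
#' Plain CSV with the processing stage recorded in a `# stage:` header
#' comment line, so re-read tables know which scale they are on.
#'
#' @param data A peak table.
#' @param path File path.
#' @return `write_peak_table()` returns `path` invisibly; `read_peak_table()`
#'   returns the tibble with its stage restored.
#' @export
write_peak_table <- function(data, path) {
  stage <- peak_stage(data) %||% "raw"
  readr::write_lines(paste0("# stage: ", stage), path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  stage <- if (grepl("^# stage: ", first)) sub("^# stage: ", "", first) else "raw"
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  peak_stage(out) <- stage
  out
}

# configuration schema: name -> allowed keys (NULL = leaf)
config_schema <- function() {
  list(
    simulate = c("cohorts", "children", "effect_size"),
    preprocess = c("excluded_peaks", "eb_covariates", "rank_offset"),
    associate = c("adjust", "traits"),
    clock = c("traits", "grid", "bootstrap_B"),
    classify = c("k", "on", "include_singleton_in_fit")
  )
}

#' Default end-to-end run configuration
#'
#' @return Nested list understood by [run_pipeline()]: simulation toggles,
#'   excluded peaks, batch-correction covariates, rank offset, analysis
#'   traits, shift grid/bootstrap settings and the PCA assignment settings.
#' @export
default_run_config <- function() {
  list(
    simulate = list(cohorts = "default", children = TRUE, effect_size = NULL),
    preprocess = list(excluded_peaks = c("GP20", "GP21"),
                      eb_covariates = c("group", "age", "sex"),
                      rank_offset = 0.5),
    associate = list(adjust = c("age", "sex"),
                     traits = c("G0", "G1", "G2", "S", "F", "B")),
    clock = list(traits = c("G0", "G2"), grid = NULL, bootstrap_B = 0),
    classify = list(k = 3, on = "peaks", include_singleton_in_fit = FALSE)
  )
}

#' Validate a run configuration
#'
#' Checks the configuration against the schema before any computation:
#' unknown sections or keys are rejected and basic types are enforced.
#'
#' @param config Nested configuration list.
#' @return The validated configuration (with defaults filled in), invisibly
#'   usable by [run_pipeline()].
#' @export
validate_run_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    rlang::abort(paste0("Unknown config section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad)) {
      rlang::abort(paste0("Unknown key(s) in '", sec, "': ",
                          paste(bad, collapse = ", ")))
    }
  }
  out <- default_run_config()
  for (sec in names(config)) out[[sec]][names(config[[sec]])] <- config[[sec]]
  if (!is.numeric(out$preprocess$rank_offset) ||
      out$preprocess$rank_offset < 0 || out$preprocess$rank_offset >= 1) {
    rlang::abort("rank_offset must lie in [0, 1).")
  }
  if (!is.numeric(out$classify$k) || out$classify$k < 1) {
    rlang::abort("classify$k must be a positive integer.")
  }
  if (!is.numeric(out$clock$bootstrap_B) || out$clock$bootstrap_B < 0) {
    rlang::abort("clock$bootstrap_B must be nonnegative.")
  }
  out
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such config file: ", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    rlang::abort("Config must be a .yaml/.yml or .json file.")
  }
  validate_run_config(cfg)
}

#' Run the full glycan-clock pipeline on simulated cohorts
#'
#' Chains every stage: simulate the adult cohorts (and children), total-area
#' normalization, log transform, empirical-Bayes plate correction, peak
#' exclusion, derived traits, per-cohort rank-INT association models with
#' fixed-effects pooling and BH adjustment, per-cohort age trends and the
#' combined glycan-age shifts, and PCA placement of the
#' segmental-duplication child. Optionally writes all stage outputs plus a
#' machine-readable run manifest.
#'
#' @param config Configuration list (see [default_run_config()]); validated
#'   before any computation.
#' @param seed Integer master seed for every source of randomness.
#' @param out_dir Optional output directory for CSV artifacts and
#'   `manifest.json`.
#' @return A `glycan_run` list: `summary` (one-row tibble with the combined
#'   shifts and the singleton assignment), `association`, `clock` (per
#'   trait), `classification`, `study`, `children`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), seed, out_dir = NULL) {
  config <- validate_run_config(config)
  rlang::inform(sprintf("stage simulate: seed %d", seed))
  study <- simulate_study(seed = substream_seed(seed, 1),
                          effect_size = config$simulate$effect_size)
  rlang::inform(sprintf("stage simulate: %d adult samples", nrow(study$peaks)))

  corrected <- study$peaks |>
    normalize_total_area() |>
    log_transform_peaks() |>
    batch_correct(study$meta, preserve = config$preprocess$eb_covariates) |>
    exclude_peaks(config$preprocess$excluded_peaks)
  traits <- derived_traits(corrected)
  rlang::inform(sprintf("stage preprocess: %d samples x %d traits",
                        nrow(traits), ncol(traits) - 1))

  assoc <- associate_cohorts(traits, study$meta,
                             which_traits = config$associate$traits,
                             adjust = config$associate$adjust,
                             rank_offset = config$preprocess$rank_offset)

  clock_data <- dplyr::inner_join(traits, study$meta, by = "sample_id")
  if ("subcohort" %in% names(clock_data)) {
    clock_data <- dplyr::filter(clock_data, .data$subcohort == "main")
  }
  clocks <- lapply(config$clock$traits, function(tr) {
    clock_analysis(clock_data, tr, grid = config$clock$grid,
                   bootstrap_B = config$clock$bootstrap_B,
                   seed = substream_seed(seed, 3))
  })
  names(clocks) <- config$clock$traits
  for (tr in names(clocks)) {
    rlang::inform(sprintf("stage clock: combined %s shift %.1f years",
                          tr, clocks[[tr]]$combined))
  }

  children <- NULL
  classification <- NULL
  if (isTRUE(config$simulate$children)) {
    children <- simulate_children(seed = substream_seed(seed, 2))
    norm <- children$peaks |>
      normalize_total_area() |>
      log_transform_peaks() |>
      batch_correct(children$meta,
                    preserve = config$preprocess$eb_covariates) |>
      as_percent_scale()
    dat <- if (config$classify$on == "traits") derived_traits(norm) else norm
    is_singleton <- children$meta$group == "segmental"
    fit_rows <- if (config$classify$include_singleton_in_fit) {
      rep(TRUE, nrow(dat))
    } else {
      !is_singleton
    }
    pca <- fit_pca(dat[fit_rows, , drop = FALSE])
    groups <- children$meta$group[fit_rows]
    if (any(is_singleton)) {
      classification <- project_and_assign(
        pca, dat[is_singleton, , drop = FALSE], groups, k = config$classify$k)
      rlang::inform(sprintf("stage classify: singleton assigned to %s",
                            classification$assigned[1]))
    }
    classification <- list(pca = pca, groups = groups,
                           singleton = classification)
  }

  summary <- tibble::tibble(
    seed = seed,
    n_samples = nrow(study$peaks),
    combined_shift_G0 = if ("G0" %in% names(clocks)) clocks$G0$combined else NA_real_,
    combined_shift_G2 = if ("G2" %in% names(clocks)) clocks$G2$combined else NA_real_,
    singleton_assigned = if (!is.null(classification$singleton)) {
      classification$singleton$assigned[1]
    } else NA_character_
  )

  manifest <- list(
    package = "glycanclock",
    version = as.character(utils::packageVersion("glycanclock")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    n_samples = nrow(study$peaks)
  )

  result <- structure(list(
    summary = summary, association = assoc, clock = clocks,
    classification = classification, study = study, children = children,
    manifest = manifest
  ), class = "glycan_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peak_table(study$peaks, file.path(out_dir, "peaks_raw.csv"))
    write_peak_table(corrected, file.path(out_dir, "peaks_corrected.csv"))
    readr::write_csv(study$meta, file.path(out_dir, "sample_meta.csv"))
    readr::write_csv(traits, file.path(out_dir, "derived_traits.csv"))
    readr::write_csv(assoc$by_cohort, file.path(out_dir, "effects_by_cohort.csv"))
    readr::write_csv(assoc$meta, file.path(out_dir, "effects_meta.csv"))
    readr::write_csv(dplyr::bind_rows(lapply(clocks, function(cl) cl$report)),
                     file.path(out_dir, "clock_report.csv"))
    readr::write_csv(dplyr::bind_rows(lapply(clocks, function(cl) cl$lines)),
                     file.path(out_dir, "clock_lines.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    truth <- lapply(study$truth, function(tt) list(
      raw_offsets = as.list(tt$raw_offsets), n_floored = tt$n_floored,
      seed = tt$seed))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  result
}

#' @export
print.glycan_run <- function(x, ...) {
  cat("Glycan-clock pipeline run\n")
  print(x$summary)
  invisible(x)
}
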