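# deterministic sub-stream seeds derived from one master seed
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 1000003) %% 2147483629)
}

#' Specify a case-control cohort for simulation
#'
#' @param name Cohort label (used to prefix sample ids).
#' @param n_control,n_ds Numbers of control and DS (trisomy 21) subjects.
#' @param age_range_control,age_range_ds Age ranges in years, `c(min, max)`.
#' @param sex_ratio Fraction of female subjects.
#' @param n_plates Number of 96-well plates samples are randomised across.
#' @param sibling_pairs Number of DS/euploid sibling pairs generated as a
#'   separate `subcohort = "sibling"` block sharing family ids.
#' @param sibling_age_range_ds,sibling_age_range_control Age ranges for the
#'   sibling block.
#' @param comorbidity_rates Named probabilities of co-morbidity flags among
#'   DS subjects (`dementia`, `thyroid`, `autoimmune`, `infection`).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(name, n_control, n_ds,
                        age_range_control, age_range_ds,
                        sex_ratio = 0.5, n_plates = 7, sibling_pairs = 0,
                        sibling_age_range_ds = c(10, 58),
                        sibling_age_range_control = c(9, 52),
                        comorbidity_rates = c(dementia = 0, thyroid = 0,
                                              autoimmune = 0, infection = 0)) {
  stopifnot(n_control >= 0, n_ds >= 0, sibling_pairs >= 0, n_plates >= 1)
  for (r in list(age_range_control, age_range_ds)) {
    if (length(r) != 2 || diff(r) <= 0) {
      rlang::abort("Age ranges must be c(min, max) with positive width.")
    }
  }
  if (sex_ratio < 0 || sex_ratio > 1 ||
      any(comorbidity_rates < 0) || any(comorbidity_rates > 1)) {
    rlang::abort("Probabilities must lie in [0, 1].")
  }
  structure(list(
    name = name, n_control = n_control, n_ds = n_ds,
    age_range_control = age_range_control, age_range_ds = age_range_ds,
    sex_ratio = sex_ratio, n_plates = n_plates,
    sibling_pairs = sibling_pairs,
    sibling_age_range_ds = sibling_age_range_ds,
    sibling_age_range_control = sibling_age_range_control,
    comorbidity_rates = comorbidity_rates
  ), class = "cohort_spec")
}

#' Default cohort specifications for the three adult study populations
#'
#' Sizes, age ranges, sex ratios and co-morbidity fractions parameterise the
#' French (FRA), Italian (ITA) and UK cohorts; the Italian cohort carries a
#' 35-pair sibling sub-cohort.
#'
#' @return Named list of [cohort_spec()] objects (`FRA`, `ITA`, `UK`).
#' @export
default_cohort_specs <- function() {
  list(
    FRA = cohort_spec("FRA", n_control = 109, n_ds = 98,
                      age_range_control = c(22, 67), age_range_ds = c(30, 67),
                      sex_ratio = 0.507,
                      comorbidity_rates = c(dementia = 0.20, thyroid = 0.23,
                                            autoimmune = 0.35, infection = 0.15)),
    ITA = cohort_spec("ITA", n_control = 53, n_ds = 57,
                      age_range_control = c(22, 66), age_range_ds = c(22, 66),
                      sex_ratio = 0.445, sibling_pairs = 35,
                      comorbidity_rates = c(dementia = 0, thyroid = 0.43,
                                            autoimmune = 0.39, infection = 0.29)),
    UK = cohort_spec("UK", n_control = 42, n_ds = 53,
                     age_range_control = c(22, 82), age_range_ds = c(22, 73),
                     sex_ratio = 0.41,
                     comorbidity_rates = c(dementia = 0.25, thyroid = 0.46,
                                           autoimmune = 0.48, infection = 0.15))
  )
}

#' Linear age-trend parameters for the generator
#'
#' The generator controls the latent means of G0, G1 and G2 as straight lines
#' in age per group; the sialylation trait S absorbs the compositional
#' remainder so that rows close to 100 exactly. Noise is additive Gaussian on
#' the latent traits (biological variation), with additional small lognormal
#' multiplicative noise per peak and a lognormal multiplicative plate effect.
#'
#' @param trends Tibble with columns `trait` (`G0`/`G1`/`G2`), `group`
#'   (`control`/`DS`), `slope` (% per year) and `intercept` (%).
#' @param noise_sd Named per-trait SD (% units) of latent trait noise.
#' @param batch_sd Log-scale SD of per-plate multiplicative effects.
#' @param peak_noise_sd Log-scale SD of per-peak multiplicative noise.
#' @param family_sd SD (% units) of the shared family random intercept for
#'   sibling pairs.
#' @param fixed_fractions Constant percentages given to peaks outside the
#'   trait formulas (GP5) and to the downstream-excluded GP20/GP21.
#' @return A `trend_params` object.
#' @export
trend_params <- function(trends,
                         noise_sd = c(G0 = 4.0, G1 = 3.5, G2 = 3.5),
                         batch_sd = 0.05, peak_noise_sd = 0.05,
                         family_sd = 2.0,
                         fixed_fractions = c(GP5 = 1, GP20 = 0.5, GP21 = 0.5)) {
  stopifnot(all(c("trait", "group", "slope", "intercept") %in% names(trends)))
  need <- expand.grid(trait = c("G0", "G1", "G2"),
                      group = c("control", "DS"), stringsAsFactors = FALSE)
  have <- paste(trends$trait, trends$group)
  if (!all(paste(need$trait, need$group) %in% have)) {
    rlang::abort("trends must define G0, G1 and G2 lines for both groups.")
  }
  if (sum(fixed_fractions) >= 100) {
    rlang::abort("Fixed peak fractions must sum to less than 100.")
  }
  if (any(noise_sd < 0) || batch_sd < 0 || peak_noise_sd < 0 || family_sd < 0) {
    rlang::abort("Noise SDs must be nonnegative.")
  }
  structure(list(
    trends = tibble::as_tibble(trends),
    noise_sd = noise_sd, batch_sd = batch_sd,
    peak_noise_sd = peak_noise_sd, family_sd = family_sd,
    fixed_fractions = fixed_fractions
  ), class = "trend_params")
}

#' Default trend parameters per adult cohort
#'
#' G0 and G2 lines are the fitted trendline coefficients of the three adult
#' study populations (per group); the G1 line (slope -0.05, intercepts
#' 38/37.2) is a package default chosen so the composition stays feasible and
#' the implied pooled G1 group effect is small and negative.
#'
#' @param cohort `"FRA"`, `"ITA"` or `"UK"`.
#' @param ... Passed to [trend_params()] (noise and plate-effect settings).
#' @return A `trend_params` object.
#' @export
default_trend_params <- function(cohort = c("FRA", "ITA", "UK"), ...) {
  cohort <- match.arg(cohort)
  lines <- list(
    FRA = list(G0 = list(control = c(0.43, 6.72),  DS = c(0.44, 11.42)),
               G2 = list(control = c(-0.22, 28.25), DS = c(-0.25, 25.96))),
    ITA = list(G0 = list(control = c(0.26, 13.74), DS = c(0.33, 15.96)),
               G2 = list(control = c(-0.17, 26.04), DS = c(-0.18, 23.23))),
    UK  = list(G0 = list(control = c(0.29, 11.63), DS = c(0.40, 14.92)),
               G2 = list(control = c(-0.18, 26.79), DS = c(-0.20, 23.22)))
  )[[cohort]]
  g1 <- list(control = c(-0.05, 38), DS = c(-0.05, 37.2))
  rows <- purrr::imap_dfr(
    list(G0 = lines$G0, G1 = g1, G2 = lines$G2),
    function(groups, trait) {
      purrr::imap_dfr(groups, function(ab, grp) {
        tibble::tibble(trait = trait, group = grp,
                       slope = ab[1], intercept = ab[2])
      })
    }
  )
  trend_params(rows, ...)
}

#' Peak-split weights
#'
#' How each controlled trait total is distributed over its member peaks.
#' These weights are artifact defaults shaped like a typical adult IgG
#' glycome (e.g. the agalactosylated core-fucosylated biantennary peak GP4
#' dominates G0), not estimates from any real cohort.
#'
#' @param weights Optional tibble `trait`, `peak`, `weight` to override the
#'   defaults. Member sets must match [trait_formulas()] exactly for the
#'   directly split groups (G0, G1, G2, S); weights must be nonnegative and
#'   sum to 1 within each trait.
#' @return A tibble of class `peak_split_weights`.
#' @export
peak_split_weights <- function(weights = NULL) {
  if (is.null(weights)) {
    weights <- tibble::tribble(
      ~trait, ~peak,  ~weight,
      "G0",   "GP1",  0.08,
      "G0",   "GP2",  0.10,
      "G0",   "GP3",  0.03,
      "G0",   "GP4",  0.70,
      "G0",   "GP6",  0.09,
      "G1",   "GP7",  0.05,
      "G1",   "GP8",  0.45,
      "G1",   "GP9",  0.25,
      "G1",   "GP10", 0.15,
      "G1",   "GP11", 0.10,
      "G2",   "GP12", 0.05,
      "G2",   "GP13", 0.08,
      "G2",   "GP14", 0.75,
      "G2",   "GP15", 0.12,
      "S",    "GP16", 0.20,
      "S",    "GP17", 0.05,
      "S",    "GP18", 0.55,
      "S",    "GP19", 0.05,
      "S",    "GP22", 0.02,
      "S",    "GP23", 0.08,
      "S",    "GP24", 0.05
    )
  }
  weights <- tibble::as_tibble(weights)
  fml <- trait_formulas()[c("G0", "G1", "G2", "S")]
  for (tr in names(fml)) {
    w <- weights[weights$trait == tr, ]
    if (!setequal(w$peak, fml[[tr]])) {
      rlang::abort(paste0("Peak members for ", tr,
                          " must match the trait formula exactly."))
    }
    if (any(w$weight < 0) || abs(sum(w$weight) - 1) > 1e-8) {
      rlang::abort(paste0("Weights for ", tr,
                          " must be nonnegative and sum to 1."))
    }
  }
  class(weights) <- c("peak_split_weights", class(weights))
  weights
}

#' Calibrate a raw group offset to a target standardized effect
#'
#' Finds the raw (% scale) DS offset `d` such that the group coefficient of
#' a linear model of the rank-inverse-normal transformed values on group,
#' age and sex equals `target` (rank-INT SD units) on the supplied latent
#' sample. Root-finding on the realized sample accounts exactly for the
#' nonlinearity (compression of large separations) of the rank-INT map.
#'
#' @param y0 Latent trait values without any group offset.
#' @param ds Logical (or 0/1) case indicator.
#' @param age,sex Covariates entering the analysis model.
#' @param target Target standardized group effect (may be negative).
#' @param offset Rank offset passed to [rank_inverse_normal()].
#' @return The raw offset `d` in % units.
#' @export
calibrate_group_offset <- function(y0, ds, age, sex, target, offset = 0.5) {
  if (target == 0) return(0)
  ds <- as.numeric(ds)
  df <- data.frame(ds = ds, age = age, sex = sex)
  covs <- c("ds", names(df)[-1][vapply(df[-1], function(v)
    length(unique(v)) > 1, logical(1))])
  f <- function(d) {
    z <- rank_inverse_normal(y0 + d * ds, offset = offset)
    fit <- stats::lm(stats::reformulate(covs, response = "z"),
                     data = cbind(df, z = z))
    unname(stats::coef(fit)["ds"]) - target
  }
  up <- 10 * stats::sd(y0) * sign(target)
  lo <- min(0, up); hi <- max(0, up)
  for (k in 1:4) {
    flo <- f(lo); fhi <- f(hi)
    if (sign(flo) != sign(fhi)) break
    if (k == 4) {
      rlang::abort("Target standardized effect is not attainable on this sample.")
    }
    if (target > 0) hi <- hi * 2 else lo <- lo * 2
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-5)$root
}

# closure check on the per-subject trait means; names the age where it breaks
check_closure <- function(mu_mat, fixed_sum, meta) {
  tot <- rowSums(mu_mat) + fixed_sum
  bad <- tot >= 100 | apply(mu_mat <= 0, 1, any)
  if (any(bad)) {
    i <- which(bad)[which.max(tot[bad])]
    rlang::abort(sprintf(
      "Infeasible composition: for group %s at age %.2f the trait means (%s) plus %.1f%% fixed fractions leave no room for the S closure buffer.",
      meta$group[i], meta$age[i],
      paste(sprintf("%.1f", mu_mat[i, ]), collapse = "/"), fixed_sum
    ))
  }
  invisible(TRUE)
}

# core generator: peaks + ground truth from a metadata frame
simulate_peaks_from_meta <- function(meta, trends, weights, effect_size, seed) {
  tr <- trends$trends
  traits <- c("G0", "G1", "G2")
  fixed <- trends$fixed_fractions
  n <- nrow(meta)
  ds <- meta$group != "control"

  set.seed(substream_seed(seed, 101))
  fam_ids <- unique(stats::na.omit(meta$family_id))
  fam_eff <- matrix(0, length(fam_ids), 3,
                    dimnames = list(fam_ids, traits))
  if (length(fam_ids) && trends$family_sd > 0) {
    fam_eff[] <- stats::rnorm(length(fam_eff), 0, trends$family_sd)
  }

  latent <- matrix(0, n, 3, dimnames = list(NULL, traits))
  mu_mat <- matrix(0, n, 3, dimnames = list(NULL, traits))
  noise <- matrix(0, n, 3, dimnames = list(NULL, traits))
  for (j in seq_along(traits)) {
    noise[, j] <- stats::rnorm(n, 0, trends$noise_sd[[traits[j]]])
  }
  offsets <- stats::setNames(numeric(3), traits)
  for (j in seq_along(traits)) {
    t_j <- traits[j]
    line <- function(grp) {
      row <- tr[tr$trait == t_j & tr$group == grp, ]
      row$slope * meta$age + row$intercept
    }
    fam_part <- ifelse(is.na(meta$family_id), 0,
                       fam_eff[match(meta$family_id, fam_ids), j])
    if (!is.null(effect_size) && t_j %in% names(effect_size)) {
      y0 <- line("control") + fam_part + noise[, j]
      d <- calibrate_group_offset(y0, ds, meta$age, meta$sex,
                                  effect_size[[t_j]])
      mu_mat[, j] <- line("control") + d * ds
      latent[, j] <- y0 + d * ds
      offsets[t_j] <- d
    } else {
      mu <- ifelse(ds, line("DS"), line("control"))
      mu_mat[, j] <- mu
      latent[, j] <- mu + fam_part + noise[, j]
      offsets[t_j] <- NA_real_
    }
  }

  # feasibility of the configured mean composition at every observed age
  check_closure(mu_mat, sum(fixed), meta)

  n_floored <- sum(latent < 0.5)
  latent[latent < 0.5] <- 0.5
  s_latent <- 100 - sum(fixed) - rowSums(latent)
  n_floored <- n_floored + sum(s_latent < 0.5)
  s_latent[s_latent < 0.5] <- 0.5

  totals <- cbind(latent, S = s_latent)
  peak_names <- glycan_peak_names()
  base <- matrix(0, n, 24, dimnames = list(NULL, peak_names))
  for (tg in c("G0", "G1", "G2", "S")) {
    w <- weights[weights$trait == tg, ]
    base[, w$peak] <- outer(totals[, tg], w$weight)
  }
  for (pkn in names(fixed)) base[, pkn] <- fixed[[pkn]]

  set.seed(substream_seed(seed, 102))
  plate_levels <- sort(unique(meta$plate))
  plate_eff <- matrix(0, length(plate_levels), 24,
                      dimnames = list(plate_levels, peak_names))
  if (trends$batch_sd > 0) {
    plate_eff[] <- stats::rnorm(length(plate_eff), 0, trends$batch_sd)
  }
  eps <- matrix(0, n, 24)
  if (trends$peak_noise_sd > 0) {
    eps[] <- stats::rnorm(length(eps), 0, trends$peak_noise_sd)
  }
  peaks <- base * exp(eps + plate_eff[match(meta$plate, plate_levels), ,
                                      drop = FALSE])
  peaks <- peaks * (100 / rowSums(peaks))

  out <- dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                          tibble::as_tibble(peaks))
  peak_stage(out) <- "raw"
  truth <- list(
    trends = trends, weights = weights,
    effect_size = effect_size, raw_offsets = offsets,
    plate_effects = plate_eff, family_effects = fam_eff,
    n_floored = n_floored, seed = seed
  )
  list(peaks = out, truth = truth)
}

#' Simulate a case-control glycan cohort
#'
#' Generates one row per subject: latent G0/G1/G2 means follow the configured
#' linear age trends per group (S is the closure buffer), trait totals are
#' split over member peaks by the weights, lognormal plate effects and peak
#' noise are applied, and rows are renormalized to sum to 100. Metadata
#' carries the true group, age, sex, plate, family id and co-morbidity flags;
#' the ground-truth parameter set is returned alongside the output.
#'
#' @param spec A [cohort_spec()].
#' @param trends A [trend_params()]; defaults to the cohort's
#'   [default_trend_params()] (FRA parameters for unknown cohort names).
#' @param weights [peak_split_weights()].
#' @param seed Integer master seed; identical inputs and seed give identical
#'   output. All sub-streams are derived from it.
#' @param effect_size Optional named vector of target standardized group
#'   effects (rank-INT SD units) per trait; when given for a trait, the DS
#'   group follows the control line plus a raw offset calibrated with
#'   [calibrate_group_offset()] instead of its own configured line.
#' @return A `cohort_sim` list with elements `peaks` (tibble, stage
#'   `"raw"`), `meta` (tibble) and `truth` (ground-truth parameters).
#' @export
simulate_cohort <- function(spec, trends = NULL,
                            weights = peak_split_weights(), seed,
                            effect_size = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(trends)) {
    trends <- if (spec$name %in% c("FRA", "ITA", "UK")) {
      default_trend_params(spec$name)
    } else {
      default_trend_params("FRA")
    }
  }
  set.seed(substream_seed(seed, 1))
  n_main <- spec$n_control + spec$n_ds
  main <- tibble::tibble(
    group = rep(c("control", "DS"), c(spec$n_control, spec$n_ds)),
    age = c(stats::runif(spec$n_control, spec$age_range_control[1],
                         spec$age_range_control[2]),
            stats::runif(spec$n_ds, spec$age_range_ds[1],
                         spec$age_range_ds[2])),
    subcohort = "main",
    family_id = NA_character_
  )
  sib <- NULL
  if (spec$sibling_pairs > 0) {
    fam <- paste0(spec$name, "_fam", sprintf("%03d", seq_len(spec$sibling_pairs)))
    sib <- tibble::tibble(
      group = rep(c("DS", "control"), spec$sibling_pairs),
      age = as.vector(rbind(
        stats::runif(spec$sibling_pairs, spec$sibling_age_range_ds[1],
                     spec$sibling_age_range_ds[2]),
        stats::runif(spec$sibling_pairs, spec$sibling_age_range_control[1],
                     spec$sibling_age_range_control[2])
      )),
      subcohort = "sibling",
      family_id = rep(fam, each = 2)
    )
  }
  meta <- dplyr::bind_rows(main, sib)
  n <- nrow(meta)
  meta$sample_id <- paste0(spec$name, "_S", sprintf("%04d", seq_len(n)))
  meta$cohort <- spec$name
  meta$sex <- ifelse(stats::runif(n) < spec$sex_ratio, "F", "M")
  meta$plate <- sample(rep_len(seq_len(spec$n_plates), n))
  is_ds <- meta$group == "DS" & meta$subcohort == "main"
  for (flag in c("dementia", "thyroid", "autoimmune", "infection")) {
    rate <- spec$comorbidity_rates[[flag]]
    if (is.null(rate) || is.na(rate)) rate <- 0
    meta[[flag]] <- as.integer(is_ds & stats::runif(n) < rate)
  }
  meta <- dplyr::select(meta, "sample_id", "cohort", "group", "age", "sex",
                        "plate", "family_id", "subcohort",
                        "dementia", "thyroid", "autoimmune", "infection")

  sim <- simulate_peaks_from_meta(meta, trends, weights, effect_size, seed)
  structure(list(peaks = sim$peaks, meta = meta,
                 truth = c(sim$truth, list(spec = spec))),
            class = "cohort_sim")
}

#' Simulate the children cohort with an optional segmental-duplication child
#'
#' Children are modelled as a group comparison, not a trend: within the
#' narrow child age span the latent trait means are constant per group (the
#' adult age slopes are not extrapolated to toddlers), with the group gap
#' equal to the adult group-line difference at age 4 and a child-level noise
#' SD of 0.8% (toddlers' narrow age span and low environmental exposure make
#' their glycome much less variable than adults'). The case and control G0
#' ranges are then essentially disjoint and the groups form separated PCA
#' clusters, matching the reported childhood pattern. When `singleton = TRUE` one extra sample labelled `"segmental"`
#' is generated with DS-distribution trait values, emulating a child whose
#' duplication covers only a segment of chromosome 21.
#'
#' @param n_ds,n_control Numbers of DS and control children.
#' @param singleton Generate the extra segmental-duplication sample?
#' @param seed Integer master seed.
#' @param trends A [trend_params()]; default flat child lines derived from
#'   the adult FRA lines at age 4, child noise SD 0.8.
#' @param weights [peak_split_weights()].
#' @param age_range_ds,age_range_control Child age ranges in years.
#' @param singleton_age Age of the singleton sample.
#' @param effect_size Optional named target standardized effects (see
#'   [simulate_cohort()]); default `NULL` (group lines used directly).
#' @return A `cohort_sim` list (`peaks`, `meta`, `truth`).
#' @export
simulate_children <- function(n_ds = 38, n_control = 17, singleton = TRUE,
                              seed, trends = NULL,
                              weights = peak_split_weights(),
                              age_range_ds = c(0.58, 5.25),
                              age_range_control = c(3, 5),
                              singleton_age = 2,
                              effect_size = NULL) {
  if (n_ds < 0 || n_control < 0) rlang::abort("Counts must be nonnegative.")
  if (is.null(trends)) {
    adult <- default_trend_params("FRA")$trends
    flat <- dplyr::mutate(adult,
                          intercept = .data$intercept + .data$slope * 4,
                          slope = 0)
    trends <- trend_params(flat, noise_sd = c(G0 = 0.8, G1 = 0.8, G2 = 0.8))
  }
  set.seed(substream_seed(seed, 1))
  meta <- tibble::tibble(
    group = rep(c("DS", "control"), c(n_ds, n_control)),
    age = c(stats::runif(n_ds, age_range_ds[1], age_range_ds[2]),
            stats::runif(n_control, age_range_control[1], age_range_control[2]))
  )
  if (singleton) {
    meta <- dplyr::bind_rows(meta,
                             tibble::tibble(group = "segmental",
                                            age = singleton_age))
  }
  n <- nrow(meta)
  meta$sample_id <- paste0("CHILD_S", sprintf("%04d", seq_len(n)))
  meta$cohort <- "CHILD"
  meta$sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  meta$plate <- sample(rep_len(1:7, n))
  meta$family_id <- NA_character_
  meta$subcohort <- "main"
  for (flag in c("dementia", "thyroid", "autoimmune", "infection")) {
    meta[[flag]] <- 0L
  }
  meta <- dplyr::select(meta, "sample_id", "cohort", "group", "age", "sex",
                        "plate", "family_id", "subcohort",
                        "dementia", "thyroid", "autoimmune", "infection")
  sim <- simulate_peaks_from_meta(meta, trends, weights, effect_size, seed)
  structure(list(peaks = sim$peaks, meta = meta, truth = sim$truth),
            class = "cohort_sim")
}

#' Simulate the full multi-cohort study
#'
#' Runs [simulate_cohort()] for each specification under deterministically
#' derived sub-seeds and binds the results. Plate labels are shared across
#' cohorts, emulating samples from all cohorts being randomised over the
#' same collection plates.
#'
#' @param specs Named list of [cohort_spec()]s; default [default_cohort_specs()].
#' @param seed Integer master seed.
#' @param trends Optional named list of [trend_params()] per cohort.
#' @param weights [peak_split_weights()].
#' @param effect_size Optional named target standardized effects, applied in
#'   every cohort (see [simulate_cohort()]).
#' @return A `study_sim` list: `peaks` (all cohorts), `meta`, `truth` (one
#'   entry per cohort).
#' @export
simulate_study <- function(specs = default_cohort_specs(), seed,
                           trends = NULL, weights = peak_split_weights(),
                           effect_size = NULL) {
  sims <- purrr::imap(specs, function(spec, nm) {
    i <- match(nm, names(specs))
    simulate_cohort(spec,
                    trends = if (!is.null(trends)) trends[[nm]] else NULL,
                    weights = weights,
                    seed = substream_seed(seed, 10 + i),
                    effect_size = effect_size)
  })
  peaks <- dplyr::bind_rows(purrr::map(sims, "peaks"))
  peak_stage(peaks) <- "raw"
  structure(list(
    peaks = peaks,
    meta = dplyr::bind_rows(purrr::map(sims, "meta")),
    truth = purrr::map(sims, "truth")
  ), class = "study_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$peaks), "samples (",
      paste(names(table(x$meta$group)), table(x$meta$group),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.study_sim <- function(x, ...) {
  cat("Simulated study:", nrow(x$peaks), "samples in",
      length(unique(x$meta$cohort)), "cohort(s)\n")
  invisible(x)
}
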