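test_that("generated peak rows always close to 100", {
  for (seed in 1:3) {
    sim <- simulate_cohort(tiny_spec(20, 20), seed = seed)
    sums <- rowSums(sim$peaks[peak_cols(sim$peaks)])
    expect_true(all(abs(sums - 100) < 1e-9))
    expect_true(all(sim$peaks[peak_cols(sim$peaks)] > 0))
  }
})

test_that("the default FRA cohort reproduces the study size", {
  sim <- simulate_cohort(default_cohort_specs()$FRA, seed = 11)
  expect_equal(nrow(sim$peaks), 207)
  expect_equal(sum(sim$meta$group == "control"), 109)
  expect_equal(sum(sim$meta$group == "DS"), 98)
})

test_that("simulation is deterministic in the master seed", {
  a <- simulate_cohort(tiny_spec(15, 15, sibling_pairs = 3), seed = 99)
  b <- simulate_cohort(tiny_spec(15, 15, sibling_pairs = 3), seed = 99)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$meta, b$meta)
  c <- simulate_cohort(tiny_spec(15, 15, sibling_pairs = 3), seed = 100)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("zero-noise traits reproduce the configured trend lines exactly", {
  sim <- simulate_cohort(default_cohort_specs()$FRA, trends = quiet_trends(),
                         seed = 21)
  tr <- derived_traits(sim$peaks)
  d <- dplyr::inner_join(tr, sim$meta, by = "sample_id")
  ctrl <- d[d$group == "control", ]
  ds <- d[d$group == "DS", ]
  expect_equal(ctrl$G0, 0.43 * ctrl$age + 6.72, tolerance = 1e-9)
  expect_equal(ds$G0, 0.44 * ds$age + 11.42, tolerance = 1e-9)
  expect_equal(ctrl$G2, -0.22 * ctrl$age + 28.25, tolerance = 1e-9)
  # a control subject at age 46 sits on the configured line: G0 = 26.50
  pt_row <- which.min(abs(ctrl$age - 46))
  expect_equal(0.43 * 46 + 6.72, 26.50)
})

test_that("configured slopes are recovered by OLS on large samples", {
  sim <- simulate_cohort(tiny_spec(5000, 5000), seed = 31)
  tr <- derived_traits(sim$peaks)
  d <- dplyr::inner_join(tr, sim$meta, by = "sample_id")
  for (grp in c("control", "DS")) {
    dd <- d[d$group == grp, ]
    fit <- lm(G0 ~ age, data = dd)
    truth <- sim$truth$trends$trends
    a_true <- truth$slope[truth$trait == "G0" & truth$group == grp]
    mc_se <- summary(fit)$coefficients["age", "Std. Error"]
    expect_lt(abs(coef(fit)["age"] - a_true), 3 * mc_se)
  }
})

test_that("plate effects are recoverable from generated data", {
  tp <- default_trend_params("FRA", batch_sd = 0.2, peak_noise_sd = 0.01)
  sim <- simulate_cohort(tiny_spec(1500, 1500, n_plates = 2), trends = tp,
                         seed = 41)
  lg <- log(as.matrix(sim$peaks[peak_cols(sim$peaks)]))
  p1 <- colMeans(lg[sim$meta$plate == 1, ])
  p2 <- colMeans(lg[sim$meta$plate == 2, ])
  truth_gap <- sim$truth$plate_effects[1, ] - sim$truth$plate_effects[2, ]
  # renormalization removes the common component of the plate offsets
  est <- (p1 - p2)
  expect_lt(max(abs((est - mean(est)) - (truth_gap - mean(truth_gap)))), 0.02)
})

test_that("infeasible compositions fail with the offending age named", {
  bad <- trend_params(
    tibble::tribble(
      ~trait, ~group, ~slope, ~intercept,
      "G0", "control", 1.5, 10, "G0", "DS", 1.5, 15,
      "G1", "control", 0, 35, "G1", "DS", 0, 35,
      "G2", "control", 0, 20, "G2", "DS", 0, 20
    ),
    noise_sd = c(G0 = 0, G1 = 0, G2 = 0), batch_sd = 0, peak_noise_sd = 0)
  expect_error(simulate_cohort(tiny_spec(10, 10), trends = bad, seed = 5),
               "age")
})

test_that("sibling pairs share families and a recoverable variance component", {
  spec <- tiny_spec(0, 0, sibling_pairs = 200)
  tp <- default_trend_params("FRA", family_sd = 3,
                             noise_sd = c(G0 = 1, G1 = 1, G2 = 1),
                             batch_sd = 0, peak_noise_sd = 0)
  sim <- simulate_cohort(spec, trends = tp, seed = 51)
  expect_true(all(table(sim$meta$family_id) == 2))
  d <- dplyr::inner_join(derived_traits(sim$peaks), sim$meta, by = "sample_id")
  est <- fit_paired(d, "G0")
  expect_equal(est$family_sd, 3, tolerance = 0.5)
})

test_that("children cohort has the study counts and the singleton flag works", {
  kids <- simulate_children(seed = 61)
  expect_equal(nrow(kids$peaks), 38 + 17 + 1)
  expect_equal(sum(kids$meta$group == "segmental"), 1)
  no_single <- simulate_children(singleton = FALSE, seed = 61)
  expect_equal(nrow(no_single$peaks), 55)
  expect_false(any(no_single$meta$group == "segmental"))
  expect_error(simulate_children(n_ds = -1, seed = 1), "nonnegative")
  again <- simulate_children(seed = 61)
  expect_identical(kids$peaks, again$peaks)
})

test_that("calibrated offsets hit the target standardized effect", {
  spec <- tiny_spec(400, 400)
  sim <- simulate_cohort(spec, seed = 71, effect_size = c(G0 = 0.72))
  d <- dplyr::inner_join(derived_traits(sim$peaks), sim$meta, by = "sample_id")
  d$z <- rank_inverse_normal(d$G0)
  est <- fit_glm(dplyr::mutate(d, G0 = z), "G0")
  # realized peak-level noise adds slight attenuation on top of MC error
  expect_equal(est$beta, 0.72, tolerance = 0.1)
  expect_true(is.finite(sim$truth$raw_offsets[["G0"]]))
})

test_that("the full study binds cohorts with shared plates", {
  st <- simulate_study(seed = 81)
  expect_setequal(unique(st$meta$cohort), c("FRA", "ITA", "UK"))
  expect_equal(nrow(st$peaks), 207 + 110 + 70 + 95)
  expect_lte(length(unique(st$meta$plate)), 7)
})
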