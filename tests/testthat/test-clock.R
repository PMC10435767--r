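line_data <- function(a_ctrl, b_ctrl, a_ds, b_ds, ages = 20:70, noise = 0,
                      seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(c("control", "DS"), each = length(ages)),
    age = rep(ages, 2),
    y = c(a_ctrl * ages + b_ctrl, a_ds * ages + b_ds) +
      rnorm(2 * length(ages), sd = noise)
  )
}

test_that("an exact line is recovered exactly", {
  d <- line_data(0.43, 6.72, 0.44, 11.42, ages = seq(25, 70, 5))
  f <- fit_trend(d, "y", group = "control")
  expect_equal(f$slope, 0.43, tolerance = 1e-10)
  expect_equal(f$intercept, 6.72, tolerance = 1e-10)
  expect_equal(f$sigma, 0, tolerance = 1e-7)
})

test_that("fit_trend equals the age-only GLM on the same subset", {
  d <- line_data(0.3, 10, 0.35, 14, noise = 2, seed = 2)
  f <- fit_trend(d, "y", group = "DS")
  ref <- lm(y ~ age, data = d[d$group == "DS", ])
  expect_equal(f$slope, unname(coef(ref)["age"]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(coef(ref)["(Intercept)"]), tolerance = 1e-12)
  expect_error(fit_trend(d[1:2, ], "y"), "at least 3")
  dd <- d; dd$age <- 40
  expect_error(fit_trend(dd, "y"), "Degenerate")
})

test_that("generator defaults are recovered within Monte-Carlo error", {
  sim <- simulate_cohort(tiny_spec(5000, 5000), seed = 12)
  d <- dplyr::inner_join(derived_traits(sim$peaks), sim$meta, by = "sample_id")
  f <- fit_trend(d, "G0", group = "control")
  se <- sqrt(f$vcov["age", "age"])
  expect_lt(abs(f$slope - 0.43), 3 * se)
})

test_that("the age shift matches the closed form of the fitted lines", {
  d <- line_data(0.43, 6.72, 0.44, 11.42, ages = seq(22, 67, 1))
  fds <- fit_trend(d, "y", group = "DS")
  fct <- fit_trend(d, "y", group = "control")
  sh <- age_shift(fds, fct, grid = 46)
  expect_equal(sh$mean, (0.01 * 46 + 4.70) / 0.43, tolerance = 1e-6)
  expect_equal(round(sh$mean, 1), 12.0)
})

test_that("identical and parallel lines give the trivial shifts", {
  d <- line_data(0.4, 10, 0.4, 12, ages = seq(20, 60, 2))
  fds <- fit_trend(d, "y", group = "DS")
  fct <- fit_trend(d, "y", group = "control")
  sh <- age_shift(fds, fct)
  expect_equal(sh$grid$shift, rep(5, nrow(sh$grid)), tolerance = 1e-8)
  # grid invariance for parallel lines
  sh2 <- age_shift(fds, fct, grid = c(25, 40, 55))
  expect_equal(sh2$mean, sh$mean, tolerance = 1e-8)

  same <- age_shift(fct, fct)
  expect_equal(same$grid$shift, rep(0, nrow(same$grid)), tolerance = 1e-10)
})

test_that("both ageing directions give a positive shift for older-like cases", {
  # trait rising with age, elevated in cases (G0-like)
  up <- line_data(0.4, 10, 0.4, 14, ages = 20:60)
  sh_up <- age_shift(fit_trend(up, "y", group = "DS"),
                     fit_trend(up, "y", group = "control"))
  expect_gt(sh_up$mean, 0)
  # trait falling with age, reduced in cases (G2-like)
  down <- line_data(-0.2, 28, -0.2, 26, ages = 20:60)
  sh_down <- age_shift(fit_trend(down, "y", group = "DS"),
                       fit_trend(down, "y", group = "control"))
  expect_gt(sh_down$mean, 0)
})

test_that("undefined shifts fail loudly", {
  d1 <- line_data(0.4, 10, -0.4, 40, ages = 20:60)
  expect_error(age_shift(fit_trend(d1, "y", group = "DS"),
                         fit_trend(d1, "y", group = "control")),
               "opposite signs")
  d2 <- line_data(0, 10, 0.4, 14, ages = 20:60)
  expect_error(age_shift(fit_trend(d2, "y", group = "DS"),
                         fit_trend(d2, "y", group = "control")),
               "near zero")
})

test_that("parallel-slopes test is exact under relabelling and calibrated under the null", {
  # two identical datasets relabelled -> interaction exactly 0
  base <- tibble::tibble(age = runif(50, 20, 70), y = rnorm(50))
  d <- dplyr::bind_rows(dplyr::mutate(base, group = "control"),
                        dplyr::mutate(base, group = "DS"))
  res <- test_parallel_slopes(d, "y")
  expect_equal(res$beta, 0, tolerance = 1e-12)

  # null calibration: equal configured slopes -> ~5% rejections
  set.seed(13)
  pvals <- vapply(1:400, function(i) {
    dd <- line_data(0.4, 10, 0.4, 14, ages = seq(20, 70, 2.5),
                    noise = 2, seed = 5000 + i)
    test_parallel_slopes(dd, "y")$p
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("a configured slope difference is detectable", {
  set.seed(14)
  hits <- vapply(1:100, function(i) {
    dd <- line_data(0.4, 10, 0.5, 12, ages = rep(seq(20, 70, 0.34), 1),
                    noise = 2, seed = 7000 + i)
    test_parallel_slopes(dd, "y")$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("combining cohort shifts averages their means", {
  expect_equal(combine_shifts(c(11.9, 17.5, 25.8)), 18.4)
  expect_equal(round(combine_shifts(c(16.3, 17.5, 23.6)), 2), 19.13)
  expect_equal(combine_shifts(7.5), 7.5)
  d <- line_data(0.4, 10, 0.4, 12, ages = 20:60)
  sh <- age_shift(fit_trend(d, "y", group = "DS"),
                  fit_trend(d, "y", group = "control"))
  expect_equal(combine_shifts(list(sh, sh)), sh$mean)
  sh2 <- sh
  sh2$trait <- "other"
  expect_error(combine_shifts(list(sh, sh2)), "mix")
})

test_that("bootstrap CIs are reproducible and collapse without noise", {
  d <- line_data(0.4, 10, 0.4, 14, ages = seq(20, 70, 2))
  ci1 <- bootstrap_shift_ci(d, "y", B = 50, seed = 15)
  ci2 <- bootstrap_shift_ci(d, "y", B = 50, seed = 15)
  expect_identical(ci1, ci2)
  expect_lt(max(ci1$upper - ci1$lower), 1e-6)  # zero-noise data

  dn <- line_data(0.4, 10, 0.4, 14, ages = seq(20, 70, 2), noise = 2,
                  seed = 16)
  ci <- bootstrap_shift_ci(dn, "y", B = 100, seed = 17)
  expect_true(all(ci$lower <= ci$shift & ci$shift <= ci$upper))
})

test_that("clock_analysis assembles the per-cohort report", {
  st <- simulate_study(
    specs = list(A = tiny_spec(60, 60, name = "A"),
                 B = tiny_spec(60, 60, name = "B")), seed = 18)
  d <- dplyr::inner_join(derived_traits(normalize_total_area(st$peaks)),
                         st$meta, by = "sample_id")
  res <- clock_analysis(d, "G0")
  expect_equal(nrow(res$report), 2)
  expect_equal(res$combined, mean(res$report$shift_mean))
  expect_true(all(c("slope_control", "interaction_p", "shift_mean") %in%
                    names(res$report)))
  expect_s3_class(autoplot(res$shifts[[1]]), "ggplot")
})
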