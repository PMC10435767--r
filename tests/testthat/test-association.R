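make_assoc_data <- function(n = 40, beta = 0, seed = 1, sd = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(c("control", "DS"), each = n / 2),
    age = runif(n, 20, 70),
    sex = sample(c("F", "M"), n, replace = TRUE),
    y = beta * (group == "DS") + 0.02 * age + rnorm(n, sd = sd)
  )
}

test_that("an exact linear structure is fitted exactly", {
  # response is exactly 2*age; group balanced within each age pair
  d <- tibble::tibble(
    group = rep(c("control", "DS"), 10),
    age = rep(1:10, each = 2),
    sex = rep(c("F", "F", "M", "M"), 5),
    y = 2 * age
  )
  est <- suppressWarnings(fit_glm(d, "y"))  # perfect fit: summary warns
  expect_equal(est$beta, 0, tolerance = 1e-12)
  fit <- lm(y ~ I(group == "DS") + age + sex, data = d)
  expect_equal(unname(coef(fit)["age"]), 2, tolerance = 1e-12)
})

test_that("fit_glm equals the normal-equations oracle", {
  d <- make_assoc_data(30, beta = 0.5, seed = 2)
  est <- fit_glm(d, "y")
  X <- cbind(1, as.numeric(d$group == "DS"), d$age,
             as.numeric(d$sex == "M"))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(est$beta, beta_hat[2], tolerance = 1e-10)
  resid <- d$y - X %*% beta_hat
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(est$se, se, tolerance = 1e-10)
  expect_equal(est$df, nrow(X) - ncol(X))
})

test_that("fit_glm recovers a simulated group effect on average", {
  est <- vapply(1:100, function(s) {
    d <- make_assoc_data(400, beta = 0.7, seed = 1000 + s, sd = 1)
    fit_glm(d, "y")$beta
  }, numeric(1))
  expect_equal(mean(est), 0.7, tolerance = 0.05)
})

test_that("fit_glm validates its inputs", {
  d <- make_assoc_data(30)
  expect_error(fit_glm(d[d$group == "DS", ], "y"), "Both groups")
  expect_error(fit_glm(d, "nope"), "No column")
  d$dup <- d$age
  expect_error(fit_glm(d, "y", adjust = c("age", "dup")),
               "rank deficient")
})

test_that("the paired model equals the paired t-test on balanced pairs", {
  set.seed(3)
  n_fam <- 30
  fam <- rep(paste0("f", 1:n_fam), each = 2)
  fam_eff <- rep(rnorm(n_fam, sd = 2), each = 2)
  d <- tibble::tibble(
    group = rep(c("DS", "control"), n_fam),
    family_id = fam,
    age = rep(runif(n_fam, 10, 50), each = 2),  # identical within pair
    sex = rep(sample(c("F", "M"), n_fam, TRUE), each = 2),
    y = 1.2 * (group == "DS") + fam_eff + rnorm(2 * n_fam)
  )
  est <- fit_paired(d, "y", adjust = NULL)
  diffs <- d$y[d$group == "DS"] - d$y[d$group == "control"]
  tt <- t.test(diffs)
  expect_equal(est$beta, mean(diffs), tolerance = 1e-8)
  expect_equal(est$se, tt$stderr, tolerance = 1e-8)
})

test_that("zero family variance collapses the paired model to OLS", {
  set.seed(4)
  d <- tibble::tibble(
    group = rep(c("DS", "control"), 40),
    family_id = paste0("f", rep(1:40, each = 2)),
    age = runif(80, 10, 50),
    sex = sample(c("F", "M"), 80, TRUE),
    y = 0.5 * (group == "DS") + 0.01 * age + rnorm(80)
  )
  # shuffle family labels so they carry no signal
  d$family_id <- sample(d$family_id)
  paired <- fit_paired(d, "y")
  ols <- fit_glm(d, "y")
  if (paired$family_sd < 1e-8) {
    expect_equal(paired$beta, ols$beta, tolerance = 1e-6)
    expect_equal(paired$se, ols$se, tolerance = 1e-6)
  } else {
    expect_equal(paired$beta, ols$beta, tolerance = 0.05)
  }
})

test_that("fixed-effects pooling follows the closed form", {
  e1 <- tibble::tibble(trait = "G0", cohort = "A", beta = 0, se = 1)
  e2 <- tibble::tibble(trait = "G0", cohort = "B", beta = 2, se = 1)
  pooled <- meta_fixed(dplyr::bind_rows(e1, e2))
  expect_equal(pooled$beta, 1)
  expect_equal(pooled$se, 1 / sqrt(2))

  single <- meta_fixed(e1)
  expect_equal(single$beta, e1$beta)
  expect_equal(single$se, e1$se)

  e3 <- tibble::tibble(trait = "G0", cohort = c("A", "B", "C"),
                       beta = c(0.5, 0.8, 0.3), se = c(0.1, 0.25, 0.4))
  pooled3 <- meta_fixed(e3)
  w <- 1 / e3$se^2
  expect_equal(pooled3$beta, sum(w * e3$beta) / sum(w), tolerance = 1e-12)
  expect_equal(pooled3$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # pooled se never exceeds the best single study; estimate in convex hull
  expect_lte(pooled3$se, min(e3$se))
  expect_gte(pooled3$beta, min(e3$beta))
  expect_lte(pooled3$beta, max(e3$beta))
})

test_that("pooling matches the reference meta-analysis package", {
  skip_if_not_installed("metafor")
  e <- tibble::tibble(trait = "G0", cohort = c("A", "B", "C"),
                      beta = c(0.72, 0.55, 0.91), se = c(0.12, 0.2, 0.17))
  pooled <- meta_fixed(e)
  ref <- metafor::rma(yi = e$beta, sei = e$se, method = "FE")
  expect_equal(pooled$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(pooled$se, ref$se, tolerance = 1e-10)
})

test_that("pooling k identical studies shrinks the se by sqrt(k)", {
  e <- tibble::tibble(trait = "G0", cohort = letters[1:4],
                      beta = 0.4, se = 0.2)
  expect_equal(meta_fixed(e)$se, 0.2 / 2, tolerance = 1e-12)
  expect_error(meta_fixed(dplyr::mutate(e, se = c(0.2, 0, 0.2, 0.2))),
               "positive")
  expect_error(meta_fixed(dplyr::mutate(e, trait = c("G0", "G1", "G0", "G0"))),
               "same trait")
})

test_that("BH adjustment matches the published example and the definition", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH equals the brute-force step-up on random vectors", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("associate_cohorts pools per-trait effects across cohorts", {
  st <- simulate_study(
    specs = list(A = tiny_spec(40, 40, name = "A"),
                 B = tiny_spec(40, 40, name = "B")),
    seed = 91)
  traits <- derived_traits(normalize_total_area(st$peaks))
  res <- associate_cohorts(traits, st$meta, which_traits = c("G0", "G2"))
  expect_equal(nrow(res$by_cohort), 4)
  expect_equal(nrow(res$meta), 2)
  expect_true(all(res$meta$q >= res$meta$p))
  # pooled se below each per-cohort se
  for (tr in c("G0", "G2")) {
    expect_lte(res$meta$se[res$meta$trait == tr],
               min(res$by_cohort$se[res$by_cohort$trait == tr]))
  }
})
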