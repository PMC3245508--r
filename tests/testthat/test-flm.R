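test_that("identical curves with an intercept-only-like design fit exactly", {
  # all curves identical; binary column present but orthogonal to the data
  cf <- constant_curves(rep(100, 6))
  cv <- tibble::tibble(subject_id = cf$subject_id, AHI = c(1, 30, 1, 30, 1, 30))
  fit <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  expect_equal(unname(fit$coef["(Intercept)", ]), c(100, rep(0, 8)))
  expect_equal(unname(fit$coef["AHI", ]), rep(0, 9))
  expect_equal(max(abs(fit$residual_coef)), 0)
})

test_that("the eight-subject constant-curve example gives the known fit", {
  fit <- worked_example_fit()
  expect_equal(unname(fit$coef["(Intercept)", 1]), 247.5)
  expect_equal(unname(fit$coef["AHI", 1]), 170)
  expect_equal(glance(fit)$r_squared, 231200 / 238060, tolerance = 1e-10)
  low <- group_mean_curve(fit, c(AHI = 1))
  high <- group_mean_curve(fit, c(AHI = -1))
  expect_equal(unique(round(low$activity, 9)), 417.5)
  expect_equal(unique(round(high$activity, 9)), 77.5)
})

test_that("fitted plus residual reconstructs the data, residuals orthogonal to Z", {
  cf <- random_curves(n_subjects = 14, seed = 41)
  withr::with_seed(42,
    cv <- tibble::tibble(subject_id = cf$subject_id, AHI = runif(14, 0, 60)))
  fit <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  A <- actflm:::curves_matrix(cf)[fit$subject_id, ]
  recon <- fit$design$Z %*% fit$coef + fit$residual_coef
  expect_equal(unname(recon), unname(A), tolerance = 1e-8)
  expect_lt(max(abs(t(fit$design$Z) %*% fit$residual_coef)), 1e-6)
})

test_that("basis-coefficient estimation equals pointwise OLS on the grid", {
  cf <- random_curves(n_subjects = 12, seed = 51)
  withr::with_seed(52,
    cv <- tibble::tibble(subject_id = cf$subject_id,
                         AHI = runif(12, 0, 60), BMI = runif(12, 18, 45)))
  s <- flm_spec(flm_binary("AHI"), flm_binary("BMI", threshold = 30),
                flm_interaction("AHI", "BMI"))
  fit <- fit_flm(cf, cv, s)
  at <- seq(0, 1439, by = 30)
  act_vals <- fit$A %*% t(eval_basis(fit$basis, at))
  oracle <- pointwise_ols_oracle(fit$design$Z, act_vals)
  beta_vals <- fit$coef %*% t(eval_basis(fit$basis, at))
  expect_equal(unname(beta_vals), unname(oracle), tolerance = 1e-8)
})

test_that("perturbing any fitted coefficient increases the integrated error", {
  cf <- random_curves(n_subjects = 10, seed = 61)
  cv <- tibble::tibble(subject_id = cf$subject_id,
                       AHI = rep(c(1, 30), 5))
  fit <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  G <- eval_basis(fit$basis, fit$basis$grid)
  lmsse <- function(B) sum(((fit$A - fit$design$Z %*% B) %*% t(G))^2)
  best <- lmsse(fit$coef)
  withr::with_seed(62, {
    for (i in 1:10) {
      B2 <- fit$coef
      j <- sample(length(B2), 1)
      B2[j] <- B2[j] + sample(c(-1, 1), 1) * runif(1, 0.5, 5)
      expect_gt(lmsse(B2), best)
    }
  })
})

test_that("group mean curves follow the add/subtract coefficient rules", {
  # balanced 2x2 cohort: one subject per cell, duplicated
  codes <- expand.grid(AHI = c(1, -1), BMI = c(1, -1))
  codes <- codes[rep(1:4, 2), ]
  cv <- tibble::tibble(subject_id = sprintf("g%d", 1:8),
                       AHI = ifelse(codes$AHI == 1, 2, 30),
                       BMI = ifelse(codes$BMI == 1, 22, 40))
  cf <- random_curves(n_subjects = 8, seed = 71)
  cf$subject_id <- cv$subject_id
  s <- flm_spec(flm_binary("AHI"), flm_binary("BMI", threshold = 30),
                flm_interaction("AHI", "BMI"))
  fit <- fit_flm(cf, cv, s)
  B <- fit$coef
  # high apnea / low BMI: b0 - bAHI + bBMI - bAHI:BMI
  hl <- group_mean_curve(fit, c(AHI = -1, BMI = 1))
  expect_equal(attr(hl, "coefficients"),
               drop(c(1, -1, 1, -1) %*% B), tolerance = 1e-12)
  # average of the 4 balanced group curves is the intercept curve
  combos <- list(c(AHI = 1, BMI = 1), c(AHI = 1, BMI = -1),
                 c(AHI = -1, BMI = 1), c(AHI = -1, BMI = -1))
  avg <- Reduce(`+`, lapply(combos, function(cb)
    group_mean_curve(fit, cb)$activity)) / 4
  b0 <- tidy(fit) |> dplyr::filter(term == "(Intercept)")
  expect_equal(avg, b0$estimate, tolerance = 1e-8)
  # under a balanced design the fitted group curve is the group's
  # pointwise arithmetic mean of fitted values
  grp <- fit$design$Z[, "AHI"] == 1 & fit$design$Z[, "BMI"] == 1
  fitted_vals <- (fit$design$Z %*% fit$coef) %*%
    t(eval_basis(fit$basis, fit$basis$grid))
  expect_equal(group_mean_curve(fit, c(AHI = 1, BMI = 1))$activity,
               unname(colMeans(fitted_vals[grp, ])), tolerance = 1e-8)
  expect_error(group_mean_curve(fit, c(AHI = 1)), "missing: BMI")
  expect_error(group_mean_curve(fit, c(AHI = 1, BMI = 1, XX = 1)), "unknown")
})

test_that("F(t) is zero when groups coincide and matches the subject-loop oracle", {
  cf <- constant_curves(rep(50, 8))
  cv <- tibble::tibble(subject_id = cf$subject_id, AHI = rep(c(1, 30), 4))
  fit0 <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  expect_warning(f0 <- pointwise_F(fit0), "0/0")   # 0 residuals too
  expect_true(all(f0$statistic == 0))

  cfr <- random_curves(n_subjects = 10, seed = 81)
  cvr <- tibble::tibble(subject_id = cfr$subject_id, AHI = rep(c(1, 30), 5))
  fit <- fit_flm(cfr, cvr, flm_spec(flm_binary("AHI")))
  at <- seq(0, 1439, by = 20)
  f <- pointwise_F(fit, at = at)
  G <- t(eval_basis(fit$basis, at))
  oracle <- naive_F_oracle(fit$design$Z, fit$coef %*% G, fit$A %*% G)
  expect_equal(f$statistic, oracle, tolerance = 1e-10)
  expect_true(all(f$statistic >= 0))
})

test_that("balanced two-group constant curves reproduce the ANOVA F", {
  y <- c(12, 15, 11, 18, 30, 28, 35, 31)
  cf <- constant_curves(y)
  cv <- tibble::tibble(subject_id = cf$subject_id,
                       AHI = c(rep(1, 4), rep(30, 4)))
  fit <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  f <- pointwise_F(fit, at = c(0, 360, 720))
  expect_equal(diff(range(f$statistic)), 0, tolerance = 1e-12)
  # textbook one-way ANOVA F computed by formula
  g <- rep(1:2, each = 4)
  gm <- tapply(y, g, mean)
  ssb <- sum(4 * (gm - mean(y))^2)
  sse <- sum((y - gm[g])^2)
  f_anova <- (ssb / 1) / (sse / 6)
  # divisor conversion: numerator uses N-1, denominator uses N
  n <- 8
  expect_equal(f$statistic[1], f_anova * n / ((n - 1) * (n - 2)),
               tolerance = 1e-12)
})

test_that("F(t) is invariant to adding a constant to every curve", {
  cf <- random_curves(n_subjects = 12, seed = 91)
  cv <- tibble::tibble(subject_id = cf$subject_id, AHI = rep(c(1, 30), 6))
  fit1 <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  cf2 <- cf
  cf2$a1 <- cf2$a1 + 250
  fit2 <- fit_flm(cf2, cv, flm_spec(flm_binary("AHI")))
  at <- seq(0, 1439, by = 60)
  expect_equal(pointwise_F(fit1, at = at)$statistic,
               pointwise_F(fit2, at = at)$statistic, tolerance = 1e-8)
})

test_that("confidence bands collapse with zero residuals and widen with level", {
  cf <- constant_curves(c(370, 397, 482, 421, 78, 76, 80, 76))
  cv <- worked_example()$covariates
  cv$subject_id <- cf$subject_id
  fit <- fit_flm(cf, cv, flm_spec(flm_binary("AHI")))
  b95 <- confidence_band(fit, c(AHI = 1), level = 0.95, at = c(0, 720))
  b99 <- confidence_band(fit, c(AHI = 1), level = 0.99, at = c(0, 720))
  expect_true(all(b99$lower < b95$lower))
  expect_true(all(b99$upper > b95$upper))
  expect_true(all(b95$lower < b95$estimate & b95$estimate < b95$upper))
  # zero residuals: band collapses onto the estimate
  cf0 <- constant_curves(c(rep(400, 4), rep(80, 4)))
  fit0 <- fit_flm(cf0, dplyr::mutate(cv, subject_id = cf0$subject_id),
                  flm_spec(flm_binary("AHI")))
  b0 <- confidence_band(fit0, c(AHI = 1), at = c(0, 720))
  expect_equal(b0$lower, b0$estimate, tolerance = 1e-10)
  expect_equal(b0$upper, b0$estimate, tolerance = 1e-10)
  expect_error(confidence_band(fit, c(AHI = 1), level = 1.2), "level")
})

test_that("tidy/glance expose curves and fit summaries", {
  fit <- worked_example_fit()
  td <- tidy(fit, at = c(0, 720))
  expect_equal(names(td), c("term", "minute", "estimate"))
  expect_equal(nrow(td), 4)
  g <- glance(fit)
  expect_equal(g$n, 8)
  expect_equal(g$p, 2)
  expect_equal(g$df_residual, 6)
  # CSV/JSON exports round-trip the headline numbers
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_flm_curves(fit, f1)
  write_flm_summary(fit, f2)
  expect_equal(nrow(readr::read_csv(f1, show_col_types = FALSE)), 1440)
  expect_equal(jsonlite::read_json(f2)$n, 8)
})

test_that("collinear designs and missing curves are rejected", {
  cf <- random_curves(n_subjects = 6, seed = 99)
  cv <- tibble::tibble(subject_id = cf$subject_id, AHI = rep(c(1, 30), 3),
                       AHI2 = rep(c(1, 30), 3))
  expect_error(
    fit_flm(cf, cv, flm_spec(flm_binary("AHI"), flm_binary("AHI2"))),
    "singular|collinear")
  d <- build_design(dplyr::bind_rows(cv, tibble::tibble(subject_id = "zz",
                                                        AHI = 15, AHI2 = 15)),
                    flm_spec(flm_binary("AHI")))
  expect_error(fit_flm(cf, design = d), "without curves")
})
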