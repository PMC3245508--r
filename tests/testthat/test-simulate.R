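noiseless_spec <- function(n = 4, effects = list()) {
  cohort_spec(n, baseline = circadian_curve(300, 150, 900),
              effects = effects, subject_sd = 0, minute_noise_sd = 0)
}

test_that("a noiseless cohort reproduces the baseline curve exactly", {
  coh <- simulate_cohort(noiseless_spec(), seed = 1)
  pr <- daily_profiles(coh$epochs)
  mu <- true_group_curve(coh$truth$spec)$activity
  for (sid in unique(pr$subject_id)) {
    expect_equal(pr$activity[pr$subject_id == sid], mu, tolerance = 1e-9)
  }
})

test_that("a noiseless binary effect doubles the group-mean gap", {
  delta <- circadian_curve(20, 30, 780)
  coh <- simulate_cohort(noiseless_spec(6, list(AHI = effect_binary(delta))),
                         seed = 2)
  pr <- daily_profiles(coh$epochs)
  codes <- coh$truth$codes
  lows <- codes$subject_id[codes$AHI == 1]
  gap <- colMeans(matrix(pr$activity[pr$subject_id %in% lows],
                         ncol = 1440, byrow = TRUE)) -
    colMeans(matrix(pr$activity[!pr$subject_id %in% lows],
                    ncol = 1440, byrow = TRUE))
  expect_equal(gap, 2 * eval_circadian(delta, 0:1439), tolerance = 1e-9)
})

test_that("true group curves combine baseline and effects correctly", {
  delta <- circadian_curve(10, 15, 600)
  spec <- noiseless_spec(6, list(AHI = effect_binary(delta)))
  mu <- true_group_curve(spec)$activity
  lo <- true_group_curve(spec, c(AHI = 1))$activity
  hi <- true_group_curve(spec, c(AHI = -1))$activity
  expect_equal(lo - hi, 2 * eval_circadian(delta, 0:1439))
  expect_equal((lo + hi) / 2, mu)
  expect_error(true_group_curve(spec, c(BMI = 1)), "unknown covariate")
  # cross-check against the generator's noiseless output
  coh <- simulate_cohort(spec, seed = 3)
  pr <- daily_profiles(coh$epochs)
  low_id <- coh$truth$codes$subject_id[coh$truth$codes$AHI == 1][1]
  expect_equal(pr$activity[pr$subject_id == low_id], lo, tolerance = 1e-9)
})

test_that("simulation is seed-deterministic with a seed-free truth bundle", {
  spec <- cohort_spec(6, baseline = circadian_curve(300, 120, 900),
                      effects = list(AHI = effect_binary(circadian_curve(20, 10, 900))),
                      subject_sd = 20, minute_noise_sd = 40)
  c1 <- simulate_cohort(spec, seed = 11)
  c2 <- simulate_cohort(spec, seed = 11)
  c3 <- simulate_cohort(spec, seed = 12)
  expect_identical(c1$epochs$count, c2$epochs$count)
  expect_false(identical(c1$epochs$count, c3$epochs$count))
  # truth identical across seeds
  expect_identical(c1$truth$mu, c3$truth$mu)
  expect_identical(c1$truth$effects, c3$truth$effects)
  expect_identical(c1$truth$codes, c3$truth$codes)
  expect_identical(c1$covariates, c3$covariates)
})

test_that("binary codes are balanced and match the emitted scores", {
  spec <- cohort_spec(10, baseline = circadian_curve(300, 100, 900),
                      effects = list(AHI = effect_binary(circadian_curve(10, 5, 900))),
                      subject_sd = 0, minute_noise_sd = 0)
  coh <- simulate_cohort(spec, seed = 4)
  expect_equal(sum(coh$truth$codes$AHI), 0)
  expect_equal(encode_binary(coh$covariates$AHI, 0.5), coh$truth$codes$AHI)
  # continuous values are an evenly spaced deterministic grid
  spec2 <- cohort_spec(5, baseline = circadian_curve(300, 50, 900),
                       effects = list(BMI = effect_continuous(
                         circadian_curve(1, 0.5, 900), range = c(-2, 2))),
                       subject_sd = 0, minute_noise_sd = 0)
  coh2 <- simulate_cohort(spec2, seed = 5)
  expect_equal(coh2$covariates$BMI, seq(-2, 2, length.out = 5))
})

test_that("minute-level gaussian noise has the specified variance", {
  spec <- cohort_spec(4, n_days = 5,
                      baseline = circadian_curve(1000, 0, 900),
                      subject_sd = 0, minute_noise_sd = 50)
  coh <- simulate_cohort(spec, seed = 6)
  resid <- coh$epochs$count - 1000
  n <- length(resid)
  v <- var(resid)
  band <- 50^2 * n / qchisq(c(0.9995, 0.0005), df = n - 1)
  expect_gt(v, min(band))
  expect_lt(v, max(band))
  # poisson-like family: variance close to mean x dispersion
  specp <- cohort_spec(4, baseline = circadian_curve(500, 0, 900),
                       subject_sd = 0, noise = "poisson", dispersion = 8)
  cohp <- simulate_cohort(specp, seed = 7)
  expect_equal(var(cohp$epochs$count), 500 * 8, tolerance = 0.05)
})

test_that("invariant-violating specs fail before simulation", {
  expect_error(
    cohort_spec(4, baseline = circadian_curve(100, 90, 900),
                effects = list(AHI = effect_binary(circadian_curve(50, 0, 900)))),
    "dips")
  expect_error(cohort_spec(3), "n_subjects")
  expect_error(cohort_spec(4, start_date = as.Date("2024-01-02")), "Monday")
  expect_error(simulate_cohort(noiseless_spec()), "seed")
})

test_that("out-of-span roughness perturbs subject curves when enabled", {
  base <- cohort_spec(4, baseline = circadian_curve(500, 100, 900),
                      subject_sd = 0, minute_noise_sd = 0)
  rough <- cohort_spec(4, baseline = circadian_curve(500, 100, 900),
                       subject_sd = 0, minute_noise_sd = 0, rough_sd = 30)
  c0 <- simulate_cohort(base, seed = 9)
  c1 <- simulate_cohort(rough, seed = 9)
  expect_false(identical(c0$epochs$count, c1$epochs$count))
  # the added structure sits at harmonic 12: invisible to the 9-term smoother
  pr <- daily_profiles(c1$epochs)
  sm <- smooth_profiles(pr)
  mu <- eval_circadian(base$baseline, 0:1439)
  fitted <- evaluate_curves(sm)
  err <- fitted$activity[fitted$subject_id == "S001"] - mu
  expect_lt(max(abs(err)), 1e-6)
})
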