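test_that("local-linear fit reproduces linear coefficient curves exactly", {
  g <- quick_grid()
  cf <- list(intercept = function(s) 0.6 - 0.002 * s,
             group = function(s) 0.01 + 0.0005 * s,
             age_years = function(s) rep(-2e-4, length(s)),
             scanner = function(s) 0.003 - 1e-5 * s,
             sex = function(s) rep(0, length(s)))
  co <- simulate_cohort(cohort_spec(n_per_group = c(6, 6), grid = g,
                                    coefficient_functions = cf,
                                    eta_sd = 0, eps_sd = 0, seed = 2))
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 9)
  for (nm in c("intercept", "group", "age_years", "scanner"))
    expect_equal(coef(fit)[nm, ], cf[[nm]](g$positions), tolerance = 1e-10)
  # residual curves vanish in the noise-free case
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("bandwidth -> 0 limit equals independent per-position OLS", {
  co <- quick_cohort(n = c(8, 8), seed = 4)
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 1e-8)
  X <- model.matrix(~ group + age_years + scanner, co$covariates)
  ols <- oracle_ols(co$values$FA, X)
  expect_lt(max(abs(coef(fit) - ols) / pmax(abs(ols), 1e-12)), 1e-10)
})

test_that("constant disease effect is inverted exactly without noise", {
  co <- quick_cohort(n = c(6, 6), eta_sd = 0, eps_sd = 0,
                     group_effect = 0.05, seed = 3)
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  expect_equal(unname(coef(fit)["group", ]), rep(0.05, 50),
               tolerance = 1e-10)
})

test_that("general missing-data path agrees with the fast path when complete", {
  co <- quick_cohort(n = c(6, 6), seed = 8)
  X <- cordvcm:::vcm_design(~ group + age_years + scanner, co$covariates)
  g <- cordvcm:::vcm_fit_general(co$values$FA, X, co$grid$positions, 6,
                                 "epanechnikov")
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  expect_equal(unname(g$Bhat), unname(coef(fit)), tolerance = 1e-9)
  expect_equal(g$cov, fit$cov, tolerance = 1e-8)
})

test_that("missing values are dropped locally, not fatally", {
  co <- quick_cohort(n = c(6, 6), seed = 9)
  co$values$FA[2, 10] <- NA
  co$values$FA[5, 30:32] <- NA
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  expect_false(anyNA(coef(fit)))
  full <- vcm(~ group + age_years + scanner, quick_cohort(n = c(6, 6),
                                                          seed = 9),
              bandwidth = 6)
  expect_lt(max(abs(coef(fit) - coef(full))), 0.05)
  # a fully missing subject is a hard error
  co$values$FA[1, ] <- NA
  expect_error(vcm(~ group + age_years + scanner, co), "entirely missing")
})

test_that("residual curves average to ~0 per position with an intercept", {
  co <- quick_cohort(n = c(10, 10), seed = 10)
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  expect_lt(max(abs(colMeans(residuals(fit)))), 0.01)
})

test_that("scalar Wald statistic is the squared t-ratio", {
  co <- quick_cohort(n = c(8, 8), seed = 11, group_effect = 0.02)
  fit <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  T <- local_wald_statistic(fit, "group")
  expect_equal(T, unname((coef(fit)["group", ] / fit$se["group", ])^2),
               tolerance = 1e-10)
  expect_true(all(T >= 0))
  expect_error(local_wald_statistic(fit, "intercept"), "intercept")
})

test_that("the statistic is invariant to rescaling the response", {
  co <- quick_cohort(n = c(8, 8), seed = 12, group_effect = 0.02)
  fit1 <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  co2 <- co
  co2$values$FA <- 2 * co$values$FA
  fit2 <- vcm(~ group + age_years + scanner, co2, bandwidth = 6)
  expect_equal(coef(fit2)["group", ], 2 * coef(fit1)["group", ],
               tolerance = 1e-10)
  expect_equal(local_wald_statistic(fit1, "group"),
               local_wald_statistic(fit2, "group"), tolerance = 1e-9)
})

test_that("swapping group labels leaves the statistic unchanged", {
  co <- quick_cohort(n = c(8, 8), seed = 13, group_effect = 0.03)
  fit1 <- vcm(~ group + age_years + scanner, co, bandwidth = 6)
  co2 <- co
  co2$covariates$group <- 1 - co$covariates$group
  fit2 <- vcm(~ group + age_years + scanner, co2, bandwidth = 6)
  expect_equal(coef(fit2)["group", ], -coef(fit1)["group", ],
               tolerance = 1e-9)
  expect_equal(local_wald_statistic(fit1, "group"),
               local_wald_statistic(fit2, "group"), tolerance = 1e-8)
})

test_that("model methods behave coherently", {
  co <- quick_cohort(n = c(6, 6), seed = 14)
  fit <- vcm(~ group + age_years + scanner, co)
  expect_s3_class(fit, "vcm")
  expect_equal(dim(coef(fit)), c(4L, 50L))
  expect_equal(fitted(fit) + residuals(fit), unname(co$values$FA),
               ignore_attr = TRUE, tolerance = 1e-12)
  pred <- predict(fit, newdata = co$covariates[1:3, ])
  expect_equal(unname(pred), unname(fitted(fit)[1:3, ]), tolerance = 1e-12)
  s <- summary(fit)
  expect_equal(s$table$covariate,
               c("intercept", "group", "age_years", "scanner"))
  expect_output(print(fit), "Varying coefficient model")
})

test_that("bandwidth selection honors ties and degenerate candidate lists", {
  g <- quick_grid()
  cf <- list(intercept = function(s) 0.6 - 0.002 * s,
             group = function(s) rep(0.01, length(s)),
             age_years = function(s) rep(0, length(s)),
             scanner = function(s) rep(0, length(s)),
             sex = function(s) rep(0, length(s)))
  co <- simulate_cohort(cohort_spec(n_per_group = c(5, 5), grid = g,
                                    coefficient_functions = cf,
                                    eta_sd = 0, eps_sd = 0, seed = 5))
  # noise-free linear truth: all candidates tie at ~0 error, smallest wins
  h <- select_bandwidth(~ group + age_years + scanner, co,
                        candidates = c(12, 3, 6))
  expect_equal(as.numeric(h), 3)
  expect_equal(select_bandwidth(~ group, co, candidates = 7), 7)
  expect_error(select_bandwidth(~ group, co, candidates = numeric(0)),
               "candidate")
})

test_that("rough coefficient curves favor smaller bandwidths", {
  g <- quick_grid()
  mk <- function(freq) list(
    intercept = function(s) 0.5 + 0.05 * sin(freq * s),
    group = function(s) rep(0, length(s)),
    age_years = function(s) rep(0, length(s)),
    scanner = function(s) rep(0, length(s)),
    sex = function(s) rep(0, length(s)))
  pick <- function(freq, seed) {
    co <- simulate_cohort(cohort_spec(n_per_group = c(10, 10), grid = g,
                                      coefficient_functions = mk(freq),
                                      eta_sd = 0.01, eps_sd = 0.02,
                                      seed = seed))
    as.numeric(select_bandwidth(~ group + age_years + scanner, co,
                                candidates = c(3, 6, 12, 24)))
  }
  smooth_h <- sapply(1:6, function(s) pick(0.05, s))
  rough_h <- sapply(1:6, function(s) pick(0.8, s))
  expect_lt(mean(rough_h), mean(smooth_h))
})
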