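test_that("noise-free cohorts equal the design mean exactly", {
  g <- quick_grid()
  co <- quick_cohort(n = c(5, 5), eta_sd = 0, eps_sd = 0,
                     group_effect = 0.05, seed = 3)
  X <- cordvcm:::cohort_design_matrix(co$covariates)
  cf <- default_coefficients(group_effect = 0.05)
  mu <- cordvcm:::true_mean_matrix(X, cf, g$positions)
  expect_equal(unname(co$values$FA), unname(mu), tolerance = 1e-14)
})

test_that("per-position variance matches eta_sd^2 + eps_sd^2 under the null", {
  g <- cord_grid(points_per_level = 1)  # 5 positions
  cf <- default_coefficients(intercept = 0, age = 0, scanner = 0)
  co <- simulate_cohort(cohort_spec(n_per_group = c(1000, 1000), grid = g,
                                    coefficient_functions = cf,
                                    eta_sd = 0.03, eps_sd = 0.01, seed = 11))
  v <- apply(co$values$FA, 2, var)
  expect_equal(v, rep(0.03^2 + 0.01^2, 5), tolerance = 0.1)
})

test_that("subject curves carry the squared-exponential correlation", {
  d <- 10; ell <- 15
  g <- cord_grid(levels = "C2", points_per_level = 2, spacing_mm = d)
  cf <- default_coefficients(intercept = 0, age = 0, scanner = 0)
  co <- simulate_cohort(cohort_spec(n_per_group = c(1000, 1000), grid = g,
                                    coefficient_functions = cf,
                                    eta_sd = 0.05, eps_sd = 0,
                                    eta_lengthscale_mm = ell, seed = 12))
  r <- cor(co$values$FA[, 1], co$values$FA[, 2])
  expect_equal(r, exp(-d^2 / (2 * ell^2)), tolerance = 0.04)
})

test_that("cross-metric subject-curve correlation matches the spec", {
  g <- cord_grid(points_per_level = 2)
  co <- simulate_cohort(cohort_spec(n_per_group = c(1000, 1000), grid = g,
                                    metrics = c("FA", "RD"),
                                    cross_metric_corr = 0.6,
                                    eta_sd = 0.03, eps_sd = 0, seed = 13))
  # remove the design mean before correlating
  X <- cordvcm:::cohort_design_matrix(co$covariates)
  resid <- function(Y) Y - X %*% qr.solve(X, Y)
  r <- cor(as.vector(resid(co$values$FA)), as.vector(resid(co$values$RD)))
  # 3 standard errors at n = 2000 draws per position
  expect_lt(abs(r - 0.6), 3 * (1 - 0.6^2) / sqrt(2000))
})

test_that("generation is a pure function of the spec", {
  sp <- cohort_spec(n_per_group = c(4, 4), seed = 42)
  expect_identical(simulate_cohort(sp), simulate_cohort(sp))
  sp2 <- cohort_spec(n_per_group = c(4, 4), seed = 43)
  expect_false(identical(simulate_cohort(sp)$values$FA,
                         simulate_cohort(sp2)$values$FA))
})

test_that("spec validation catches bad generative parameters", {
  expect_error(cohort_spec(eta_sd = -1), "eta_sd")
  expect_error(cohort_spec(eta_lengthscale_mm = 0), "positive")
  expect_error(cohort_spec(cross_metric_corr = 1.5), "cross_metric_corr")
  expect_error(cohort_spec(metrics = "T1"), "subset")
  cf <- default_coefficients()
  cf$scanner <- NULL
  expect_error(simulate_cohort(cohort_spec(coefficient_functions = cf)),
               "missing coefficient function")
})

test_that("covariates respect the cohort structure", {
  co <- quick_cohort(n = c(20, 20), seed = 5)
  cv <- co$covariates
  expect_true(all(cv$group %in% 0:1))
  expect_true(all(cv$scanner %in% 0:1))
  expect_true(all(cv$sex %in% 0:1))
  expect_true(all((cv$onset_site == "none") == (cv$group == 0)))
  expect_true(all(cv$age_years >= 20))
})

test_that("longitudinal pairs share subjects and apply change curves", {
  g <- quick_grid()
  chg <- list(intercept = function(s) rep(0, length(s)),
              group = function(s) rep(0.02, length(s)),
              age_years = function(s) rep(0, length(s)),
              scanner = function(s) rep(0, length(s)),
              sex = function(s) rep(0, length(s)))
  sp <- cohort_spec(n_per_group = c(6, 6), grid = g, eta_sd = 0, eps_sd = 0,
                    seed = 7)
  lg <- simulate_longitudinal(sp, change_functions = chg)
  expect_identical(lg$baseline$covariates$subject_id,
                   lg$followup$covariates$subject_id)
  d <- lg$followup$values$FA - lg$baseline$values$FA
  als <- lg$baseline$covariates$group == 1
  expect_equal(unname(d[als, ]),
               matrix(0.02, sum(als), length(g$positions)), tolerance = 1e-12)
  expect_equal(unname(d[!als, ]),
               matrix(0, sum(!als), length(g$positions)), tolerance = 1e-12)
})

test_that("clinical scores honor item ranges and the target coupling", {
  co <- simulate_cohort(cohort_spec(n_per_group = c(1000, 1000),
                                    grid = cord_grid(points_per_level = 4),
                                    seed = 2))
  cl <- simulate_clinical_scores(co, target_corr = 0.8, seed = 3)
  items <- as.matrix(cl[paste0("item_", 1:12)])
  expect_true(all(items %in% 0:4))
  expect_true(all(alsfrs_subscore(cl, 1:12) <= 48))
  expect_true(all(cl$umn %in% 0:6))
  sv <- rowMeans(co$values$FA)
  expect_lt(abs(cor(sv, alsfrs_subscore(cl, 4:12)) - 0.8), 0.05)

  cl0 <- simulate_clinical_scores(co, target_corr = 0, seed = 3)
  expect_lt(abs(cor(sv, alsfrs_subscore(cl0, 4:12))), 0.05)
  expect_error(simulate_clinical_scores(co, target_corr = 1.2), "target_corr")
})
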