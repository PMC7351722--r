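make_clinical <- function(n = 10, seed = 1) {
  set.seed(seed)
  items <- matrix(sample(0:4, n * 12, replace = TRUE), n, 12,
                  dimnames = list(NULL, paste0("item_", 1:12)))
  out <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    timepoint = "baseline", items, umn = sample(0:6, n, TRUE))
  class(out) <- c("clinical_table", "data.frame")
  out
}

test_that("sub-scores hit the published scale anchors", {
  tab <- make_clinical(3)
  tab[paste0("item_", 1:12)] <- 4L
  expect_equal(unname(alsfrs_subscore(tab, 4:12)), rep(36L, 3))
  expect_equal(unname(alsfrs_subscore(tab, 1:12)), rep(48L, 3))
  tab[paste0("item_", 10:12)] <- 0L
  expect_equal(unname(alsfrs_subscore(tab, 10:12)), rep(0L, 3))
})

test_that("sub-scores are additive over disjoint item sets", {
  tab <- make_clinical(25, seed = 2)
  expect_equal(alsfrs_subscore(tab, 1:12),
               alsfrs_subscore(tab, 1:3) + alsfrs_subscore(tab, 4:12))
})

test_that("missing items yield NA with a warning; absent items error", {
  tab <- make_clinical(4)
  tab$item_5[2] <- NA
  expect_warning(s <- alsfrs_subscore(tab, 4:12), "missing")
  expect_true(is.na(s[2]) && !is.na(s[1]))
  expect_error(alsfrs_subscore(tab, 13), "not present")
})

test_that("profile summaries average the requested levels only", {
  g <- quick_grid()
  vals <- ifelse(g$levels == "C2", 0.6, 0.4)
  p <- cordvcm:::new_metric_profile("s1", "whole_cord", "FA", g, vals)
  expect_equal(summarize_profile(p, "C2")$value, 0.6)
  expect_equal(summarize_profile(p)$value, mean(vals))
  const <- cordvcm:::new_metric_profile("s1", "whole_cord", "FA", g,
                                        rep(0.5, 50))
  expect_equal(summarize_profile(const, c("C3", "C4"))$value, 0.5)
  ramp <- cordvcm:::new_metric_profile("s1", "whole_cord", "FA", g,
                                       seq(0.3, 0.7, length.out = 50))
  expect_equal(summarize_profile(ramp)$value, mean(seq(0.3, 0.7,
                                                       length.out = 50)))
  allna <- cordvcm:::new_metric_profile("s1", "whole_cord", "FA", g,
                                        rep(NA_real_, 50))
  expect_error(summarize_profile(allna), "non-missing")
})

test_that("Pearson correlation matches the textbook formula", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  hand <- pearson_correlation(c(1, 2, 3), c(6, 4, 5))
  expect_equal(hand$r, -0.5, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_correlation(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # affine invariance (sign-preserving slope)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_correlation(3 * x - 2, 0.5 * y + 4)$r,
               pearson_correlation(x, y)$r, tolerance = 1e-12)
  flagged <- pearson_correlation(rep(1, 5), rnorm(5))
  expect_true(flagged$undefined)
  expect_error(pearson_correlation(1:2, 2:3), "3 complete pairs")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  same <- paired_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  shift <- paired_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(shift$degenerate)
  expect_equal(shift$p, 0)
  expect_equal(shift$mean_change, 1)

  b <- c(0.5, 0.5, 0.5, 0.5)
  f <- b + c(0.1, 0.2, 0.0, 0.3)
  got <- paired_t_test(b, f)
  want <- oracle_paired_t(b, f)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    bb <- rnorm(n); ff <- rnorm(n)
    got <- paired_t_test(bb, ff)
    want <- oracle_paired_t(bb, ff)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("independent scores give null correlations at scale", {
  set.seed(9)
  x <- rnorm(2000); y <- rnorm(2000)
  pc <- pearson_correlation(x, y)
  expect_lt(abs(pc$r), 0.05)
})

test_that("subgroup means recover programmed offsets", {
  set.seed(10)
  cov <- data.frame(
    subject_id = sprintf("S%02d", 1:40),
    group = c(rep(1, 20), rep(0, 20)),
    onset_site = c(rep("upper_limb", 10), rep("lower_limb", 5),
                   rep("bulbar", 5), rep("none", 20)))
  truth <- c(upper_limb = 0.45, lower_limb = 0.47, bulbar = 0.50,
             control = 0.53)
  lab <- ifelse(cov$onset_site == "none", "control", cov$onset_site)
  vals <- setNames(truth[lab] + rnorm(40, sd = 1e-3), cov$subject_id)
  sg <- subgroup_means(vals, cov)
  got <- setNames(sg$means$mean, sg$means$subgroup)
  expect_equal(got[names(truth)], truth, tolerance = 0.01)
  expect_equal(sort(sg$means$n), sort(c(10L, 5L, 5L, 20L)))
  expect_equal(nrow(sg$pairwise), 6)
  expect_true(all(sg$pairwise$p >= 0 & sg$pairwise$p <= 1))

  # single subject in a subgroup: mean reported, SD missing
  cov1 <- cov[c(1, 11, 21), ]
  v1 <- vals[c(1, 11, 21)]
  cov1$onset_site[3] <- "bulbar"
  sg1 <- subgroup_means(v1, cov1)
  expect_true(all(is.na(sg1$means$sd)))
  expect_equal(sg1$means$n, rep(1L, 3))

  # one subgroup only: the grand mean
  cov2 <- cov[1:10, ]
  sg2 <- subgroup_means(vals[1:10], cov2)
  expect_equal(nrow(sg2$means), 1)
  expect_equal(sg2$means$mean, mean(vals[1:10]))
})
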