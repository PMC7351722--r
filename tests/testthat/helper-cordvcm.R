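# shared fixtures and independent oracles (kept deliberately naive:
# they must not share code paths with the package internals)

quick_grid <- function(ppl = 10, spacing = 1.5)
  cord_grid(points_per_level = ppl, spacing_mm = spacing)

quick_cohort <- function(n = c(8, 8), seed = 1, grid = quick_grid(),
                         group_effect = 0, eta_sd = 0.03, eps_sd = 0.01,
                         metrics = "FA", ...) {
  simulate_cohort(cohort_spec(
    n_per_group = n, grid = grid,
    coefficient_functions = default_coefficients(group_effect = group_effect),
    eta_sd = eta_sd, eps_sd = eps_sd, metrics = metrics, seed = seed, ...))
}

# brute-force truncated sliding mean (independent of the package routine)
oracle_sliding_mean <- function(x, h) {
  n <- length(x)
  sapply(seq_len(n), function(k) {
    w <- x[max(1, k - h):min(n, k + h)]
    if (all(is.na(w))) NA_real_ else sum(w, na.rm = TRUE) / sum(!is.na(w))
  })
}

# per-position ordinary least squares, the bandwidth->0 oracle
oracle_ols <- function(Y, X) {
  sapply(seq_len(ncol(Y)), function(s)
    qr.solve(X, Y[, s]))
}

# textbook paired t-test
oracle_paired_t <- function(b, f) {
  d <- f - b; n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), mean_change = mean(d))
}

# textbook Pearson r and t-transform p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# independent FA formula (pairwise-difference form)
oracle_fa <- function(l1, l2, l3) {
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2
  sqrt(0.5) * sqrt(num) / sqrt(l1^2 + l2^2 + l3^2)
}
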