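#' Specification for a synthetic along-cord cohort
#'
#' Collects the generative parameters of the profile model
#' \deqn{Y_{i}(s) = x_i^T B(s) + \eta_i(s) + \epsilon_i(s)}
#' where \eqn{B(s)} are the true coefficient curves, \eqn{\eta_i} is a
#' smooth zero-mean Gaussian process with squared-exponential covariance
#' (the subject-specific curve variation) and \eqn{\epsilon_i} is iid
#' measurement error.
#'
#' @param n_per_group Length-2 integer vector: number of patients (group 1)
#'   and controls (group 0). Default \code{c(20, 20)}, the usual size of a
#'   single-site ALS imaging cohort.
#' @param grid A \code{\link{cord_grid}}.
#' @param coefficient_functions Named list of functions of arc-length s
#'   (mm), one per design column (\code{intercept}, \code{group},
#'   \code{age_years}, \code{scanner}, and \code{sex} if
#'   \code{include_sex}). Either one list applied to every metric, or a
#'   list of such lists named by metric.
#' @param eta_sd Standard deviation of the subject curve process; a scalar
#'   applied to every metric, or a named vector with one entry per metric
#'   (FA and CSA live on very different scales).
#' @param eta_lengthscale_mm Correlation length (mm) of the
#'   squared-exponential kernel: \eqn{cov(\eta(s),\eta(t)) =
#'   \sigma^2 \exp(-(s-t)^2 / (2 \ell^2))}.
#' @param eps_sd Standard deviation of the independent measurement error.
#' @param metrics Character vector of metric names to emit (subset of
#'   FA, RD, MD, AD, CSA).
#' @param cross_metric_corr Correlation of the subject curve draws between
#'   metrics at each position (used by the multimodal test); in [-1, 1].
#' @param include_sex Include sex in the design (default FALSE).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class \code{cohort_spec}.
#' @seealso \code{\link{simulate_cohort}}, \code{\link{default_coefficients}}
#' @export
cohort_spec <- function(n_per_group = c(20, 20),
                        grid = cord_grid(),
                        coefficient_functions = default_coefficients(),
                        eta_sd = 0.03,
                        eta_lengthscale_mm = 15,
                        eps_sd = 0.01,
                        metrics = "FA",
                        cross_metric_corr = 0,
                        include_sex = FALSE,
                        seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1))
  validate_grid(grid)
  if (any(eta_sd < 0) || any(eps_sd < 0)) stop("eta_sd and eps_sd must be >= 0")
  if (eta_lengthscale_mm <= 0) stop("eta_lengthscale_mm must be positive")
  if (abs(cross_metric_corr) > 1) stop("|cross_metric_corr| must be <= 1")
  ok <- c("FA", "RD", "MD", "AD", "CSA")
  if (!all(metrics %in% ok))
    stop("metrics must be a subset of: ", paste(ok, collapse = ", "))
  spec <- list(n_per_group = as.integer(n_per_group), grid = grid,
               coefficient_functions = coefficient_functions,
               eta_sd = eta_sd, eta_lengthscale_mm = eta_lengthscale_mm,
               eps_sd = eps_sd, metrics = metrics,
               cross_metric_corr = cross_metric_corr,
               include_sex = include_sex, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Default true coefficient curves
#'
#' A mildly declining FA-like intercept along the cord (healthy controls
#' show a rostral-to-caudal FA decrease), a configurable disease effect,
#' and small age and scanner effects.
#'
#' @param group_effect Function of s giving the disease-status coefficient
#'   curve, or a single number used as a constant. Default 0 (null).
#' @param intercept,age,scanner,sex Other coefficient curves (functions of
#'   s or constants).
#' @return Named list of functions of s.
#' @export
default_coefficients <- function(group_effect = 0,
                                 intercept = function(s) 0.55 - 0.001 * s,
                                 age = -2e-4, scanner = 0.005, sex = 0) {
  as_fun <- function(v) if (is.function(v)) v else {
    force(v); function(s) rep(v, length(s))
  }
  list(intercept = as_fun(intercept), group = as_fun(group_effect),
       age_years = as_fun(age), scanner = as_fun(scanner), sex = as_fun(sex))
}

#' Default coefficient curves on the CSA scale
#'
#' Cord cross-sectional area declines mildly from C2 caudally in healthy
#' cords (~70-80 mm^2 at C2); disease-related atrophy enters through
#' \code{group_effect} (mm^2, typically negative).
#'
#' @inheritParams default_coefficients
#' @return Named list of functions of s.
#' @export
csa_coefficients <- function(group_effect = 0,
                             intercept = function(s) 76 - 0.08 * s,
                             age = -0.08, scanner = 0.5, sex = 0) {
  default_coefficients(group_effect, intercept, age, scanner, sex)
}

#' Level-localized effect curve
#'
#' Returns a function of arc length equal to \code{amplitude} on the grid
#' positions of the given vertebral levels and 0 elsewhere. Convenient for
#' programming level-localized group effects.
#'
#' @param grid A \code{\link{cord_grid}}.
#' @param levels Level labels carrying the effect.
#' @param amplitude Effect size on those levels.
#' @return Function of s.
#' @export
level_effect <- function(grid, levels, amplitude) {
  idx <- grid_level_index(grid, levels)
  lo <- min(grid$positions[idx]); hi <- max(grid$positions[idx])
  force(amplitude)
  function(s) ifelse(s >= lo - 1e-9 & s <= hi + 1e-9, amplitude, 0)
}

# squared-exponential covariance factor (upper-triangular chol with jitter)
se_kernel_chol <- function(positions, sd, lengthscale) {
  d <- outer(positions, positions, "-")
  K <- sd^2 * exp(-d^2 / (2 * lengthscale^2))
  chol(K + diag(1e-10 * max(sd^2, 1), length(positions)))
}

# simulate subject covariates for a two-group cohort; onset split 10/5/5
# (upper limb : lower limb : bulbar) as in typical limb-majority ALS cohorts
simulate_covariates <- function(n_per_group) {
  n_als <- n_per_group[1]; n_ctl <- n_per_group[2]; n <- n_als + n_ctl
  group <- c(rep(1L, n_als), rep(0L, n_ctl))
  onset <- rep("none", n)
  if (n_als > 0) {
    pool <- rep(c("upper_limb", "lower_limb", "bulbar"),
                times = pmax(1, round(n_als * c(0.5, 0.25, 0.25))))
    onset[seq_len(n_als)] <- sample(pool, n_als, replace = length(pool) < n_als)
  }
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    age_years = round(pmax(20, stats::rnorm(n, 57.5, 10)), 1),
    scanner = sample(0:1, n, replace = TRUE),
    sex = sample(0:1, n, replace = TRUE),
    onset_site = onset,
    stringsAsFactors = FALSE
  )
}

design_columns <- function(include_sex) {
  c("intercept", "group", "age_years", "scanner", if (include_sex) "sex")
}

cohort_design_matrix <- function(covariates, include_sex = FALSE) {
  cols <- design_columns(include_sex)
  X <- cbind(intercept = 1, as.matrix(covariates[setdiff(cols, "intercept")]))
  colnames(X) <- cols
  rownames(X) <- covariates$subject_id
  X
}

# true mean n x M for one metric given its coefficient function list
true_mean_matrix <- function(X, cf, positions) {
  miss <- setdiff(colnames(X), names(cf))
  if (length(miss) > 0)
    stop("missing coefficient function(s) for covariate(s): ",
         paste(miss, collapse = ", "))
  B <- vapply(colnames(X), function(nm) cf[[nm]](positions),
              numeric(length(positions)))   # M x p
  X %*% t(B)
}

#' Simulate an along-cord cohort
#'
#' Draws per-subject metric profiles from the varying coefficient
#' generative model of \code{\link{cohort_spec}}: deterministic mean
#' \eqn{x_i^T B(s)}, a smooth Gaussian-process subject curve
#' \eqn{\eta_i(s)} (squared-exponential covariance, correlated across
#' metrics by \code{cross_metric_corr}) and iid measurement noise.
#' Deterministic given the spec (including its seed).
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param covariates Optional pre-built covariate data frame (columns
#'   \code{subject_id, group, age_years, scanner, sex, onset_site});
#'   simulated from \code{spec} when NULL.
#' @param timepoint Label, one of \code{"baseline"}, \code{"month6"},
#'   \code{"month12"}.
#' @return A \code{cord_cohort}: list with \code{grid}, \code{covariates},
#'   \code{values} (named list of n x M matrices, one per metric),
#'   \code{metric_names}, \code{timepoint}.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = c(5, 5), seed = 7))
#' dim(cohort$values$FA)  # 10 x 50
#' @export
simulate_cohort <- function(spec, covariates = NULL, timepoint = "baseline") {
  stopifnot(inherits(spec, "cohort_spec"))
  timepoint <- match.arg(timepoint, c("baseline", "month6", "month12"))
  set.seed(spec$seed)
  if (is.null(covariates)) covariates <- simulate_covariates(spec$n_per_group)
  X <- cohort_design_matrix(covariates, spec$include_sex)
  pos <- spec$grid$positions
  n <- nrow(X); M <- length(pos); k <- length(spec$metrics)

  cf_list <- per_metric_coefficients(spec)
  eta_sd <- metric_param(spec$eta_sd, spec$metrics)
  eps_sd <- metric_param(spec$eps_sd, spec$metrics)
  Lt <- se_kernel_chol(pos, 1, spec$eta_lengthscale_mm)
  Ck <- cross_metric_chol(k, spec$cross_metric_corr)

  # eta: n x M x k, unit variance, metric-correlated at each position
  Z <- array(stats::rnorm(n * M * k), dim = c(n, M, k))
  eta <- array(0, dim = c(n, M, k))
  for (j in seq_len(k)) {
    mix <- matrix(0, n, M)
    for (l in seq_len(k)) mix <- mix + Ck[j, l] * Z[, , l]
    eta[, , j] <- mix %*% Lt
  }
  values <- vector("list", k); names(values) <- spec$metrics
  for (j in seq_len(k)) {
    mu <- true_mean_matrix(X, cf_list[[spec$metrics[j]]], pos)
    eps <- matrix(stats::rnorm(n * M, sd = eps_sd[j]), n, M)
    Y <- mu + eta_sd[j] * eta[, , j] + eps
    dimnames(Y) <- list(covariates$subject_id, NULL)
    values[[j]] <- Y
  }
  new_cord_cohort(spec$grid, covariates, values, timepoint)
}

# scalar-or-named per-metric parameter
metric_param <- function(p, metrics) {
  if (length(p) == 1 && is.null(names(p))) return(rep(p, length(metrics)))
  out <- p[metrics]
  if (anyNA(out)) stop("per-metric parameter missing entries for: ",
                       paste(metrics[is.na(out)], collapse = ", "))
  unname(out)
}

# expand coefficient_functions to a per-metric list
per_metric_coefficients <- function(spec) {
  cf <- spec$coefficient_functions
  if (all(vapply(cf, is.function, logical(1)))) {
    out <- rep(list(cf), length(spec$metrics))
  } else {
    miss <- setdiff(spec$metrics, names(cf))
    if (length(miss) > 0)
      stop("no coefficient functions for metric(s): ",
           paste(miss, collapse = ", "))
    out <- cf[spec$metrics]
  }
  names(out) <- spec$metrics
  out
}

cross_metric_chol <- function(k, rho) {
  if (k == 1) return(matrix(1, 1, 1))
  R <- matrix(rho, k, k); diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, k)))
  t(ch)  # lower triangular mixing matrix
}

new_cord_cohort <- function(grid, covariates, values, timepoint = "baseline") {
  obj <- list(grid = grid, covariates = covariates, values = values,
              metric_names = names(values), timepoint = timepoint)
  class(obj) <- "cord_cohort"
  obj
}

#' @export
print.cord_cohort <- function(x, ...) {
  cat("Along-cord cohort (", x$timepoint, "): ",
      nrow(x$covariates), " subjects (",
      sum(x$covariates$group == 1), " patients / ",
      sum(x$covariates$group == 0), " controls), metrics: ",
      paste(x$metric_names, collapse = ", "), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Simulate a paired longitudinal cohort
#'
#' Draws baseline and follow-up profile sets for the same subjects. The
#' follow-up mean adds the change coefficient curves
#' \eqn{x_i^T \Delta B(s)} to the baseline mean; the subject curve process
#' is shared between timepoints with correlation \code{timepoint_corr}
#' (the within-subject stability of the smooth curve component), and
#' measurement error is drawn fresh.
#'
#' @param spec A \code{\link{cohort_spec}} (single- or multi-metric).
#' @param change_functions Coefficient-function list (same structure as
#'   \code{spec$coefficient_functions}) giving the true change curves
#'   \eqn{\Delta B(s)}; default all-zero.
#' @param timepoint_corr Between-timepoint correlation of the subject
#'   curve process, in [0, 1].
#' @param followup_label Timepoint label of the follow-up set.
#' @return List with elements \code{baseline} and \code{followup}, both
#'   \code{cord_cohort}s over the same subjects.
#' @export
simulate_longitudinal <- function(spec, change_functions = NULL,
                                  timepoint_corr = 0.8,
                                  followup_label = "month12") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (timepoint_corr < 0 || timepoint_corr > 1)
    stop("timepoint_corr must be in [0, 1]")
  set.seed(spec$seed)
  covariates <- simulate_covariates(spec$n_per_group)
  X <- cohort_design_matrix(covariates, spec$include_sex)
  pos <- spec$grid$positions
  n <- nrow(X); M <- length(pos); k <- length(spec$metrics)
  cf_list <- per_metric_coefficients(spec)
  dcf <- change_functions
  eta_sd <- metric_param(spec$eta_sd, spec$metrics)
  eps_sd <- metric_param(spec$eps_sd, spec$metrics)
  Lt <- se_kernel_chol(pos, 1, spec$eta_lengthscale_mm)
  Ck <- cross_metric_chol(k, spec$cross_metric_corr)

  draw_eta <- function() {
    Z <- array(stats::rnorm(n * M * k), dim = c(n, M, k))
    eta <- array(0, dim = c(n, M, k))
    for (j in seq_len(k)) {
      mix <- matrix(0, n, M)
      for (l in seq_len(k)) mix <- mix + Ck[j, l] * Z[, , l]
      eta[, , j] <- mix %*% Lt
    }
    eta
  }
  eta1 <- draw_eta(); eta_new <- draw_eta()
  eta2 <- timepoint_corr * eta1 + sqrt(1 - timepoint_corr^2) * eta_new

  build <- function(eta, add_change, timepoint) {
    values <- vector("list", k); names(values) <- spec$metrics
    for (j in seq_len(k)) {
      mu <- true_mean_matrix(X, cf_list[[spec$metrics[j]]], pos)
      if (add_change && !is.null(dcf)) {
        dj <- if (all(vapply(dcf, is.function, logical(1)))) dcf
              else dcf[[spec$metrics[j]]]
        if (!is.null(dj)) mu <- mu + true_mean_matrix(X, dj, pos)
      }
      eps <- matrix(stats::rnorm(n * M, sd = eps_sd[j]), n, M)
      Y <- mu + eta_sd[j] * eta[, , j] + eps
      dimnames(Y) <- list(covariates$subject_id, NULL)
      values[[j]] <- Y
    }
    new_cord_cohort(spec$grid, covariates, values, timepoint)
  }
  list(baseline = build(eta1, FALSE, "baseline"),
       followup = build(eta2, TRUE, followup_label))
}

#' Simulate ALSFRS-R style clinical score tables
#'
#' Generates integer item scores (items 1-12, each 0-4) whose spinal
#' sub-score (items 4-12) is coupled to a chosen imaging summary with a
#' target population correlation before integer rounding: a continuous
#' sub-score is drawn as a linear-Gaussian function of the standardized
#' summary, split evenly across the nine spinal items with zero-sum item
#' noise, then clipped to [0, 4] and rounded. Bulbar items 1-3 are
#' independent. An upper-motor-neuron burden score (0-6) is emitted for
#' patients.
#'
#' @param cohort A \code{cord_cohort}.
#' @param target_corr Target correlation in [-1, 1] between the continuous
#'   spinal sub-score and the imaging summary.
#' @param summary Either a numeric vector (one value per subject) or a list
#'   \code{list(metric=, levels=)} naming the per-subject profile mean to
#'   couple to (default mean FA over all levels).
#' @param seed Integer seed.
#' @param subscore_mean,subscore_sd Location/scale of the continuous
#'   spinal sub-score (0-36 scale) before clipping.
#' @return Data frame of class \code{clinical_table}: subject_id,
#'   timepoint, item_1..item_12, umn.
#' @export
simulate_clinical_scores <- function(cohort, target_corr = 0.5,
                                     summary = list(metric = NULL, levels = NULL),
                                     seed = 1L,
                                     subscore_mean = 23, subscore_sd = 5) {
  stopifnot(inherits(cohort, "cord_cohort"))
  if (abs(target_corr) > 1) stop("|target_corr| must be <= 1")
  n <- nrow(cohort$covariates)
  if (n < 1) stop("cohort is empty")
  set.seed(seed)

  if (is.numeric(summary)) {
    sv <- summary
    if (length(sv) != n) stop("summary vector length must equal #subjects")
  } else {
    metric <- summary$metric %||% cohort$metric_names[1]
    levels <- summary$levels %||% unique(cohort$grid$levels)
    idx <- grid_level_index(cohort$grid, levels)
    sv <- rowMeans(cohort$values[[metric]][, idx, drop = FALSE], na.rm = TRUE)
  }
  z <- if (stats::sd(sv) > 0) (sv - mean(sv)) / stats::sd(sv) else rep(0, n)
  latent <- target_corr * z + sqrt(1 - target_corr^2) * stats::rnorm(n)
  sub_cont <- subscore_mean + subscore_sd * latent   # continuous 0-36 scale

  # split across items 4-12 with zero-sum noise so the pre-rounding item sum
  # keeps exactly the target correlation
  items <- matrix(NA_integer_, n, 12,
                  dimnames = list(NULL, paste0("item_", 1:12)))
  for (i in seq_len(n)) {
    d <- stats::rnorm(9, sd = 0.3); d <- d - mean(d)
    sp <- pmin(4, pmax(0, sub_cont[i] / 9 + d))
    items[i, 4:12] <- as.integer(round(sp))
    bulbar <- pmin(4, pmax(0, stats::rnorm(3, 3.4, 0.6)))
    items[i, 1:3] <- as.integer(round(bulbar))
  }
  umn <- ifelse(cohort$covariates$group == 1,
                pmin(6L, pmax(0L, as.integer(round(stats::rnorm(n, 3, 1.5))))),
                0L)
  out <- data.frame(subject_id = cohort$covariates$subject_id,
                    timepoint = cohort$timepoint, items, umn = umn,
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
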