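#' Wild-bootstrap corrected local test along the cord
#'
#' Tests whether the varying coefficient(s) of the tested covariate are
#' zero at each position along the cord. The local statistic is the Wald
#' form on the local-linear WLS estimate with cluster-robust covariance;
#' p-values come from a wild bootstrap under the null model (tested
#' columns removed): each bootstrap sample multiplies every subject's
#' null-model residual curve by a single mean-0 variance-1 multiplier,
#' refits the full model, and records both the local statistic and its
#' curve-wide maximum. The family-wise corrected p-value at position s
#' compares the observed statistic with the bootstrap distribution of the
#' maximum over all grid positions, correcting for multiple testing along
#' the cord.
#'
#' With two metrics (e.g. FA and CSA) the statistic is the joint Wald form
#' on the stacked tested coefficients with their cross-metric covariance
#' estimated from paired residual curves; the same per-subject multiplier
#' is applied to both metrics' residual curves. Metrics are standardized
#' per position by their pooled standard deviation by default, making
#' unitless FA and CSA in mm^2 commensurate (the statistic is invariant to
#' this scaling up to numerical ridge effects; the coefficient curves are
#' reported on the standardized scale).
#'
#' @param formula RHS design formula over covariates.
#' @param cohort A \code{cord_cohort}.
#' @param metric One metric name, or two for the joint multimodal test.
#' @param test Tested covariate name(s); never the intercept.
#' @param bandwidth Bandwidth in mm.
#' @param kernel Kernel name.
#' @param B Number of bootstrap samples (>= 100 recommended for reported
#'   p-values; smaller allowed for quick checks).
#' @param multiplier \code{"rademacher"} (default) or \code{"gaussian"}.
#' @param seed Integer seed (mandatory: bootstrap results must be
#'   reproducible).
#' @param standardize Per-position pooled-SD standardization (default on
#'   for multimodal, off otherwise).
#' @param min_subjects Minimum contributing subjects per position.
#' @return Object of class \code{vcm_test}: grid, statistic T(s),
#'   p_pointwise(s), p_corrected(s), tested coefficient curves, bootstrap
#'   max statistics, df, and run metadata.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = c(10, 10), seed = 2))
#' tst <- vcm_test(~ group + age_years + scanner, cohort, B = 100, seed = 9)
#' min(tst$p_corrected)
#' @export
vcm_test <- function(formula, cohort, metric = cohort$metric_names[1],
                     test = "group", bandwidth = 6,
                     kernel = c("epanechnikov", "gaussian"), B = 1000,
                     multiplier = c("rademacher", "gaussian"), seed,
                     standardize = length(metric) > 1, min_subjects = 3) {
  stopifnot(inherits(cohort, "cord_cohort"))
  kernel <- match.arg(kernel)
  multiplier <- match.arg(multiplier)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for bootstrap inference")
  if (B < 1) stop("B must be >= 1")
  X <- vcm_design(formula, cohort$covariates)
  idx <- resolve_test_index(colnames(X), test)
  pos <- cohort$grid$positions
  n <- nrow(X); M <- length(pos)
  k <- length(metric); q <- length(idx)

  Ylist <- lapply(metric, function(m) {
    Y <- cohort$values[[m]]
    if (is.null(Y)) stop("cohort has no metric '", m, "'")
    Y
  })
  names(Ylist) <- metric
  if (k > 1) {
    bad <- unique(unlist(lapply(Ylist, function(Y)
      cohort$covariates$subject_id[rowSums(is.na(Y)) > 0])))
    if (length(bad) > 0)
      stop("multimodal test requires complete profiles; missing data for: ",
           paste(bad, collapse = ", "))
  }
  if (standardize)
    Ylist <- lapply(Ylist, function(Y) {
      sdv <- apply(Y, 2, stats::sd, na.rm = TRUE)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      sweep(Y, 2, sdv, "/")
    })

  has_na <- any(vapply(Ylist, anyNA, logical(1)))
  set.seed(as.integer(seed))
  res <- if (has_na)
    wild_bootstrap_general(Ylist, X, idx, pos, bandwidth, kernel, B,
                           multiplier, min_subjects)
  else
    wild_bootstrap_fast(Ylist, X, idx, pos, bandwidth, kernel, B, multiplier)

  p_pointwise <- (1 + res$exceed_pt) / (B + 1)
  p_corrected <- (1 + vapply(res$T_obs, function(t)
    if (is.na(t)) NA_real_ else sum(res$max_stats >= t), numeric(1))) / (B + 1)

  out <- list(grid = cohort$grid, statistic = res$T_obs,
              p_pointwise = p_pointwise, p_corrected = p_corrected,
              tested_coefficients = res$b_obs,
              max_stats = res$max_stats, n_bootstrap = B,
              multiplier = multiplier, seed = as.integer(seed),
              test = colnames(X)[idx], metric = metric,
              df = k * q, bandwidth = bandwidth, kernel = kernel,
              standardized = standardize, n = n)
  class(out) <- "vcm_test"
  out
}

# fast complete-data engine
wild_bootstrap_fast <- function(Ylist, X, idx, pos, bandwidth, kernel, B,
                                multiplier) {
  n <- nrow(X); M <- length(pos); k <- length(Ylist); q <- length(idx)
  Aw <- local_smoother(pos, bandwidth, kernel)
  AiXt <- qr.coef(qr(X), diag(n))
  Ainv <- tcrossprod(AiXt)
  X0 <- X[, -idx, drop = FALSE]
  A0iX0t <- qr.coef(qr(X0), diag(n))
  H <- X %*% Ainv[, idx, drop = FALSE]            # n x q

  b_obs <- vector("list", k); E_obs <- vector("list", k)
  F0eff <- vector("list", k); Reff <- vector("list", k)
  for (j in seq_len(k)) {
    Yeff <- Ylist[[j]] %*% Aw
    Bh <- AiXt %*% Yeff
    b_obs[[j]] <- Bh[idx, , drop = FALSE]
    E_obs[[j]] <- Yeff - X %*% Bh
    B0 <- A0iX0t %*% Yeff
    Fit0 <- X0 %*% B0                              # null fitted curves
    R <- Ylist[[j]] - Fit0                         # null residual curves
    F0eff[[j]] <- Fit0 %*% Aw
    Reff[[j]] <- R %*% Aw
  }
  T_obs <- stacked_wald(b_obs, E_obs, H, k, q)

  exceed_pt <- numeric(M); max_stats <- numeric(B)
  bb <- vector("list", k); ee <- vector("list", k)
  for (bi in seq_len(B)) {
    m <- if (multiplier == "rademacher") sample(c(-1, 1), n, replace = TRUE)
         else stats::rnorm(n)
    for (j in seq_len(k)) {
      Yeff_b <- F0eff[[j]] + m * Reff[[j]]
      Bh <- AiXt %*% Yeff_b
      bb[[j]] <- Bh[idx, , drop = FALSE]
      ee[[j]] <- Yeff_b - X %*% Bh
    }
    Tb <- stacked_wald(bb, ee, H, k, q)
    max_stats[bi] <- max(Tb, na.rm = TRUE)
    exceed_pt <- exceed_pt + (Tb >= T_obs)
  }
  list(T_obs = T_obs, exceed_pt = exceed_pt, max_stats = max_stats,
       b_obs = do.call(rbind, b_obs))
}

# Wald statistic per position for tested coefficients stacked across
# metrics, with cluster-robust covariance Sigma(s) = sum_i h_i h_i' e e'
stacked_wald <- function(blist, elist, H, k, q, tiny = 1e-24) {
  M <- ncol(blist[[1]])
  if (k == 1 && q == 1) {
    b <- blist[[1]][1, ]
    se2 <- colSums(H[, 1]^2 * elist[[1]]^2)
    out <- ifelse(se2 > tiny, b^2 / se2, ifelse(b^2 > tiny, Inf, 0))
    return(out)
  }
  if (k == 2 && q == 1) {
    h2 <- H[, 1]^2
    b1 <- blist[[1]][1, ]; b2 <- blist[[2]][1, ]
    s11 <- colSums(h2 * elist[[1]]^2)
    s22 <- colSums(h2 * elist[[2]]^2)
    s12 <- colSums(h2 * elist[[1]] * elist[[2]])
    tr <- s11 + s22
    det <- s11 * s22 - s12^2
    lam <- ifelse(det < 1e-10 * tr^2, 1e-8 * pmax(tr, 0), 0)
    detr <- (s11 + lam) * (s22 + lam) - s12^2
    out <- ((s22 + lam) * b1^2 - 2 * s12 * b1 * b2 + (s11 + lam) * b2^2) / detr
    zero <- !(tr > tiny)
    out[zero] <- ifelse(b1[zero]^2 + b2[zero]^2 > tiny, Inf, 0)
    return(pmax(out, 0))
  }
  # general case: per-position quadratic form
  out <- numeric(M)
  for (s in seq_len(M)) {
    G <- do.call(cbind, lapply(seq_len(k), function(j) H * elist[[j]][, s]))
    b <- unlist(lapply(blist, function(bm) bm[, s]))
    out[s] <- wald_quadform(b, crossprod(G))
  }
  out
}

# slow path for profiles with missing values (single metric)
wild_bootstrap_general <- function(Ylist, X, idx, pos, bandwidth, kernel, B,
                                   multiplier, min_subjects) {
  if (length(Ylist) > 1)
    stop("multimodal test requires complete profiles")
  Y <- Ylist[[1]]
  n <- nrow(X); M <- length(pos)
  X0 <- X[, -idx, drop = FALSE]
  T_of <- function(Ymat) {
    g <- vcm_fit_general(Ymat, X, pos, bandwidth, kernel, min_subjects)
    T <- numeric(M)
    for (s in seq_len(M)) {
      b <- g$Bhat[idx, s]
      Sg <- matrix(g$cov[idx, idx, s], length(idx), length(idx))
      T[s] <- if (anyNA(b) || anyNA(Sg)) NA_real_ else wald_quadform(b, Sg)
    }
    list(T = T, b = g$Bhat[idx, , drop = FALSE])
  }
  obs <- T_of(Y)
  g0 <- vcm_fit_general(Y, X0, pos, bandwidth, kernel, min_subjects)
  Fit0 <- X0 %*% g0$Bhat
  R <- Y - Fit0
  exceed_pt <- numeric(M); max_stats <- numeric(B)
  for (bi in seq_len(B)) {
    m <- if (multiplier == "rademacher") sample(c(-1, 1), n, replace = TRUE)
         else stats::rnorm(n)
    Tb <- T_of(Fit0 + m * R)$T
    max_stats[bi] <- max(Tb, na.rm = TRUE)
    exceed_pt <- exceed_pt + ifelse(is.na(Tb) | is.na(obs$T), NA, Tb >= obs$T)
  }
  list(T_obs = obs$T, exceed_pt = exceed_pt, max_stats = max_stats,
       b_obs = obs$b)
}

#' @export
print.vcm_test <- function(x, alpha = 0.05, ...) {
  cat("Wild-bootstrap local test: metric ", paste(x$metric, collapse = "+"),
      ", tested: ", paste(x$test, collapse = ", "),
      " (df ", x$df, ")\n", sep = "")
  cat(x$n, " subjects, B = ", x$n_bootstrap, " (", x$multiplier,
      " multipliers, seed ", x$seed, "), bandwidth ", x$bandwidth,
      " mm\n", sep = "")
  pc <- x$p_corrected
  sig <- which(!is.na(pc) & pc < alpha)
  cat("min corrected p = ", format(min(pc, na.rm = TRUE), digits = 3),
      " at ", x$grid$levels[which.min(pc)], "\n", sep = "")
  if (length(sig) > 0)
    cat("significant (corrected p < ", alpha, ") at levels: ",
        paste(unique(x$grid$levels[sig]), collapse = ", "), "\n", sep = "")
  else cat("no position significant at corrected p < ", alpha, "\n", sep = "")
  invisible(x)
}

#' Plot an along-cord test curve
#'
#' Two panels: the local statistic T(s) and the pointwise/corrected
#' p-value profiles on a -log10 scale with the significance threshold
#' marked (the tabular twin of an along-cord p-value heat map).
#'
#' @param x A \code{vcm_test}.
#' @param alpha Reference level (default 0.05).
#' @param ... Passed to plot.
#' @export
plot.vcm_test <- function(x, alpha = 0.05, ...) {
  pos <- x$grid$positions
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(pos, x$statistic, type = "l", xlab = "position (mm)",
                 ylab = "T(s)", main = paste("local statistic,",
                                             paste(x$metric, collapse = "+")),
                 ...)
  bnd <- pos[cumsum(rle(x$grid$levels)$lengths)]
  graphics::abline(v = bnd, col = "grey90", lty = 3)
  lp <- -log10(cbind(x$p_pointwise, x$p_corrected))
  graphics::matplot(pos, lp, type = "l", lty = c(2, 1), col = c("grey50", 1),
                    xlab = "position (mm)", ylab = "-log10 p")
  graphics::abline(h = -log10(alpha), col = 2, lty = 3)
  graphics::abline(v = bnd, col = "grey90", lty = 3)
  graphics::legend("topright", c("pointwise", "corrected"), lty = c(2, 1),
                   col = c("grey50", 1), bty = "n")
  invisible(x)
}

#' Longitudinal change test along the cord
#'
#' Replaces the imaging metric by its within-subject change (follow-up
#' minus baseline) and runs the wild-bootstrap corrected local test on the
#' change profiles, testing the disease-status coefficient: the
#' group-difference-in-change analysis. Subjects present at only one
#' timepoint are excluded with a warning.
#'
#' @param formula RHS design formula.
#' @param baseline,followup \code{cord_cohort}s over (a superset of) the
#'   same subjects on the same grid.
#' @param metric Metric name.
#' @param ... Passed to \code{\link{vcm_test}} (bandwidth, B, seed, ...).
#' @return A \code{vcm_test} on the change profiles.
#' @export
vcm_change_test <- function(formula, baseline, followup,
                            metric = baseline$metric_names[1], ...) {
  stopifnot(inherits(baseline, "cord_cohort"),
            inherits(followup, "cord_cohort"))
  if (!isTRUE(all.equal(baseline$grid$positions, followup$grid$positions)))
    stop("baseline and follow-up grids do not match")
  ids <- intersect(baseline$covariates$subject_id,
                   followup$covariates$subject_id)
  n_drop <- length(union(baseline$covariates$subject_id,
                         followup$covariates$subject_id)) - length(ids)
  if (n_drop > 0)
    warning(n_drop, " unpaired subject(s) excluded from the change analysis")
  if (length(ids) < 3) stop("fewer than 3 paired subjects")
  ib <- match(ids, baseline$covariates$subject_id)
  if_ <- match(ids, followup$covariates$subject_id)
  change <- lapply(metric, function(m)
    followup$values[[m]][if_, , drop = FALSE] -
      baseline$values[[m]][ib, , drop = FALSE])
  names(change) <- metric
  chg <- new_cord_cohort(baseline$grid, baseline$covariates[ib, ], change,
                         timepoint = "change")
  vcm_test(formula, chg, metric = metric, ...)
}
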