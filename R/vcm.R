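#' @keywords internal
kernel_weight <- function(t, kernel = c("epanechnikov", "gaussian")) {
  kernel <- match.arg(kernel)
  switch(kernel,
         epanechnikov = ifelse(abs(t) < 1, 0.75 * (1 - t^2), 0),
         gaussian = stats::dnorm(t))
}

# Effective local-linear smoother weights.
# Column m0 of the returned M x M matrix holds weights a(.) such that
# sum_m a_m y(s_m) is the local-linear estimate of y at s_{m0}
# (sum a = 1, sum a*u = 0). Falls back to local-constant (Nadaraya-Watson)
# where the kernel support contains fewer than two distinct positions, so
# the bandwidth -> 0 limit is the per-position estimate.
local_smoother <- function(positions, bandwidth, kernel = "epanechnikov") {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  M <- length(positions)
  Aw <- matrix(0, M, M)
  for (m0 in seq_len(M)) {
    u <- positions - positions[m0]
    w <- kernel_weight(u / bandwidth, kernel)
    if (all(w <= 0)) w[m0] <- 1   # degenerate support: keep the point itself
    sup <- w > 0
    if (length(unique(positions[sup])) < 2) {
      Aw[, m0] <- w / sum(w)
    } else {
      S <- rbind(c(sum(w), sum(w * u)), c(sum(w * u), sum(w * u^2)))
      cvec <- solve(S, c(1, 0))
      Aw[, m0] <- w * (cvec[1] + cvec[2] * u)
    }
  }
  Aw
}

# design matrix from an RHS formula over the cohort covariates
vcm_design <- function(formula, covariates) {
  X <- stats::model.matrix(formula, covariates)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  if (qr(X)$rank < ncol(X)) stop("design matrix is not of full column rank")
  X
}

# complete-data core: local-linear WLS factorizes into per-subject
# smoothing (Yeff = Y Aw) followed by position-wise OLS across subjects.
# The OLS projector comes from a QR factorization (not normal equations)
# for numerical accuracy on poorly scaled designs.
vcm_core <- function(Y, X, Aw) {
  AiXt <- qr.coef(qr(X), diag(nrow(X)))   # (X'X)^{-1} X'
  Ainv <- tcrossprod(AiXt)
  Yeff <- Y %*% Aw
  Bhat <- AiXt %*% Yeff
  Eeff <- Yeff - X %*% Bhat
  list(Bhat = Bhat, Eeff = Eeff, Yeff = Yeff, Ainv = Ainv, AiXt = AiXt)
}

# cluster-robust sandwich covariance (complete data): p x p x M
vcm_cov_complete <- function(X, Ainv, Eeff) {
  p <- ncol(X); M <- ncol(Eeff)
  cov_arr <- array(NA_real_, c(p, p, M))
  for (s in seq_len(M)) {
    XE <- X * Eeff[, s]
    cov_arr[, , s] <- Ainv %*% crossprod(XE) %*% Ainv
  }
  cov_arr
}

# general path: joint local-linear WLS with (i, s_m) terms dropped at
# missing values; cluster-robust (by subject) sandwich covariance
vcm_fit_general <- function(Y, X, positions, bandwidth, kernel,
                            min_subjects = 3) {
  n <- nrow(Y); p <- ncol(X); M <- length(positions)
  B <- matrix(NA_real_, p, M)
  cov_arr <- array(NA_real_, c(p, p, M))
  for (m0 in seq_len(M)) {
    u <- positions - positions[m0]
    w <- kernel_weight(u / bandwidth, kernel)
    if (all(w <= 0)) w[m0] <- 1
    sup <- which(w > 0)
    obs <- !is.na(Y[, sup, drop = FALSE])
    subj <- which(rowSums(obs) > 0)
    if (length(subj) < min_subjects) next
    upos <- positions[sup][colSums(obs) > 0]
    slope <- length(unique(upos)) >= 2
    q <- if (slope) 2L * p else p
    ZtWZ <- matrix(0, q, q); ZtWy <- numeric(q)
    ulist <- vector("list", length(subj))
    for (ii in seq_along(subj)) {
      i <- subj[ii]
      mi <- sup[obs[i, ]]
      ui <- positions[mi] - positions[m0]
      wi <- w[mi]
      yi <- Y[i, mi]
      k <- length(mi)
      Zi <- matrix(rep(X[i, ], each = k), k, p)
      if (slope) Zi <- cbind(Zi, Zi * ui)
      ZtWZ <- ZtWZ + crossprod(Zi * wi, Zi)
      ZtWy <- ZtWy + crossprod(Zi * wi, yi)[, 1]
      ulist[[ii]] <- list(Zi = Zi, wi = wi, yi = yi)
    }
    beta <- tryCatch(solve(ZtWZ, ZtWy), error = function(e)
      stop("local system rank-deficient at position ",
           signif(positions[m0], 5), " mm"))
    B[, m0] <- beta[1:p]
    Hfull <- tryCatch(solve(ZtWZ), error = function(e)
      stop("local system rank-deficient at position ",
           signif(positions[m0], 5), " mm"))
    meat <- matrix(0, q, q)
    for (rec in ulist) {
      ei <- rec$yi - rec$Zi %*% beta
      uvec <- crossprod(rec$Zi * rec$wi, ei)[, 1]
      meat <- meat + tcrossprod(uvec)
    }
    full_cov <- Hfull %*% meat %*% Hfull
    cov_arr[, , m0] <- full_cov[1:p, 1:p, drop = FALSE]
  }
  list(Bhat = B, cov = cov_arr)
}

#' Fit a varying coefficient model to along-cord profiles
#'
#' Estimates the model \eqn{Y_i(s) = x_i^T B(s) + \eta_i(s) +
#' \epsilon_i(s)} by local-linear kernel weighted least squares: at each
#' grid position \eqn{s_0} the coefficient curves \eqn{B(s_0)} are the
#' intercept block of the minimizer of
#' \deqn{\sum_{i,m} K((s_m - s_0)/h)\,(Y_i(s_m) - x_i^T(\beta_0 +
#' \beta_1 (s_m - s_0)))^2.}
#' Per-position coefficient covariances use the cluster-robust (by
#' subject) sandwich built from the residual curves. With complete data
#' the fit factorizes into per-subject local-linear smoothing followed by
#' position-wise ordinary least squares across subjects, which is the fast
#' path; missing values drop the corresponding terms from the local sums,
#' and positions with fewer than \code{min_subjects} contributing subjects
#' are reported missing.
#'
#' @param formula RHS-only formula over covariate columns, e.g.
#'   \code{~ group + age_years + scanner}.
#' @param cohort A \code{cord_cohort}.
#' @param metric Metric name (default the cohort's first metric).
#' @param bandwidth Kernel bandwidth in mm. The local-linear fit reduces
#'   to per-position least squares as the bandwidth shrinks below the grid
#'   spacing.
#' @param kernel \code{"epanechnikov"} (default) or \code{"gaussian"}.
#' @param min_subjects Minimum contributing subjects per position.
#' @return Object of class \code{vcm} with components
#'   \code{coefficients} (p x M matrix of coefficient curves), \code{se}
#'   (p x M), \code{cov} (p x p x M), \code{fitted} (n x M),
#'   \code{residual_curves} (n x M, the estimated \eqn{\eta + \epsilon}
#'   curves), \code{grid}, \code{bandwidth}, \code{kernel}, \code{X}.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_per_group = c(10, 10), seed = 1))
#' fit <- vcm(~ group + age_years + scanner, cohort, bandwidth = 6)
#' dim(coef(fit))
#' @export
vcm <- function(formula, cohort, metric = cohort$metric_names[1],
                bandwidth = 6, kernel = c("epanechnikov", "gaussian"),
                min_subjects = 3) {
  stopifnot(inherits(cohort, "cord_cohort"))
  kernel <- match.arg(kernel)
  Y <- cohort$values[[metric]]
  if (is.null(Y)) stop("cohort has no metric '", metric, "'")
  if (any(rowSums(!is.na(Y)) == 0))
    stop("subject(s) with entirely missing profiles: ",
         paste(cohort$covariates$subject_id[rowSums(!is.na(Y)) == 0],
               collapse = ", "))
  X <- vcm_design(formula, cohort$covariates)
  pos <- cohort$grid$positions
  if (anyNA(Y)) {
    g <- vcm_fit_general(Y, X, pos, bandwidth, kernel, min_subjects)
    Bhat <- g$Bhat; cov_arr <- g$cov
  } else {
    Aw <- local_smoother(pos, bandwidth, kernel)
    core <- vcm_core(Y, X, Aw)
    Bhat <- core$Bhat
    cov_arr <- vcm_cov_complete(X, core$Ainv, core$Eeff)
  }
  dimnames(Bhat) <- list(colnames(X), NULL)
  se <- sqrt(pmax(apply(cov_arr, 3, diag), 0))
  se <- matrix(se, nrow(Bhat), ncol(Bhat), dimnames = dimnames(Bhat))
  fitted <- X %*% Bhat
  obj <- list(coefficients = Bhat, se = se, cov = cov_arr,
              fitted = fitted, residual_curves = Y - fitted,
              grid = cohort$grid, bandwidth = bandwidth, kernel = kernel,
              metric = metric, X = X, call = match.call())
  class(obj) <- "vcm"
  obj
}

#' @export
coef.vcm <- function(object, ...) object$coefficients

#' @export
fitted.vcm <- function(object, ...) object$fitted

#' @export
residuals.vcm <- function(object, ...) object$residual_curves

#' @export
print.vcm <- function(x, ...) {
  cat("Varying coefficient model: ", x$metric, " ~ ",
      paste(rownames(x$coefficients)[-1], collapse = " + "), "\n", sep = "")
  cat(nrow(x$X), " subjects, ", ncol(x$coefficients),
      " positions, bandwidth ", x$bandwidth, " mm (", x$kernel,
      " kernel)\n", sep = "")
  invisible(x)
}

#' @export
summary.vcm <- function(object, ...) {
  B <- object$coefficients
  tab <- data.frame(
    covariate = rownames(B),
    mean = rowMeans(B, na.rm = TRUE),
    min = apply(B, 1, min, na.rm = TRUE),
    max = apply(B, 1, max, na.rm = TRUE),
    mean_se = rowMeans(object$se, na.rm = TRUE),
    row.names = NULL
  )
  out <- list(table = tab, metric = object$metric,
              bandwidth = object$bandwidth, kernel = object$kernel,
              n = nrow(object$X), M = ncol(B))
  class(out) <- "summary.vcm"
  out
}

#' @export
print.summary.vcm <- function(x, ...) {
  cat("Varying coefficient model for ", x$metric, ": ", x$n, " subjects, ",
      x$M, " positions, bandwidth ", x$bandwidth, " mm\n\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
predict.vcm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  f <- stats::formula(object$call$formula)
  Xn <- stats::model.matrix(f, newdata)
  colnames(Xn)[colnames(Xn) == "(Intercept)"] <- "intercept"
  Xn[, rownames(object$coefficients), drop = FALSE] %*% object$coefficients
}

#' Plot coefficient curves of a fitted varying coefficient model
#'
#' Draws each coefficient curve with a pointwise band of plus/minus two
#' robust standard errors, with vertebral level boundaries marked.
#'
#' @param x A \code{vcm} object.
#' @param covariates Which coefficient curves to plot (default all but the
#'   intercept).
#' @param ... Passed to \code{matplot}.
#' @export
plot.vcm <- function(x, covariates = setdiff(rownames(x$coefficients),
                                             "intercept"), ...) {
  pos <- x$grid$positions
  old <- graphics::par(mfrow = c(length(covariates), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cv in covariates) {
    b <- x$coefficients[cv, ]; s <- x$se[cv, ]
    graphics::matplot(pos, cbind(b, b - 2 * s, b + 2 * s), type = "l",
                      lty = c(1, 2, 2), col = c(1, "grey50", "grey50"),
                      xlab = "position along cord (mm)",
                      ylab = paste0("B_", cv, "(s)"), main = cv, ...)
    graphics::abline(h = 0, col = "grey80")
    bnd <- pos[cumsum(rle(x$grid$levels)$lengths)]
    graphics::abline(v = bnd, col = "grey90", lty = 3)
  }
  invisible(x)
}

#' Local Wald statistic along the cord
#'
#' Computes \eqn{T(s) = \hat b(s)^T \hat\Sigma_b(s)^{-1} \hat b(s)} for
#' the tested coefficient sub-vector at each grid position, with a
#' ridge-stabilized inverse where the estimated covariance
#' block is numerically singular. Positions where both the coefficient and
#' its variance vanish give T = 0.
#'
#' @param fit A \code{vcm} object.
#' @param test Covariate names (or indices) to test; the intercept cannot
#'   be tested.
#' @return Numeric vector T(s), non-negative, one value per position.
#' @export
local_wald_statistic <- function(fit, test = "group") {
  stopifnot(inherits(fit, "vcm"))
  idx <- resolve_test_index(rownames(fit$coefficients), test)
  M <- ncol(fit$coefficients)
  T <- numeric(M)
  for (s in seq_len(M)) {
    b <- fit$coefficients[idx, s]
    Sg <- matrix(fit$cov[idx, idx, s], length(idx), length(idx))
    T[s] <- if (anyNA(b) || anyNA(Sg)) NA_real_ else wald_quadform(b, Sg)
  }
  T
}

# b' Sigma^{-1} b with ridge fallback; returns 0 when both b and Sigma vanish
wald_quadform <- function(b, Sg, tiny = 1e-20) {
  q <- length(b)
  scale <- mean(diag(Sg))
  if (!is.finite(scale) || scale <= tiny) {
    return(if (sum(b^2) <= tiny) 0 else Inf)
  }
  out <- tryCatch(drop(crossprod(b, solve(Sg, b))), error = function(e) NA)
  if (is.na(out) || out < 0 ||
      rcond_2x2(Sg) < 1e-12) {
    Sg2 <- Sg + diag(1e-8 * scale, q)
    out <- drop(crossprod(b, solve(Sg2, b)))
  }
  max(out, 0)
}

rcond_2x2 <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(1, 1))
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

resolve_test_index <- function(cols, test) {
  idx <- if (is.numeric(test)) as.integer(test) else match(test, cols)
  if (anyNA(idx)) stop("unknown tested covariate(s): ",
                       paste(test[is.na(match(test, cols))], collapse = ", "))
  if (any(cols[idx] == "intercept"))
    stop("the intercept cannot be a tested covariate")
  idx
}

#' Leave-one-subject-out bandwidth selection
#'
#' For each candidate bandwidth, fits the varying coefficient model with
#' each subject held out in turn and scores the squared error of the
#' predicted mean curve \eqn{x_i^T \hat B(s)} for the held-out subject;
#' returns the candidate minimizing the cross-validated error (ties go to
#' the smallest bandwidth).
#'
#' @param formula RHS design formula.
#' @param cohort A \code{cord_cohort}.
#' @param metric Metric name.
#' @param candidates Numeric vector of candidate bandwidths (mm).
#' @param kernel Kernel name.
#' @return The selected bandwidth, with the CV error profile attached as
#'   attribute \code{"cv"}.
#' @export
select_bandwidth <- function(formula, cohort, metric = cohort$metric_names[1],
                             candidates = c(3, 4.5, 6, 9, 12),
                             kernel = "epanechnikov") {
  if (length(candidates) < 1) stop("need at least one candidate bandwidth")
  candidates <- sort(candidates)
  if (length(candidates) == 1) return(candidates)
  Y <- cohort$values[[metric]]
  X <- vcm_design(formula, cohort$covariates)
  pos <- cohort$grid$positions
  n <- nrow(Y)
  cv <- vapply(candidates, function(h) {
    Aw <- local_smoother(pos, h, kernel)
    err <- 0
    for (i in seq_len(n)) {
      core <- vcm_core(Y[-i, , drop = FALSE], X[-i, , drop = FALSE], Aw)
      pred <- drop(X[i, , drop = FALSE] %*% core$Bhat)
      err <- err + mean((Y[i, ] - pred)^2, na.rm = TRUE)
    }
    err / n
  }, numeric(1))
  out <- candidates[which.min(cv)]
  attr(out, "cv") <- stats::setNames(cv, candidates)
  out
}
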