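#' ALSFRS-R sub-score
#'
#' Sum of selected ALSFRS-R item scores per subject. Items 1-12 give the
#' total (0-48); items 4-12 the spinal sub-score (0-36, bulbar questions
#' excluded); items 10-12 the respiratory sub-score (0-12).
#'
#' @param table A \code{clinical_table} (columns item_1..item_12).
#' @param items Integer item indices (default 4:12, the spinal sub-score).
#' @return Named integer vector (subject ids), NA with a warning for
#'   subjects missing any requested item.
#' @export
alsfrs_subscore <- function(table, items = 4:12) {
  cols <- paste0("item_", items)
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0) stop("items not present: ", paste(miss, collapse = ", "))
  m <- as.matrix(table[cols])
  bad <- rowSums(is.na(m)) > 0
  if (any(bad))
    warning(sum(bad), " subject(s) with missing items; sub-score set NA")
  out <- ifelse(bad, NA_integer_, as.integer(rowSums(m)))
  stats::setNames(out, table$subject_id)
}

#' Per-subject summary of a metric profile
#'
#' Unweighted mean of a profile over the grid positions of the requested
#' vertebral levels (e.g. mean FA over C2-C6, or at C2 only).
#'
#' @param profile A \code{metric_profile}.
#' @param levels Level labels to average over (default all).
#' @return A one-row data frame: subject_id, summary (name), value, tract,
#'   metric, levels.
#' @export
summarize_profile <- function(profile, levels = unique(profile$grid$levels)) {
  stopifnot(inherits(profile, "metric_profile"))
  idx <- grid_level_index(profile$grid, levels)
  v <- profile$values[idx]
  if (all(is.na(v))) stop("no non-missing values in the requested levels")
  data.frame(subject_id = profile$subject_id,
             summary = paste0("mean_", profile$metric, "_",
                              paste(range_label(levels), collapse = "_")),
             value = mean(v, na.rm = TRUE),
             tract = profile$tract, metric = profile$metric,
             levels = paste(levels, collapse = ","),
             stringsAsFactors = FALSE)
}

range_label <- function(levels) {
  if (length(levels) == 1) levels else c(levels[1], levels[length(levels)])
}

# per-subject level means from a cohort values matrix
cohort_level_means <- function(cohort, metric, levels = unique(cohort$grid$levels)) {
  idx <- grid_level_index(cohort$grid, levels)
  rowMeans(cohort$values[[metric]][, idx, drop = FALSE], na.rm = TRUE)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation between paired per-subject summaries, with
#' the usual t-transform p-value on n-2 degrees of freedom; incomplete
#' pairs are dropped pairwise. Zero variance in either argument flags the
#' result as undefined.
#'
#' @param x,y Numeric vectors.
#' @return List: r, p, n, undefined (logical flag).
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}

#' Paired t-test on per-subject means
#'
#' Classical two-tailed paired t-test on the within-subject differences
#' (follow-up minus baseline), as used for the longitudinal per-group
#' means. Zero-variance differences are flagged degenerate, with p = 0 for
#' a nonzero mean change and p = 1 otherwise.
#'
#' @param baseline,followup Paired numeric vectors.
#' @return List: t, df, p, mean_change, n, degenerate.
#' @export
paired_t_test <- function(baseline, followup) {
  ok <- stats::complete.cases(baseline, followup)
  b <- baseline[ok]; f <- followup[ok]
  n <- length(b)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- f - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = n - 1L,
                p = if (mean(d) == 0) 1 else 0,
                mean_change = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(f, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_change = unname(tt$estimate), n = n, degenerate = FALSE)
}

#' Site-of-onset subgroup summaries
#'
#' Per-subgroup mean, SD and n of a per-subject imaging summary, with
#' exploratory pairwise Welch two-sample comparisons (unadjusted p-values;
#' single-subject subgroups report the mean with a missing SD, empty
#' subgroups are omitted with a warning).
#'
#' @param values Named numeric vector of per-subject summaries.
#' @param covariates Covariate data frame with \code{subject_id} and
#'   \code{onset_site} ("none" marks controls).
#' @return List with \code{means} (data frame: subgroup, n, mean, sd) and
#'   \code{pairwise} (data frame: group1, group2, p, flagged exploratory).
#' @export
subgroup_means <- function(values, covariates) {
  lab <- covariates$onset_site
  lab[lab == "none"] <- "control"
  v <- values[match(covariates$subject_id, names(values))]
  if (all(is.na(match(covariates$subject_id, names(values)))))
    v <- values  # unnamed vector aligned with covariates
  groups <- unique(lab)
  rows <- list(); keep <- character(0)
  for (g in groups) {
    vi <- v[lab == g & !is.na(v)]
    if (length(vi) == 0) { warning("empty subgroup omitted: ", g); next }
    keep <- c(keep, g)
    rows[[g]] <- data.frame(subgroup = g, n = length(vi), mean = mean(vi),
                            sd = if (length(vi) > 1) stats::sd(vi) else NA_real_,
                            stringsAsFactors = FALSE)
  }
  means <- do.call(rbind, rows); rownames(means) <- NULL
  pw <- list()
  if (length(keep) > 1) {
    cmb <- utils::combn(keep, 2)
    for (ci in seq_len(ncol(cmb))) {
      g1 <- cmb[1, ci]; g2 <- cmb[2, ci]
      v1 <- v[lab == g1 & !is.na(v)]; v2 <- v[lab == g2 & !is.na(v)]
      p <- if (length(v1) > 1 && length(v2) > 1 &&
               (stats::sd(v1) > 0 || stats::sd(v2) > 0))
        stats::t.test(v1, v2)$p.value else NA_real_
      pw[[ci]] <- data.frame(group1 = g1, group2 = g2, p = p,
                             note = "Welch t, exploratory, unadjusted",
                             stringsAsFactors = FALSE)
    }
  }
  list(means = means,
       pairwise = if (length(pw) > 0) do.call(rbind, pw) else NULL)
}
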