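#' Default pipeline run configuration
#'
#' A complete configuration list for \code{\link{run_pipeline}}; YAML
#' configs are merged over these defaults, CLI flags over the YAML.
#' Extraction defaults mirror the processing choices the analyses assume:
#' tract confidence threshold 0.1, five-point (half-width 2) sliding mean
#' window, trilinear metric interpolation, C7 excluded from the grid.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    mode = "synthetic",
    output_dir = "cordvcm_run",
    seed = 1L,
    grid = list(levels = c("C2", "C3", "C4", "C5", "C6"),
                points_per_level = 10, spacing_mm = 1.5),
    simulate = list(
      n_per_group = c(20L, 20L),
      metrics = c("FA", "CSA"),
      eta_sd = c(FA = 0.03, CSA = 3),
      eps_sd = c(FA = 0.01, CSA = 1),
      eta_lengthscale_mm = 15,
      cross_metric_corr = 0.3,
      group_effect = list(
        FA = list(amplitude = -0.03, levels = c("C2", "C3")),
        CSA = list(amplitude = -5, levels = c("C2", "C3", "C4", "C5", "C6"))),
      clinical_target_corr = 0.6
    ),
    inputs = list(profiles = NULL, covariates = NULL, clinical = NULL,
                  profiles_followup = NULL),
    extraction = list(threshold = 0.1, window_half_width = 2,
                      interpolation = "trilinear"),
    model = list(covariates = c("group", "age_years", "scanner"),
                 bandwidth = 6, kernel = "epanechnikov",
                 B = 1000, multiplier = "rademacher"),
    analyses = list(cross_sectional = TRUE, multimodal = TRUE,
                    longitudinal = FALSE, correlations = TRUE,
                    subgroups = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; its entries override
#'   \code{\link{default_run_config}}.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(default_run_config(), yaml::read_yaml(path))
}

validate_config <- function(config) {
  bootstrap_on <- isTRUE(config$analyses$cross_sectional) ||
    isTRUE(config$analyses$multimodal) || isTRUE(config$analyses$longitudinal)
  if (bootstrap_on && (is.null(config$seed) || is.na(config$seed)))
    stop("a seed is mandatory when any bootstrap analysis is enabled")
  th <- config$extraction$threshold
  if (th < 0 || th > 1) stop("extraction threshold must be in [0, 1]")
  if (!config$mode %in% c("synthetic", "files"))
    stop("mode must be 'synthetic' or 'files'")
  invisible(config)
}

model_formula <- function(config) {
  stats::as.formula(paste("~", paste(config$model$covariates, collapse = " + ")))
}

write_test_tsv <- function(tst, path) {
  utils::write.table(
    data.frame(position_mm = tst$grid$positions, level = tst$grid$levels,
               T = tst$statistic, p_pointwise = tst$p_pointwise,
               p_corrected = tst$p_corrected),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the along-cord analysis pipeline
#'
#' Executes the configured stages end to end: cohort simulation (or
#' profile/covariate TSV input), per-metric cross-sectional
#' wild-bootstrap tests, the joint multimodal FA+CSA test, the
#' longitudinal change test when follow-up profiles are present, clinical
#' correlations and onset-site subgroup summaries. Writes per-analysis
#' results TSVs (the tabular twin of along-cord p-value heat maps), a
#' machine-readable metadata JSON, and a plain-text log to the output
#' directory. Fully deterministic under a fixed config and seed.
#'
#' @param config Configuration list (see
#'   \code{\link{default_run_config}}) or path to a YAML file.
#' @return Invisibly, a list with the output directory, the written file
#'   paths, and the analysis objects.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "run.log")
  loglines <- character(0)
  log <- function(...) {
    msg <- paste0(...)
    loglines <<- c(loglines, msg)
    writeLines(loglines, logfile)
  }
  stage <- "setup"
  out <- tryCatch({
    grid <- cord_grid(config$grid$levels, config$grid$points_per_level,
                      config$grid$spacing_mm)
    hw <- config$extraction$window_half_width
    log("grid: ", length(grid$positions), " positions, spacing ",
        grid$spacing_mm, " mm; sliding window ", 2 * hw + 1, " points (~",
        (2 * hw + 1) * grid$spacing_mm, " mm)")

    stage <- "input"
    followup <- NULL
    if (config$mode == "synthetic") {
      sim <- config$simulate
      cf <- list()
      for (m in sim$metrics) {
        ge <- sim$group_effect[[m]]
        gfun <- if (is.null(ge) || ge$amplitude == 0) 0
                else level_effect(grid, ge$levels, ge$amplitude)
        cf[[m]] <- if (m == "CSA") csa_coefficients(group_effect = gfun)
                   else default_coefficients(group_effect = gfun)
      }
      spec <- cohort_spec(n_per_group = unlist(sim$n_per_group), grid = grid,
                          coefficient_functions = cf,
                          eta_sd = unlist(sim$eta_sd),
                          eps_sd = unlist(sim$eps_sd),
                          eta_lengthscale_mm = sim$eta_lengthscale_mm,
                          metrics = sim$metrics,
                          cross_metric_corr = sim$cross_metric_corr,
                          seed = config$seed)
      cohort <- simulate_cohort(spec)
      clinical <- simulate_clinical_scores(
        cohort, target_corr = sim$clinical_target_corr,
        seed = config$seed + 1L)
      log("simulated cohort: ", nrow(cohort$covariates), " subjects, metrics ",
          paste(sim$metrics, collapse = ", "))
    } else {
      if (is.null(config$inputs$profiles) ||
          !file.exists(config$inputs$profiles))
        stop("profile TSV not found: ",
             config$inputs$profiles %||% "(not set)")
      cohort <- read_profiles(config$inputs$profiles,
                              config$inputs$covariates)
      clinical <- if (!is.null(config$inputs$clinical))
        read_clinical(config$inputs$clinical) else NULL
      if (!is.null(config$inputs$profiles_followup))
        followup <- read_profiles(config$inputs$profiles_followup,
                                  config$inputs$covariates)
      log("loaded cohort: ", nrow(cohort$covariates), " subjects")
    }
    paths <- character(0)
    pp <- file.path(config$output_dir, "profiles_baseline.tsv")
    write_profiles(cohort, pp)
    write_covariates(cohort$covariates,
                     file.path(config$output_dir, "covariates.tsv"))
    if (!is.null(clinical))
      write_clinical(clinical, file.path(config$output_dir, "clinical.tsv"))
    paths <- c(paths, pp)

    fml <- model_formula(config)
    mdl <- config$model
    tests <- list()

    if (isTRUE(config$analyses$cross_sectional)) {
      stage <- "cross-sectional analysis"
      for (m in cohort$metric_names) {
        tst <- vcm_test(fml, cohort, metric = m, test = "group",
                        bandwidth = mdl$bandwidth, kernel = mdl$kernel,
                        B = mdl$B, multiplier = mdl$multiplier,
                        seed = config$seed + 11L)
        f <- file.path(config$output_dir, paste0("analysis_", m, ".tsv"))
        write_test_tsv(tst, f); paths <- c(paths, f)
        tests[[m]] <- tst
        log("cross-sectional ", m, ": min corrected p = ",
            format(min(tst$p_corrected, na.rm = TRUE), digits = 4))
      }
    }
    if (isTRUE(config$analyses$multimodal) &&
        all(c("FA", "CSA") %in% cohort$metric_names)) {
      stage <- "multimodal analysis"
      tst <- vcm_test(fml, cohort, metric = c("FA", "CSA"), test = "group",
                      bandwidth = mdl$bandwidth, kernel = mdl$kernel,
                      B = mdl$B, multiplier = mdl$multiplier,
                      seed = config$seed + 12L)
      f <- file.path(config$output_dir, "analysis_FA_CSA_joint.tsv")
      write_test_tsv(tst, f); paths <- c(paths, f)
      tests$FA_CSA_joint <- tst
      log("multimodal FA+CSA: min corrected p = ",
          format(min(tst$p_corrected, na.rm = TRUE), digits = 4))
    }
    if (isTRUE(config$analyses$longitudinal) && !is.null(followup)) {
      stage <- "longitudinal analysis"
      for (m in cohort$metric_names) {
        tst <- vcm_change_test(fml, cohort, followup, metric = m,
                               bandwidth = mdl$bandwidth, kernel = mdl$kernel,
                               B = mdl$B, multiplier = mdl$multiplier,
                               seed = config$seed + 13L)
        f <- file.path(config$output_dir, paste0("analysis_change_", m, ".tsv"))
        write_test_tsv(tst, f); paths <- c(paths, f)
        tests[[paste0("change_", m)]] <- tst
      }
    }
    correlations <- NULL
    if (isTRUE(config$analyses$correlations) && !is.null(clinical)) {
      stage <- "clinical correlations"
      sub <- alsfrs_subscore(clinical, 4:12)
      rows <- list()
      for (m in cohort$metric_names) {
        for (lv in list(unique(grid$levels), "C2")) {
          smry <- cohort_level_means(cohort, m, lv)
          pc <- pearson_correlation(smry, sub)
          rows[[length(rows) + 1L]] <- list(
            summary = paste0("mean_", m, "_", paste(range_label(lv),
                                                    collapse = "_")),
            r = pc$r, p = pc$p, n = pc$n)
        }
      }
      correlations <- rows
      jsonlite::write_json(rows,
                           file.path(config$output_dir, "correlations.json"),
                           auto_unbox = TRUE, digits = NA)
      paths <- c(paths, file.path(config$output_dir, "correlations.json"))
    }
    subgroups <- NULL
    if (isTRUE(config$analyses$subgroups) &&
        "onset_site" %in% names(cohort$covariates)) {
      stage <- "subgroup summaries"
      smry <- stats::setNames(cohort_level_means(cohort,
                                                 cohort$metric_names[1]),
                              cohort$covariates$subject_id)
      subgroups <- subgroup_means(smry, cohort$covariates)
      utils::write.table(subgroups$means,
                         file.path(config$output_dir, "subgroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, file.path(config$output_dir, "subgroups.tsv"))
    }
    stage <- "metadata"
    meta <- list(package_version = as.character(utils::packageVersion("cordvcm")),
                 seed = config$seed, mode = config$mode,
                 bandwidth = mdl$bandwidth, kernel = mdl$kernel,
                 B = mdl$B, multiplier = mdl$multiplier,
                 window_points = 2 * hw + 1,
                 window_mm = (2 * hw + 1) * grid$spacing_mm,
                 threshold = config$extraction$threshold,
                 covariates = mdl$covariates)
    jsonlite::write_json(meta, file.path(config$output_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    log("done")
    list(output_dir = config$output_dir, paths = paths,
         cohort = cohort, tests = tests,
         correlations = correlations, subgroups = subgroups,
         config = config)
  }, error = function(e) {
    log("ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}

#' Consolidated report from a completed run
#'
#' Reads the artifacts of a \code{\link{run_pipeline}} output directory
#' and assembles, per analysed metric: group means, the group difference,
#' and the minimum corrected p-value with its vertebral level; plus the
#' correlation and subgroup tables when present. Pure function of the
#' artifacts: regenerating from the same directory gives identical output.
#'
#' @param output_dir Run output directory.
#' @return List with \code{analyses} (data frame), \code{correlations},
#'   \code{subgroups}; also written to \code{report.tsv} in the directory.
#' @export
report_summary <- function(output_dir) {
  pp <- file.path(output_dir, "profiles_baseline.tsv")
  if (!file.exists(pp)) stop("no run artifacts in ", output_dir)
  cohort <- read_profiles(pp, file.path(output_dir, "covariates.tsv"))
  files <- list.files(output_dir, pattern = "^analysis_.*\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no analysis artifacts in ", output_dir)
  rows <- lapply(files, function(f) {
    a <- utils::read.delim(f)
    name <- sub("^analysis_(.*)\\.tsv$", "\\1", basename(f))
    i <- which.min(a$p_corrected)
    m <- if (name %in% cohort$metric_names) name else cohort$metric_names[1]
    g <- cohort$covariates$group
    mu1 <- mean(cohort$values[[m]][g == 1, ], na.rm = TRUE)
    mu0 <- mean(cohort$values[[m]][g == 0, ], na.rm = TRUE)
    data.frame(analysis = name,
               mean_patients = if (name %in% cohort$metric_names) mu1 else NA,
               mean_controls = if (name %in% cohort$metric_names) mu0 else NA,
               group_difference = if (name %in% cohort$metric_names)
                 mu1 - mu0 else NA,
               min_p_corrected = a$p_corrected[i],
               at_level = a$level[i], stringsAsFactors = FALSE)
  })
  analyses <- do.call(rbind, rows)
  utils::write.table(analyses, file.path(output_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  corr <- NULL
  cj <- file.path(output_dir, "correlations.json")
  if (file.exists(cj)) corr <- jsonlite::read_json(cj, simplifyVector = TRUE)
  sg <- NULL
  st <- file.path(output_dir, "subgroups.tsv")
  if (file.exists(st)) sg <- utils::read.delim(st)
  list(analyses = analyses, correlations = corr, subgroups = sg)
}

#' Extract along-cord profiles for one subject from imaging files
#'
#' File-based front end to the extraction pipeline: reads metric volumes
#' (\code{metric_<name>.nii.gz}), the cord mask, tract confidence maps
#' (\code{tract_<name>.nii.gz}), per-tract streamline files
#' (\code{streamlines_<tract>.<side>.trk}) and \code{slice_levels.tsv}
#' from a subject directory laid out as written by
#' \code{\link{write_phantom}}, and produces tract metric profiles and the
#' whole-cord CSA profile on the canonical grid.
#'
#' @param input_dir Subject directory.
#' @param grid Target grid; default one point per native slice.
#' @param metric Metric name to profile.
#' @param threshold Confidence threshold.
#' @param smooth_half_width Sliding-window half-width.
#' @param mode Interpolation mode.
#' @param subject_id Subject label.
#' @return Named list of \code{metric_profile}s (tracts plus CSA).
#' @export
extract_subject_profiles <- function(input_dir, grid = NULL, metric = "FA",
                                     threshold = 0.1, smooth_half_width = 2,
                                     mode = "trilinear",
                                     subject_id = basename(input_dir)) {
  need <- function(p) {
    if (!file.exists(p)) stop("input file not found: ", p)
    p
  }
  vol <- read_volume(need(file.path(input_dir,
                                    paste0("metric_", metric, ".nii.gz"))))
  mask <- read_volume(need(file.path(input_dir, "cord_mask.nii.gz")))
  sl <- utils::read.delim(need(file.path(input_dir, "slice_levels.tsv")))
  if (is.null(grid)) {
    lv <- rle(as.character(sl$level))
    grid <- cord_grid(lv$values, points_per_level = lv$lengths[1],
                      spacing_mm = vol$voxel_dims[3])
  }
  trk_files <- list.files(input_dir, pattern = "^streamlines_.*\\.trk$",
                          full.names = TRUE)
  if (length(trk_files) == 0)
    stop("input file not found: ", file.path(input_dir, "streamlines_*.trk"))
  streamlines <- list()
  for (f in trk_files) {
    parts <- strsplit(sub("^streamlines_(.*)\\.trk$", "\\1", basename(f)),
                      ".", fixed = TRUE)[[1]]
    trk <- read_trk(f)
    for (p in trk$streamlines)
      streamlines[[length(streamlines) + 1L]] <-
        list(points = p, tract = parts[1],
             side = if (length(parts) > 1) parts[2] else "midline")
  }
  samples <- streamline_samples(vol$volume, vol$voxel_dims, streamlines, mode)
  tract_files <- list.files(input_dir, pattern = "^tract_.*\\.nii(\\.gz)?$",
                            full.names = TRUE)
  tract_names <- sub("^tract_(.*?)\\.nii(\\.gz)?$", "\\1",
                     basename(tract_files))
  out <- list()
  for (tr in unique(tract_base_name(tract_names))) {
    maps <- lapply(tract_files[tract_base_name(tract_names) == tr],
                   function(f) read_volume(f)$volume)
    cmap <- Reduce(pmax, maps)
    sub <- samples[vapply(samples, function(s) s$tract == tr, logical(1))]
    if (length(sub) == 0) next
    class(sub) <- "streamline_samples"
    p <- tract_profile(sub, cmap, vol$voxel_dims, grid,
                       threshold = threshold, tract = tr, metric = metric,
                       subject_id = subject_id)
    if (smooth_half_width > 0)
      p$values <- sliding_mean_window(p$values, smooth_half_width)
    out[[tr]] <- p
  }
  out$CSA <- cord_csa_profile(mask$volume, mask$voxel_dims,
                              as.character(sl$level), grid, subject_id)
  out
}
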