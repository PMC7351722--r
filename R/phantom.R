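#' Schematic tract layout for the cord phantom
#'
#' In-plane tract centers (mm offsets from the cord axis; x lateral,
#' y dorsal) and Gaussian confidence widths, anatomically inspired:
#' lateral corticospinal tracts lateral, posterior column dorsal midline,
#' spinal lemnisci anterolateral.
#'
#' @return Named list of tracts, each \code{list(offset, sd_mm, side)}.
#' @export
default_tract_layout <- function() {
  list(
    lateral_CST_left       = list(offset = c(-2.2,  0.3), sd_mm = 0.8, side = "left"),
    lateral_CST_right      = list(offset = c( 2.2,  0.3), sd_mm = 0.8, side = "right"),
    posterior_column       = list(offset = c( 0.0,  2.3), sd_mm = 0.9, side = "midline"),
    spinal_lemniscus_left  = list(offset = c(-2.0, -1.7), sd_mm = 0.7, side = "left"),
    spinal_lemniscus_right = list(offset = c( 2.0, -1.7), sd_mm = 0.7, side = "right")
  )
}

tract_base_name <- function(name) sub("_(left|right)$", "", name)

#' Simulate a voxel cord phantom
#'
#' Builds a cylindrical spinal cord along the slice axis with
#' probabilistic tract confidence maps (in-plane Gaussian bumps at the
#' layout offsets), piecewise-constant metric volumes (per-tract values on
#' a background cord value, plus optional voxel noise and a subject-level
#' shift), axis-parallel streamlines seeded in each tract (one point per
#' slice, mm coordinates), and the per-slice vertebral level labels.
#' Disease-flagged phantoms receive the configured per-tract metric offset
#' only on slices of the configured levels.
#'
#' World coordinates: voxel (i, j, k) (0-based) has its center at
#' (i, j, k) * voxel_dims mm; slices are ordered rostral to caudal.
#'
#' @param levels Vertebral level labels, rostral to caudal.
#' @param slices_per_level Slices per level (default 6: 5 levels x 6
#'   slices = 30 slices).
#' @param voxel_dims In-plane voxel size and slice thickness in mm
#'   (default \code{c(1.12, 1.12, 3.3)}).
#' @param fov In-plane matrix size (voxels).
#' @param cord_radius_mm Cord radius in mm.
#' @param tracts Tract layout, see \code{\link{default_tract_layout}}.
#' @param metric_values Named list: per metric, a named numeric vector of
#'   per-tract values (base tract names) plus a \code{background} entry.
#' @param group_effect NULL or \code{list(metric, tract, levels, offset)}:
#'   metric offset applied to that tract's voxels on those levels when
#'   \code{als = TRUE}.
#' @param als Logical: apply the group effect to this phantom.
#' @param noise_sd Voxelwise Gaussian noise SD added to metric volumes.
#' @param subject_shift Scalar added to every metric voxel (between-subject
#'   variation).
#' @param n_streamlines Streamlines seeded per tract.
#' @param min_center_distance_mm Below this center-to-center distance two
#'   distinct tracts are flagged as overlapping in the output metadata
#'   (a warning, not an error).
#' @param confidence_floor Seeding keeps streamlines in voxels whose tract
#'   confidence is at least this value.
#' @param seed Integer seed.
#' @return Object of class \code{cord_phantom}: voxel_dims_mm,
#'   metric_volumes, cord_mask, tract_maps, streamlines, slice_levels,
#'   metadata.
#' @export
simulate_cord_phantom <- function(levels = c("C2", "C3", "C4", "C5", "C6"),
                                  slices_per_level = 6,
                                  voxel_dims = c(1.12, 1.12, 3.3),
                                  fov = c(32, 32),
                                  cord_radius_mm = 4,
                                  tracts = default_tract_layout(),
                                  metric_values = list(
                                    FA = c(background = 0.40,
                                           lateral_CST = 0.55,
                                           posterior_column = 0.60,
                                           spinal_lemniscus = 0.50)),
                                  group_effect = NULL,
                                  als = FALSE,
                                  noise_sd = 0,
                                  subject_shift = 0,
                                  n_streamlines = 9,
                                  min_center_distance_mm = 1.5,
                                  confidence_floor = 0.5,
                                  seed = 1L) {
  set.seed(seed)
  nx <- fov[1]; ny <- fov[2]
  nz <- length(levels) * slices_per_level
  dx <- voxel_dims[1]; dy <- voxel_dims[2]; dz <- voxel_dims[3]
  center <- c((nx - 1) / 2 * dx, (ny - 1) / 2 * dy)
  if (cord_radius_mm + max(vapply(tracts, function(t) max(abs(t$offset)),
                                  numeric(1))) > min(center))
    stop("cord radius plus tract offsets exceed the field of view")
  slice_levels <- rep(levels, each = slices_per_level)

  xs <- (seq_len(nx) - 1) * dx; ys <- (seq_len(ny) - 1) * dy
  r2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  disk <- r2 <= cord_radius_mm^2
  cord_mask <- array(rep(disk, nz), dim = c(nx, ny, nz))

  # in-plane Gaussian confidence bumps, replicated across slices
  tract_maps <- lapply(tracts, function(t) {
    cx <- center[1] + t$offset[1]; cy <- center[2] + t$offset[2]
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    conf <- exp(-d2 / (2 * t$sd_mm^2)) * disk
    array(rep(conf, nz), dim = c(nx, ny, nz))
  })
  names(tract_maps) <- names(tracts)

  # voxel -> tract assignment: highest confidence above the floor wins
  conf_stack <- vapply(tract_maps, function(a) a[, , 1], matrix(0, nx, ny))
  best <- apply(conf_stack, c(1, 2), which.max)
  best_conf <- apply(conf_stack, c(1, 2), max)
  assign_slice <- ifelse(best_conf >= confidence_floor & disk, best, 0L)

  effect_slices <- integer(0)
  if (!is.null(group_effect) && als)
    effect_slices <- which(slice_levels %in% group_effect$levels)

  metric_volumes <- lapply(names(metric_values), function(metric) {
    mv <- metric_values[[metric]]
    plane <- matrix(ifelse(disk, mv[["background"]], 0), nx, ny)
    for (ti in seq_along(tracts)) {
      base <- tract_base_name(names(tracts)[ti])
      if (base %in% names(mv)) plane[assign_slice == ti] <- mv[[base]]
    }
    vol <- array(rep(plane, nz), dim = c(nx, ny, nz))
    if (length(effect_slices) > 0 && group_effect$metric == metric) {
      sel_tracts <- which(tract_base_name(names(tracts)) == group_effect$tract)
      vox <- assign_slice %in% sel_tracts
      for (k in effect_slices)
        vol[, , k][vox] <- vol[, , k][vox] + group_effect$offset
    }
    vol[cord_mask] <- vol[cord_mask] + subject_shift
    if (noise_sd > 0)
      vol[cord_mask] <- vol[cord_mask] + stats::rnorm(sum(cord_mask), sd = noise_sd)
    vol
  })
  names(metric_volumes) <- names(metric_values)

  # axis-parallel streamlines: constant in-plane seed, one point per slice
  streamlines <- list()
  zs <- (seq_len(nz) - 1) * dz
  for (ti in seq_along(tracts)) {
    t <- tracts[[ti]]
    cx <- center[1] + t$offset[1]; cy <- center[2] + t$offset[2]
    for (s in seq_len(n_streamlines)) {
      # seeds snap to voxel centers so sampled values are interpolation-exact
      ic <- round(cx / dx) + 1; jc <- round(cy / dy) + 1
      pt <- c((ic - 1) * dx, (jc - 1) * dy)
      for (try in seq_len(100)) {
        cand <- c(cx, cy) + stats::rnorm(2, sd = t$sd_mm * 0.4)
        i <- round(cand[1] / dx) + 1; j <- round(cand[2] / dy) + 1
        if (i >= 1 && i <= nx && j >= 1 && j <= ny && disk[i, j] &&
            conf_stack[i, j, ti] >= confidence_floor) {
          pt <- c((i - 1) * dx, (j - 1) * dy); break
        }
      }
      streamlines[[length(streamlines) + 1L]] <- list(
        points = cbind(x = rep(pt[1], nz), y = rep(pt[2], nz), z = zs),
        tract = tract_base_name(names(tracts)[ti]),
        side = t$side)
    }
  }

  # flag schematically overlapping tracts (distinct base names too close)
  warnings <- character(0)
  nm <- names(tracts)
  for (a in seq_along(tracts)) for (b in seq_len(a - 1L)) {
    if (tract_base_name(nm[a]) == tract_base_name(nm[b])) next
    d <- sqrt(sum((tracts[[a]]$offset - tracts[[b]]$offset)^2))
    if (d < min_center_distance_mm)
      warnings <- c(warnings, sprintf(
        "tracts %s and %s overlap (center distance %.2f mm < %.2f mm)",
        nm[a], nm[b], d, min_center_distance_mm))
  }

  obj <- list(voxel_dims_mm = voxel_dims, metric_volumes = metric_volumes,
              cord_mask = cord_mask, tract_maps = tract_maps,
              streamlines = streamlines, slice_levels = slice_levels,
              metadata = list(levels = levels,
                              slices_per_level = slices_per_level,
                              als = als, seed = seed, warnings = warnings))
  class(obj) <- "cord_phantom"
  obj
}

#' Simulate a cohort of phantoms and extract their profiles
#'
#' End-to-end validation helper: generates one voxel phantom per subject
#' (patients carry the configured tract- and level-localized FA deficit,
#' plus a subject-level metric shift and voxel noise), runs the full
#' extraction pipeline on each (streamline sampling, confidence
#' thresholding, arc-length binning, sliding-window smoothing, left/right
#' averaging), and assembles the per-tract profiles into a
#' \code{cord_cohort} whose "metrics" are named by tract (plus whole-cord
#' CSA).
#'
#' @param n_per_group Patients / controls.
#' @param deficit FA offset applied to patients (typically negative).
#' @param levels Levels carrying the deficit.
#' @param tract Tract carrying the deficit (base name).
#' @param noise_sd Voxel noise SD.
#' @param subject_sd SD of the subject-level FA shift.
#' @param seed Integer seed.
#' @param fov In-plane matrix size passed to the phantom.
#' @param n_streamlines Streamlines per tract per subject.
#' @param threshold Confidence threshold for extraction.
#' @param smooth_half_width Sliding-window half-width.
#' @return A \code{cord_cohort} with one value matrix per profiled tract
#'   and a CSA matrix.
#' @export
phantom_cohort <- function(n_per_group = c(20, 20), deficit = -0.05,
                           levels = c("C2", "C3"), tract = "lateral_CST",
                           noise_sd = 0.02, subject_sd = 0.02, seed = 1L,
                           fov = c(28, 28), n_streamlines = 9,
                           threshold = 0.1, smooth_half_width = 2) {
  set.seed(seed)
  covariates <- simulate_covariates(n_per_group)
  n <- nrow(covariates)
  shifts <- stats::rnorm(n, 0, subject_sd)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  grid <- NULL; prof_list <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- simulate_cord_phantom(
      als = covariates$group[i] == 1,
      group_effect = list(metric = "FA", tract = tract, levels = levels,
                          offset = deficit),
      noise_sd = noise_sd, subject_shift = shifts[i], fov = fov,
      n_streamlines = n_streamlines, seed = sub_seeds[i])
    if (is.null(grid))
      grid <- cord_grid(ph$metadata$levels, ph$metadata$slices_per_level,
                        ph$voxel_dims_mm[3])
    prof_list[[i]] <- extract_phantom_profiles(
      ph, grid, threshold = threshold,
      smooth_half_width = smooth_half_width,
      subject_id = covariates$subject_id[i])
  }
  tracts <- names(prof_list[[1]])
  values <- lapply(tracts, function(tr)
    t(vapply(prof_list, function(p) p[[tr]]$values,
             numeric(length(grid$positions)))))
  names(values) <- tracts
  for (v in seq_along(values))
    rownames(values[[v]]) <- covariates$subject_id
  new_cord_cohort(grid, covariates, values)
}

#' @export
print.cord_phantom <- function(x, ...) {
  d <- dim(x$cord_mask)
  cat("Cord phantom: ", d[1], "x", d[2], "x", d[3], " voxels (",
      paste(x$voxel_dims_mm, collapse = " x "), " mm), ",
      length(x$streamlines), " streamlines, tracts: ",
      paste(names(x$tract_maps), collapse = ", "), "\n", sep = "")
  if (length(x$metadata$warnings) > 0)
    cat("Warnings:", paste(x$metadata$warnings, collapse = "; "), "\n")
  invisible(x)
}
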