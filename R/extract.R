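#' Truncated sliding mean window
#'
#' Smooths a sequence with a centered mean window of \code{2*half_width+1}
#' points ("five points, about 6 mm" at the default half-width of 2 on a
#' typical along-cord sampling), truncated at the ends. Missing values are
#' excluded from both the sum and the count; a window containing only
#' missing values yields a missing output.
#'
#' @param values Numeric vector (NAs allowed).
#' @param half_width Non-negative integer; default 2.
#' @return Numeric vector of the same length.
#' @examples
#' sliding_mean_window(1:7)  # 2 2.5 3 4 5 5.5 6
#' @export
sliding_mean_window <- function(values, half_width = 2) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (half_width < 0 || half_width != round(half_width))
    stop("'half_width' must be a non-negative integer")
  n <- length(values)
  if (half_width == 0) return(values)
  out <- numeric(n)
  for (k in seq_len(n)) {
    w <- values[max(1, k - half_width):min(n, k + half_width)]
    out[k] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# world (mm) -> 0-based continuous voxel coordinates
world_to_voxel <- function(points, voxel_dims) {
  sweep(points, 2, voxel_dims, "/")
}

#' Sample a scalar volume along a streamline
#'
#' Looks up the volume at each streamline point (mm coordinates; voxel
#' (i,j,k) center at (i,j,k)*voxel_dims, 0-based) and accumulates arc
#' length from Euclidean segment lengths.
#'
#' @param volume 3-D numeric array.
#' @param voxel_dims Length-3 voxel dimensions in mm.
#' @param points n x 3 matrix of point coordinates in mm.
#' @param mode \code{"trilinear"} (default) or \code{"nearest"}.
#' @return List with \code{values} and \code{arc_mm} (arc length from the
#'   first point).
#' @export
sample_along_streamline <- function(volume, voxel_dims, points,
                                    mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  v <- world_to_voxel(points, voxel_dims)
  d <- dim(volume)
  oob <- which(v[, 1] < 0 | v[, 1] > d[1] - 1 |
               v[, 2] < 0 | v[, 2] > d[2] - 1 |
               v[, 3] < 0 | v[, 3] > d[3] - 1)
  if (length(oob) > 0)
    stop("streamline point ", oob[1], " outside volume bounds: (",
         paste(signif(points[oob[1], ], 4), collapse = ", "), ") mm")
  if (mode == "nearest") {
    idx <- round(v) + 1
    values <- volume[cbind(idx[, 1], idx[, 2], idx[, 3])]
  } else {
    f <- floor(v)
    for (k in 1:3) f[, k] <- pmin(pmax(f[, k], 0), max(d[k] - 2, 0))
    r <- v - f
    for (k in 1:3) if (d[k] == 1) r[, k] <- 0  # degenerate axis: no blend
    i0 <- f + 1
    g <- function(a, b, c) volume[cbind(pmin(i0[, 1] + a, d[1]),
                                        pmin(i0[, 2] + b, d[2]),
                                        pmin(i0[, 3] + c, d[3]))]
    values <-
      g(0,0,0) * (1-r[,1])*(1-r[,2])*(1-r[,3]) + g(1,0,0) * r[,1]*(1-r[,2])*(1-r[,3]) +
      g(0,1,0) * (1-r[,1])*r[,2]*(1-r[,3])     + g(0,0,1) * (1-r[,1])*(1-r[,2])*r[,3] +
      g(1,1,0) * r[,1]*r[,2]*(1-r[,3])         + g(1,0,1) * r[,1]*(1-r[,2])*r[,3] +
      g(0,1,1) * (1-r[,1])*r[,2]*r[,3]         + g(1,1,1) * r[,1]*r[,2]*r[,3]
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  list(values = values, arc_mm = c(0, cumsum(seg)))
}

#' Sample metric values along a set of streamlines
#'
#' Applies \code{\link{sample_along_streamline}} to every streamline and
#' carries tract and side labels through, yielding the sample set consumed
#' by \code{\link{tract_profile}}.
#'
#' @param volume 3-D metric array.
#' @param voxel_dims Voxel dimensions (mm).
#' @param streamlines List of streamlines: each \code{list(points, tract,
#'   side)} with points in mm.
#' @param mode Interpolation mode for metric sampling.
#' @return Object of class \code{streamline_samples}: list of per-streamline
#'   records (points, arc_mm, values, tract, side).
#' @export
streamline_samples <- function(volume, voxel_dims, streamlines,
                               mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  out <- lapply(seq_along(streamlines), function(i) {
    sl <- streamlines[[i]]
    s <- tryCatch(sample_along_streamline(volume, voxel_dims, sl$points, mode),
                  error = function(e) stop("streamline ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    list(points = sl$points, arc_mm = s$arc_mm, values = s$values,
         tract = sl$tract %||% "whole_cord", side = sl$side %||% "midline")
  })
  class(out) <- "streamline_samples"
  out
}

new_metric_profile <- function(subject_id, tract, metric, grid, values) {
  stopifnot(length(values) == length(grid$positions))
  obj <- list(subject_id = subject_id, tract = tract, metric = metric,
              grid = grid, values = as.numeric(values))
  class(obj) <- "metric_profile"
  obj
}

#' @export
print.metric_profile <- function(x, ...) {
  cat("Metric profile: ", x$metric, " along ", x$tract, " (subject ",
      x$subject_id, "), ", length(x$values), " positions, ",
      sum(is.na(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Along-cord tract profile from streamline samples
#'
#' Averages metric samples from all streamlines passing through a
#' segmented pathway at each position along the cord. Samples in voxels
#' whose tract confidence (nearest-voxel lookup) is below \code{threshold}
#' are excluded; surviving samples are binned to the nearest grid position
#' by arc length (ties rostral); the per-position value is the mean over
#' contributing samples. With \code{lr_average} the left and right
#' homologues are averaged position-wise after per-side means, so unequal
#' streamline counts per side do not bias the profile.
#'
#' @param samples A \code{\link{streamline_samples}} set.
#' @param tract_map 3-D confidence array in [0,1] for the tract (use the
#'   cord mask for whole-cord profiles).
#' @param voxel_dims Voxel dimensions (mm).
#' @param grid Target \code{\link{cord_grid}}.
#' @param threshold Confidence cut, default 0.1.
#' @param lr_average Average left/right homologues (default TRUE).
#' @param tract,metric,subject_id Labels for the output profile.
#' @return A \code{metric_profile}; positions with no contributing sample
#'   are missing.
#' @export
tract_profile <- function(samples, tract_map, voxel_dims, grid,
                          threshold = 0.1, lr_average = TRUE,
                          tract = "tract", metric = "FA",
                          subject_id = "subject") {
  validate_grid(grid)
  if (threshold < 0) stop("threshold must be non-negative")
  M <- length(grid$positions)
  acc <- list()  # per side: sum and count vectors
  for (sl in samples) {
    idx <- round(world_to_voxel(as.matrix(sl$points), voxel_dims)) + 1
    conf <- tract_map[cbind(idx[, 1], idx[, 2], idx[, 3])]
    keep <- which(conf >= threshold & !is.na(sl$values))
    if (length(keep) == 0) next
    bins <- vapply(sl$arc_mm[keep],
                   function(a) which.min(abs(grid$positions - a)), integer(1))
    side <- if (lr_average) sl$side else "pooled"
    if (is.null(acc[[side]]))
      acc[[side]] <- list(sum = numeric(M), n = numeric(M))
    for (q in seq_along(keep)) {
      b <- bins[q]
      acc[[side]]$sum[b] <- acc[[side]]$sum[b] + sl$values[keep[q]]
      acc[[side]]$n[b] <- acc[[side]]$n[b] + 1
    }
  }
  if (length(acc) == 0)
    stop("no samples survive the confidence threshold for tract '",
         tract, "'")
  side_means <- vapply(acc, function(a) ifelse(a$n > 0, a$sum / a$n, NA_real_),
                       numeric(M))
  side_means <- matrix(side_means, nrow = M)
  vals <- rowMeans(side_means, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  if (all(is.na(vals)))
    stop("empty contribution at every position for tract '", tract, "'")
  new_metric_profile(subject_id, tract, metric, grid, vals)
}

#' Cord cross-sectional area profile
#'
#' Per slice, CSA = in-slice voxel count x in-plane voxel area (default
#' 1.12 x 1.12 = 1.2544 mm^2); the per-slice values are then resampled
#' within each vertebral level onto the canonical grid
#' (\code{\link{level_align}}).
#'
#' @param cord_mask Binary 3-D array (slices along the third axis, rostral
#'   to caudal).
#' @param voxel_dims Voxel dimensions (mm).
#' @param slice_levels Level label per slice.
#' @param grid Target grid.
#' @param subject_id Label.
#' @return A \code{metric_profile} with metric "CSA".
#' @export
cord_csa_profile <- function(cord_mask, voxel_dims, slice_levels, grid,
                             subject_id = "subject") {
  nz <- dim(cord_mask)[3]
  stopifnot(length(slice_levels) == nz)
  area <- voxel_dims[1] * voxel_dims[2]
  csa <- vapply(seq_len(nz), function(k) sum(cord_mask[, , k] != 0) * area,
                numeric(1))
  lv <- unique(grid$levels)
  empties <- which(csa == 0 & slice_levels %in% lv)
  if (length(empties) > 0)
    warning("empty cord mask slice(s) inside the analysis range: ",
            paste(empties, collapse = ", "))
  level_align(csa, slice_levels, grid, tract = "whole_cord", metric = "CSA",
              subject_id = subject_id)
}

#' Resample native-slice values onto the canonical grid, level by level
#'
#' Within each vertebral level the native values are linearly resampled
#' (by relative position within the level) onto that level's canonical
#' grid positions; no extrapolation beyond the first/last native sample
#' (end values are clamped). A level with a single native sample is
#' replicated with a warning.
#'
#' @param values Numeric vector, one value per native slice.
#' @param slice_levels Level label per native slice (must cover every grid
#'   level).
#' @param grid Target \code{\link{cord_grid}}.
#' @param tract,metric,subject_id Labels for the output profile.
#' @return A \code{metric_profile} on the canonical grid.
#' @export
level_align <- function(values, slice_levels, grid, tract = "whole_cord",
                        metric = "metric", subject_id = "subject") {
  validate_grid(grid)
  stopifnot(length(values) == length(slice_levels))
  out <- rep(NA_real_, length(grid$positions))
  for (lv in unique(grid$levels)) {
    gi <- which(grid$levels == lv)
    si <- which(slice_levels == lv)
    if (length(si) == 0)
      stop("no native slices for level ", lv)
    v <- values[si]
    if (length(si) == 1) {
      warning("level ", lv, " has a single native sample; replicated")
      out[gi] <- v
    } else if (length(gi) == 1) {
      out[gi] <- mean(v, na.rm = TRUE)
    } else {
      xin <- seq(0, 1, length.out = length(si))
      xout <- seq(0, 1, length.out = length(gi))
      ok <- !is.na(v)
      if (sum(ok) == 0) next
      if (sum(ok) == 1) out[gi] <- v[ok]
      else out[gi] <- stats::approx(xin[ok], v[ok], xout, rule = 2)$y
    }
  }
  new_metric_profile(subject_id, tract, metric, grid, out)
}

#' Longitudinal change profile
#'
#' Position-wise difference follow-up minus baseline for the same subject,
#' tract and metric; missing wherever either side is missing.
#'
#' @param baseline,followup \code{metric_profile}s on the same grid.
#' @return A \code{metric_profile} of differences.
#' @export
change_profile <- function(baseline, followup) {
  stopifnot(inherits(baseline, "metric_profile"),
            inherits(followup, "metric_profile"))
  if (!isTRUE(all.equal(baseline$grid$positions, followup$grid$positions)) ||
      !identical(baseline$grid$levels, followup$grid$levels))
    stop("grids of baseline and follow-up profiles do not match")
  if (!identical(baseline$metric, followup$metric))
    stop("metrics do not match")
  new_metric_profile(baseline$subject_id, baseline$tract,
                     baseline$metric, baseline$grid,
                     followup$values - baseline$values)
}

#' Extract along-cord profiles from a phantom
#'
#' Convenience wrapper running the extraction pipeline (streamline
#' sampling, confidence thresholding, arc-length binning, optional
#' sliding-window smoothing, left/right averaging) on a
#' \code{\link{simulate_cord_phantom}} object, plus the whole-cord CSA
#' profile.
#'
#' @param phantom A \code{cord_phantom}.
#' @param grid Target grid; default one grid point per slice.
#' @param metric Metric volume to sample.
#' @param tracts Base tract names to profile; default all in the phantom.
#' @param threshold Confidence cut (default 0.1).
#' @param smooth_half_width Sliding-window half-width applied to each
#'   profile (default 2; 0 disables).
#' @param mode Interpolation mode for metric sampling.
#' @param subject_id Label.
#' @return Named list of \code{metric_profile}s (one per tract, plus
#'   \code{CSA}).
#' @export
extract_phantom_profiles <- function(phantom, grid = NULL, metric = "FA",
                                     tracts = NULL, threshold = 0.1,
                                     smooth_half_width = 2,
                                     mode = "trilinear",
                                     subject_id = "subject") {
  stopifnot(inherits(phantom, "cord_phantom"))
  if (is.null(grid))
    grid <- cord_grid(levels = phantom$metadata$levels,
                      points_per_level = phantom$metadata$slices_per_level,
                      spacing_mm = phantom$voxel_dims_mm[3])
  vol <- phantom$metric_volumes[[metric]]
  if (is.null(vol)) stop("phantom has no metric volume '", metric, "'")
  samples <- streamline_samples(vol, phantom$voxel_dims_mm,
                                phantom$streamlines, mode)
  if (is.null(tracts))
    tracts <- unique(tract_base_name(names(phantom$tract_maps)))
  out <- list()
  for (tr in tracts) {
    maps <- phantom$tract_maps[tract_base_name(names(phantom$tract_maps)) == tr]
    cmap <- Reduce(pmax, maps)
    sub <- samples[vapply(samples, function(s) s$tract == tr, logical(1))]
    class(sub) <- "streamline_samples"
    p <- tract_profile(sub, cmap, phantom$voxel_dims_mm, grid,
                       threshold = threshold, tract = tr, metric = metric,
                       subject_id = subject_id)
    if (smooth_half_width > 0)
      p$values <- sliding_mean_window(p$values, smooth_half_width)
    out[[tr]] <- p
  }
  out$CSA <- cord_csa_profile(phantom$cord_mask, phantom$voxel_dims_mm,
                              phantom$slice_levels, grid, subject_id)
  out
}
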