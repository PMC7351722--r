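# I/O conventions: voxel indices are 0-based; world coordinates are mm with
# voxel (i,j,k) centered at (i,j,k)*voxel_dims; slices are ordered rostral
# to caudal. Profile and covariate tables are plain TSV.

#' Write cohort profiles as a long TSV
#'
#' Columns: subject_id, timepoint, metric, level, position_mm, value.
#'
#' @param cohort A \code{cord_cohort}.
#' @param path Output file.
#' @export
write_profiles <- function(cohort, path) {
  stopifnot(inherits(cohort, "cord_cohort"))
  g <- cohort$grid
  rows <- lapply(cohort$metric_names, function(m) {
    Y <- cohort$values[[m]]
    data.frame(
      subject_id = rep(cohort$covariates$subject_id, times = ncol(Y)),
      timepoint = cohort$timepoint,
      metric = m,
      level = rep(g$levels, each = nrow(Y)),
      position_mm = rep(g$positions, each = nrow(Y)),
      value = as.vector(Y),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort profiles from a long TSV
#'
#' Inverse of \code{\link{write_profiles}}; the grid is reconstructed from
#' the (position_mm, level) pairs.
#'
#' @param path Profile TSV.
#' @param covariates Optional covariate data frame or TSV path to attach;
#'   when NULL a minimal covariate table (ids only) is built.
#' @return A \code{cord_cohort}.
#' @export
read_profiles <- function(path, covariates = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "metric", "level", "position_mm", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("profile TSV missing column(s): ", paste(miss, collapse = ", "))
  gp <- unique(df[order(df$position_mm), c("position_mm", "level")])
  spacing <- if (nrow(gp) > 1) stats::median(diff(gp$position_mm)) else 1
  grid <- list(positions = gp$position_mm, levels = as.character(gp$level),
               spacing_mm = spacing)
  class(grid) <- "cord_grid"
  validate_grid(grid)
  ids <- unique(df$subject_id)
  if (is.character(covariates)) covariates <- read_covariates(covariates)
  if (is.null(covariates))
    covariates <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  covariates <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  if (anyNA(covariates$subject_id))
    stop("covariate table missing subjects present in the profiles")
  values <- lapply(unique(df$metric), function(m) {
    sub <- df[df$metric == m, ]
    Y <- matrix(NA_real_, length(ids), length(grid$positions),
                dimnames = list(ids, NULL))
    ri <- match(sub$subject_id, ids)
    ci <- match(round(sub$position_mm, 6), round(grid$positions, 6))
    Y[cbind(ri, ci)] <- sub$value
    Y
  })
  names(values) <- unique(df$metric)
  tp <- if ("timepoint" %in% names(df)) df$timepoint[1] else "baseline"
  new_cord_cohort(grid, covariates, values, tp)
}

#' Read / write subject covariate TSV
#'
#' Columns: subject_id, group, age_years, scanner, sex, onset_site.
#'
#' @param path TSV path.
#' @return Covariate data frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("covariate TSV needs a subject_id column")
  df
}

#' @rdname read_covariates
#' @param covariates Covariate data frame.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write clinical score TSV
#'
#' Columns: subject_id, timepoint, item_1..item_12, umn.
#'
#' @param path TSV path.
#' @return A \code{clinical_table} data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @rdname read_clinical
#' @param table Clinical table.
#' @export
write_clinical <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a scalar volume as NIfTI
#'
#' Thin wrappers over RNifti carrying the voxel dimensions.
#'
#' @param volume 3-D array.
#' @param voxel_dims Voxel dimensions mm.
#' @param path File path (.nii or .nii.gz).
#' @export
write_volume <- function(volume, voxel_dims, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return \code{read_volume}: list(volume, voxel_dims).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim = dim(img)),
       voxel_dims = RNifti::pixdim(img)[1:3])
}

#' Write streamlines to a TrackVis .trk file
#'
#' Minimal TrackVis format (version 2) writer; points are stored in mm
#' (voxel-size-scaled) coordinates matching this package's world
#' convention, with a diagonal vox-to-ras affine.
#'
#' @param streamlines List of n x 3 point matrices (mm), or of
#'   \code{list(points=...)} records.
#' @param path Output .trk path.
#' @param voxel_dims Voxel dimensions mm.
#' @param dim Volume dimensions (voxels).
#' @export
write_trk <- function(streamlines, path, voxel_dims = c(1, 1, 1),
                      dim = c(0L, 0L, 0L)) {
  pts <- lapply(streamlines, function(s) {
    p <- if (is.list(s) && !is.null(s$points)) s$points else s
    matrix(as.numeric(as.matrix(p)), ncol = 3)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(width - length(raw_s))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_dims), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  wchar("", 200)
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  wchar("", 200)
  aff <- diag(c(voxel_dims, 1))                                # vox_to_ras
  writeBin(as.numeric(t(aff)), con, size = 4, endian = "little")
  wchar("", 444)                                               # reserved
  wchar("RAS", 4)                                              # voxel_order
  wchar("", 4)                                                 # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  wchar("", 2)                                                 # pad1
  writeBin(raw(6), con)                                        # invert/swap
  writeBin(length(pts), con, size = 4, endian = "little")      # n_count
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (p in pts) {
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read streamlines from a TrackVis .trk file
#'
#' @param path .trk path.
#' @return List with \code{streamlines} (list of n x 3 mm point matrices),
#'   \code{voxel_dims}, \code{dim}.
#' @export
read_trk <- function(path) {
  if (!file.exists(path)) stop("TRK file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(magic, "TRACK")) stop("not a TRK file: ", path)
  dim <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_dims <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")      # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  readBin(con, "numeric", 16, size = 4, endian = "little")     # vox_to_ras
  readBin(con, "raw", 444 + 4 + 4)
  readBin(con, "numeric", 6, size = 4, endian = "little")
  readBin(con, "raw", 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr != 1000L) stop("unexpected TRK header size: ", hdr)
  out <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4,
                             endian = "little")
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)
    out[[length(out) + 1L]] <- m[, 1:3, drop = FALSE]
    if (n_count > 0 && length(out) >= n_count) break
  }
  list(streamlines = out, voxel_dims = voxel_dims, dim = dim)
}

#' Write a cord phantom to disk
#'
#' Metric volumes, cord mask and tract confidence maps as NIfTI;
#' streamlines as one .trk per (tract, side).
#'
#' @param phantom A \code{cord_phantom}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cord_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vd <- phantom$voxel_dims_mm
  paths <- character(0)
  wv <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    write_volume(vol, vd, p)
    paths <<- c(paths, p)
  }
  for (m in names(phantom$metric_volumes))
    wv(phantom$metric_volumes[[m]], paste0("metric_", m))
  wv(phantom$cord_mask + 0, "cord_mask")
  for (t in names(phantom$tract_maps))
    wv(phantom$tract_maps[[t]], paste0("tract_", t))
  groups <- split(phantom$streamlines,
                  vapply(phantom$streamlines,
                         function(s) paste(s$tract, s$side, sep = "."),
                         character(1)))
  for (g in names(groups)) {
    p <- file.path(dir, paste0("streamlines_", g, ".trk"))
    write_trk(groups[[g]], p, vd, dim(phantom$cord_mask))
    paths <- c(paths, p)
  }
  utils::write.table(
    data.frame(slice = seq_along(phantom$slice_levels) - 1L,
               level = phantom$slice_levels),
    file.path(dir, "slice_levels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, file.path(dir, "slice_levels.tsv")))
}
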