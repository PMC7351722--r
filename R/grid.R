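#' Canonical along-cord sampling grid
#'
#' Builds the 1-D arc-length grid on which all along-cord profiles live:
#' an ordered set of positions (mm) tagged with cervical vertebral levels,
#' rostral (C2) to caudal (C6).
#'
#' @param levels Character vector of vertebral level labels, ordered
#'   rostral to caudal (default \code{c("C2","C3","C4","C5","C6")}).
#' @param points_per_level Number of grid positions per level (positive
#'   integer).
#' @param spacing_mm Distance between adjacent positions in mm (positive).
#' @return An object of class \code{cord_grid}: a list with
#'   \code{positions} (ascending arc-length coordinates in mm, starting at
#'   0), \code{levels} (level label per position, contiguous ordered
#'   blocks) and \code{spacing_mm}.
#' @examples
#' g <- cord_grid(points_per_level = 10, spacing_mm = 1.5)
#' length(g$positions)  # 50
#' @export
cord_grid <- function(levels = c("C2", "C3", "C4", "C5", "C6"),
                      points_per_level = 10, spacing_mm = 1.5) {
  if (length(levels) < 1L) stop("'levels' must be non-empty")
  if (!is.numeric(points_per_level) || points_per_level < 1 ||
      points_per_level != round(points_per_level))
    stop("'points_per_level' must be a positive integer")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("'spacing_mm' must be positive")
  n <- length(levels) * as.integer(points_per_level)
  g <- list(
    positions  = (seq_len(n) - 1) * spacing_mm,
    levels     = rep(as.character(levels), each = points_per_level),
    spacing_mm = spacing_mm
  )
  class(g) <- "cord_grid"
  g
}

#' @export
print.cord_grid <- function(x, ...) {
  cat("Along-cord grid: ", length(x$positions), " positions, ",
      x$positions[1], "-", x$positions[length(x$positions)], " mm (spacing ",
      x$spacing_mm, " mm)\n", sep = "")
  cat("Levels:", paste(rle(x$levels)$values, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.cord_grid <- function(x) length(x$positions)

# indices of grid positions belonging to the given levels
grid_level_index <- function(grid, levels) {
  idx <- which(grid$levels %in% levels)
  if (length(idx) == 0L)
    stop("no grid positions in levels: ", paste(levels, collapse = ", "))
  idx
}

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "cord_grid"))
  if (any(diff(grid$positions) <= 0))
    stop("grid positions must be strictly increasing")
  r <- rle(grid$levels)
  if (anyDuplicated(r$values))
    stop("grid level labels must form contiguous blocks")
  invisible(grid)
}
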