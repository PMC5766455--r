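#' 3D scalar volume
#'
#' A scalar grid with axis-aligned geometry: voxel spacing in mm and the
#' world position of the center of voxel (1, 1, 1) (voxel-center
#' convention). This is the in-memory form of every simulated or loaded
#' acquisition.
#'
#' @param data 3D numeric array.
#' @param spacing length-3, mm per voxel along (x, y, z).
#' @param origin length-3, world mm of the first voxel center.
#' @return object of class `mmri_volume`.
#' @export
mmri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("volume error: data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("volume error: spacing must be 3 positive values")
  if (length(origin) != 3L) stop("volume error: origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "mmri_volume")
}

#' @export
print.mmri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mmri_volume: %d x %d x %d voxels, spacing (%.4f, %.4f, %.4f) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f, %.2f, %.2f  intensity range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel / world coordinate conversion
#'
#' 1-based voxel indices map to world mm through
#' `world = origin + (index - 1) * spacing` (voxel-center convention).
#'
#' @param vol `mmri_volume`.
#' @param idx Nx3 matrix of (possibly fractional) 1-based voxel indices.
#' @param pts Nx3 matrix of world points, mm.
#' @return Nx3 matrix.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Trilinear interpolation of a volume at world points
#'
#' @param vol `mmri_volume`.
#' @param pts Nx3 world points, mm; must lie inside the grid.
#' @return numeric vector of interpolated intensities.
#' @export
sample_volume <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  cpp_sample_trilinear(vol$data, dim(vol$data), vol$spacing, vol$origin,
                       as.matrix(pts))
}

#' Binary mask sharing a volume's geometry
#'
#' @param data 3D logical array.
#' @param spacing,origin as in [mmri_volume].
#' @return object of class `mmri_mask`.
#' @export
mmri_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("mask error: data must be a 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "mmri_mask")
}

#' @export
print.mmri_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mmri_mask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

mask_like <- function(vol, data) mmri_mask(data, vol$spacing, vol$origin)
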