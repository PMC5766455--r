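#' Profile line
#'
#' A straight line between two world points along which intensities are
#' sampled to choose a threshold window — the scripted equivalent of
#' drawing a profile line across a tissue boundary.
#'
#' @param p0,p1 endpoints, world mm.
#' @param n number of samples (>= 16).
#' @return object of class `profile_line`.
#' @export
profile_line <- function(p0, p1, n = 64L) {
  if (n < 16L) stop("profile error: need at least 16 samples")
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1), n = as.integer(n)),
            class = "profile_line")
}

# Otsu threshold over a sample vector: the cut maximizing between-class
# variance on a `bins`-bin histogram; returns the bin-edge intensity
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("no-contrast error: constant samples")
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                nbins = bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (edges[-(bins + 1L)] + diff(edges) / 2))
  mu_t <- mu[bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- -Inf
  # ties (any cut between well-separated groups maximizes the criterion)
  # resolve to the midpoint of the tied plateau, the conventional choice
  best <- max(bcv)
  ks <- which(bcv >= best - 1e-9 * max(abs(best), 1))
  mean(edges[ks + 1L])
}

#' Threshold window from a profile line
#'
#' Samples the volume along the line (trilinear interpolation) and returns
#' an intensity window for bright-structure segmentation: `low` is the Otsu
#' threshold of the samples (the cut maximizing between-class variance),
#' `high` the maximal sample. Deterministic.
#'
#' @param vol [mmri_volume].
#' @param line [profile_line] (endpoints inside the volume).
#' @return list `(low, high)`, signal units.
#' @export
profile_threshold <- function(vol, line) {
  stopifnot(inherits(vol, "mmri_volume"), inherits(line, "profile_line"))
  tt <- seq(0, 1, length.out = line$n)
  pts <- outer(1 - tt, line$p0) + outer(tt, line$p1)
  x <- sample_volume(vol, pts)
  if (diff(range(x)) <= 1e-12) stop("no-contrast error: profile is constant")
  list(low = otsu_threshold(x), high = max(x))
}

#' Region growing within an intensity window
#'
#' Collects the connected component (26-connected by default, 6-connected
#' optionally) of voxels with `low <= intensity <= high` containing the
#' seed voxel.
#'
#' @param vol [mmri_volume].
#' @param window numeric length-2 `(low, high)`.
#' @param seed_voxel 1-based voxel index `(i, j, k)`.
#' @param connectivity 26 or 6.
#' @return [mmri_mask].
#' @export
region_grow <- function(vol, window, seed_voxel, connectivity = 26L) {
  stopifnot(inherits(vol, "mmri_volume"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  d <- dim(vol$data)
  seed_voxel <- as.integer(round(seed_voxel))
  if (any(seed_voxel < 1L) || any(seed_voxel > d)) {
    stop("seed error: seed voxel outside volume")
  }
  inwin <- vol$data >= window[1] & vol$data <= window[2]
  lin <- (seed_voxel[3] - 1L) * d[1] * d[2] + (seed_voxel[2] - 1L) * d[1] +
    (seed_voxel[1] - 1L)
  grown <- cpp_region_grow(as.vector(inwin), as.integer(d), as.integer(lin),
                           as.integer(connectivity))
  mask_like(vol, array(grown, dim = d))
}

#' Scripted mask edits
#'
#' The reproducible stand-in for the manual erase/fill steps of the
#' semi-automatic workflow: a deterministic set-difference (`erase`)
#' followed by a set-union (`fill`).
#'
#' @param mask [mmri_mask].
#' @param erase,fill Nx3 matrices of 1-based voxel indices (or `NULL`).
#' @return edited [mmri_mask].
#' @export
edit_mask <- function(mask, erase = NULL, fill = NULL) {
  stopifnot(inherits(mask, "mmri_mask"))
  d <- dim(mask$data)
  out <- mask$data
  check <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(NULL)
    m <- matrix(as.integer(round(m)), ncol = 3)
    if (any(m < 1L) || any(sweep(m, 2, d, ">"))) {
      stop("bounds error: edit voxel indices outside mask")
    }
    m
  }
  e <- check(erase); f <- check(fill)
  if (!is.null(e)) out[e] <- FALSE
  if (!is.null(f)) out[f] <- TRUE
  mmri_mask(out, mask$spacing, mask$origin)
}

disk_offsets <- function(radius, mode) {
  r <- as.integer(radius)
  g <- -r:r
  if (mode == "slice") {
    off <- as.matrix(expand.grid(x = g, y = g, z = 0L))
  } else {
    off <- as.matrix(expand.grid(x = g, y = g, z = g))
  }
  keep <- rowSums(off^2) <= r^2 + 1e-9
  matrix(as.integer(off[keep, ]), ncol = 3)
}

#' Morphological closing of a binary mask
#'
#' Binary closing (dilation then erosion) with a disk structuring element
#' applied slice by slice (the default, mirroring a slice-wise 2D
#' workflow) or a 3D ball. The result contains the input and the operation
#' is idempotent.
#'
#' @param mask [mmri_mask].
#' @param radius_vox structuring element radius in voxels (>= 1).
#' @param mode "slice" (per-slice disk) or "3d" (ball).
#' @return closed [mmri_mask].
#' @export
morph_close <- function(mask, radius_vox = 1L, mode = c("slice", "3d")) {
  stopifnot(inherits(mask, "mmri_mask"))
  mode <- match.arg(mode)
  if (radius_vox < 1) stop("morphology error: radius must be >= 1")
  off <- disk_offsets(radius_vox, mode)
  d <- dim(mask$data)
  out <- cpp_binary_close(as.vector(mask$data), as.integer(d), off)
  mmri_mask(array(out, dim = d), mask$spacing, mask$origin)
}

#' Iso-surface extraction from a binary mask
#'
#' Extracts the 0.5 iso-surface of the (optionally Gaussian-smoothed) mask
#' using marching tetrahedra on the conforming six-tetrahedron cube split
#' — the tetrahedral variant of marching cubes, watertight by
#' construction. The field is zero-padded by one voxel so masks touching
#' the grid boundary still yield closed surfaces, and the raw iso-surface
#' is relaxed by a few Taubin (shrink-free) smoothing passes to remove the
#' tetrahedral faceting. For structures so small that smoothing pulls the
#' field peak below the level (single voxels), the level drops to half the
#' peak so the surface never vanishes. Vertices are returned in world mm
#' through the volume geometry.
#'
#' @param mask [mmri_mask].
#' @param smooth_sigma Gaussian pre-smoothing in voxels (0 disables).
#' @param level iso level on the smoothed indicator.
#' @param taubin_iterations Taubin smoothing passes on the extracted mesh
#'   (0 disables).
#' @return [surface_mesh].
#' @export
extract_surface <- function(mask, smooth_sigma = 0.5, level = 0.5,
                            taubin_iterations = 10L) {
  stopifnot(inherits(mask, "mmri_mask"))
  if (!any(mask$data)) stop("empty-segmentation error: mask has no foreground")
  d <- dim(mask$data)
  pad <- 1L + as.integer(ceiling(3 * smooth_sigma))
  dp <- d + 2L * pad
  field <- array(0, dim = dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$data)
  if (smooth_sigma > 0) {
    field <- cpp_gaussian_smooth(field, as.integer(dp),
                                 rep(smooth_sigma, 3))
  }
  level <- min(level, max(field) / 2)
  res <- cpp_marching_tets(field, as.integer(dp), level)
  if (nrow(res$vertices) == 0) stop("empty-segmentation error: no surface at iso level")
  verts <- res$vertices
  if (taubin_iterations > 0) {
    verts <- cpp_taubin_smooth(verts, res$faces, as.integer(taubin_iterations),
                               0.5, -0.53)
  }
  # padded 0-based grid coords -> 1-based voxel coords -> world
  idx <- sweep(verts, 2, pad - 1)
  verts <- sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  surface_mesh(verts, res$faces)
}

#' Segment one structure from a volume
#'
#' The full semi-automatic chain for one target: window threshold + region
#' growing from one or more seeds (components are unioned, e.g. tibia and
#' fibula), scripted edits, per-slice morphological closing, and surface
#' extraction.
#'
#' @param vol [mmri_volume].
#' @param window intensity window `(low, high)`.
#' @param seeds Nx3 matrix of 1-based seed voxels (one row per component).
#' @param erase,fill scripted edits, see [edit_mask].
#' @param closing_radius structuring radius for [morph_close] (0 skips).
#' @param closing_mode "slice" or "3d".
#' @param smooth_sigma surface smoothing, voxels.
#' @param connectivity region-growing connectivity.
#' @return list with `mask` ([mmri_mask]) and `mesh` ([surface_mesh]).
#' @export
segment_structure <- function(vol, window, seeds, erase = NULL, fill = NULL,
                              closing_radius = 1L, closing_mode = "slice",
                              smooth_sigma = 0.5, connectivity = 26L) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  acc <- NULL
  for (s in seq_len(nrow(seeds))) {
    m <- region_grow(vol, window, seeds[s, ], connectivity)
    acc <- if (is.null(acc)) m$data else acc | m$data
  }
  mask <- mask_like(vol, acc)
  mask <- edit_mask(mask, erase = erase, fill = fill)
  if (closing_radius >= 1) mask <- morph_close(mask, closing_radius, closing_mode)
  list(mask = mask, mesh = extract_surface(mask, smooth_sigma))
}

#' Sub-voxel boundary refinement of a segmentation surface
#'
#' Window thresholding places the binarized boundary where the
#' partial-volume intensity ramp crosses the window edge, not at the true
#' tissue interface; with anisotropic voxels the shift differs by surface
#' orientation (up to half a slice thickness through-plane). This step
#' relocates every vertex along its outward normal to the half-way
#' intensity crossing of the local partial-volume ramp: the intensity
#' profile is sampled within 1.2 directional voxel footprints of the
#' vertex and the vertex moves to the nearest crossing of the midpoint
#' between the inside and outside intensities -- the interface position
#' under linear mixing. Vertices without a clear local contrast are left
#' in place.
#'
#' @param mesh segmentation `surface_mesh` (outward-oriented normals).
#' @param vol the [mmri_volume] the mask came from.
#' @param window the intensity window used for segmentation.
#' @return refined `surface_mesh`.
#' @export
refine_surface_subvoxel <- function(mesh, vol, window) {
  v <- mesh$vertices
  n <- mesh_vertex_normals(mesh)
  w <- as.numeric(abs(n) %*% vol$spacing) # directional voxel footprint
  d <- dim(vol$data)
  clamp <- function(p) {
    lo <- vol$origin + 1e-6
    hi <- vol$origin + (d - 1) * vol$spacing - 1e-6
    pmin(pmax(p, rep(lo, each = nrow(p))), rep(hi, each = nrow(p)))
  }
  # search within +-1 footprint: enough to undo the binarization staircase
  # (up to half a slice) while the nearest-crossing rule keeps vertices of
  # thin structures on their own wall
  ss <- seq(-1, 1, length.out = 9L) # profile positions in units of w
  P <- vapply(ss, function(s) sample_volume(vol, clamp(v + n * (s * w))),
              numeric(nrow(v)))
  I_in <- P[, 1]; I_out <- P[, ncol(P)]
  mid <- (I_in + I_out) / 2
  span <- max(abs(diff(window)), 1e-12)
  # crossing of the half-way intensity nearest the current vertex
  best_t <- rep(NA_real_, nrow(v))
  for (k in seq_len(length(ss) - 1L)) {
    D0 <- P[, k] - mid; D1 <- P[, k + 1] - mid
    crossing <- D0 * D1 <= 0 & D0 != D1
    tk <- ss[k] + (0 - D0) / (D1 - D0) * (ss[k + 1] - ss[k])
    take <- crossing & (is.na(best_t) | abs(tk) < abs(best_t))
    best_t[take] <- tk[take]
  }
  ok <- !is.na(best_t) & abs(I_out - I_in) > 0.2 * span
  delta <- ifelse(ok, best_t * w, 0)
  # relax residual wrinkles where neighbouring vertices locked onto
  # different crossings
  out <- cpp_taubin_smooth(v + n * delta, mesh$faces, 5L, 0.5, -0.53)
  surface_mesh(out, mesh$faces)
}
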