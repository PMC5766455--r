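#' Triangulated surface mesh
#'
#' Vertices in world mm, triangular faces as 1-based vertex indices.
#' Used for the parametric reference models and for segmentation surfaces.
#'
#' @param vertices Nx3 numeric matrix, mm.
#' @param faces Mx3 integer matrix, 1-based.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("mesh error: vertices must be Nx3")
  if (ncol(faces) != 3L) stop("mesh error: faces must be Mx3 (triangles only)")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("mesh error: face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh summaries
#'
#' `mesh_bbox` returns the 2x3 axis-aligned bounding box (min/max rows);
#' `mesh_area` the total surface area in mm^2; `mesh_centroid` the vertex
#' centroid; `mesh_area_centroid` the area-weighted surface centroid.
#'
#' @param mesh `surface_mesh`.
#' @return see description.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

triangle_data <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(centroid = (a + b + cc) / 3,
       area = 0.5 * sqrt(rowSums(cr^2)),
       normal = cr)
}

#' @rdname mesh_bbox
#' @export
mesh_area <- function(mesh) sum(triangle_data(mesh)$area)

#' @rdname mesh_bbox
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' @rdname mesh_bbox
#' @export
mesh_area_centroid <- function(mesh) {
  td <- triangle_data(mesh)
  colSums(td$centroid * td$area) / sum(td$area)
}

#' Watertightness check
#'
#' A closed triangulated surface has every undirected edge shared by exactly
#' two faces.
#'
#' @param mesh `surface_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Apply a rigid transform to a mesh
#' @param x `rigid_transform`.
#' @param mesh `surface_mesh`.
#' @return transformed `surface_mesh`.
#' @export
transform_mesh <- function(x, mesh) {
  surface_mesh(transform_points(x, mesh$vertices), mesh$faces)
}

#' Concatenate meshes into one (multi-component) mesh
#' @param ... `surface_mesh` objects.
#' @return `surface_mesh`.
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  off <- 0L
  vs <- list(); fs <- list()
  for (m in ms) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

## --- parametric primitives -------------------------------------------------
## Builders for the CAD-like reference models. All are watertight by
## construction; caps of non-convex outlines use ear clipping.

# ear-clipping triangulation of a simple (possibly non-convex) CCW polygon;
# returns Mx3 indices into the polygon rows
ear_clip <- function(poly) {
  n <- nrow(poly)
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_tri <- function(p, a, b, c) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c, p); d3 <- cross2(c, a, p)
    !(any(c(d1, d2, d3) < -1e-12) && any(c(d1, d2, d3) > 1e-12))
  }
  guard <- 0L
  while (length(idx) > 3L) {
    guard <- guard + 1L
    if (guard > 10000L) stop("mesh error: ear clipping failed (polygon not simple?)")
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[(k - 2) %% m + 1]; i1 <- idx[(k - 1) %% m + 1]; i2 <- idx[k %% m + 1]
      a <- poly[i0, ]; b <- poly[i1, ]; cc <- poly[i2, ]
      if (cross2(a, b, cc) <= 1e-12) next # reflex or degenerate corner
      others <- setdiff(idx, c(i0, i1, i2))
      if (any(vapply(others, function(j) in_tri(poly[j, ], a, b, cc), logical(1)))) next
      tris <- rbind(tris, c(i0, i1, i2))
      idx <- setdiff(idx, i1)
      clipped <- TRUE
      break
    }
    if (!clipped) stop("mesh error: ear clipping failed (no ear found)")
  }
  rbind(tris, idx)
}

# extrude a CCW 2D polygon from z0 to z1 (z1 > z0); watertight prism
extrude_polygon <- function(poly, z0, z1) {
  n <- nrow(poly)
  vb <- cbind(poly, z0)
  vt <- cbind(poly, z1)
  verts <- rbind(vb, vt)
  tri <- ear_clip(poly)
  # bottom cap faces down (reverse CCW), top cap faces up
  faces <- rbind(tri[, c(1, 3, 2)], tri + n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    faces <- rbind(faces, c(i, j, j + n), c(i, j + n, i + n))
  }
  surface_mesh(verts, faces)
}

# solid (possibly tapered) cylinder along z with disc caps
cylinder_mesh <- function(center_xy = c(0, 0), radius0, radius1 = radius0,
                          z0, z1, n_theta = 32, n_z = 8) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(z0, z1, length.out = n_z + 1)
  rs <- seq(radius0, radius1, length.out = n_z + 1)
  verts <- do.call(rbind, lapply(seq_along(zs), function(i) {
    cbind(center_xy[1] + rs[i] * cos(th), center_xy[2] + rs[i] * sin(th), zs[i])
  }))
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n_z)) {
    base0 <- (i - 1L) * n_theta; base1 <- i * n_theta
    for (k in seq_len(n_theta)) {
      k2 <- k %% n_theta + 1L
      faces <- rbind(faces,
                     c(base0 + k, base0 + k2, base1 + k2),
                     c(base0 + k, base1 + k2, base1 + k))
    }
  }
  # cap centers
  cb <- nrow(verts) + 1L; ct <- nrow(verts) + 2L
  verts <- rbind(verts, c(center_xy, z0), c(center_xy, z1))
  topb <- n_z * n_theta
  for (k in seq_len(n_theta)) {
    k2 <- k %% n_theta + 1L
    faces <- rbind(faces, c(cb, k2, k), c(ct, topb + k, topb + k2))
  }
  surface_mesh(verts, faces)
}

# hollow tapered tube (cortical shell): outer wall, inner wall, annular caps
tube_mesh <- function(center_xy = c(0, 0), router0, router1, rinner0, rinner1,
                      z0, z1, n_theta = 48, n_z = 24) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(z0, z1, length.out = n_z + 1)
  ro <- seq(router0, router1, length.out = n_z + 1)
  ri <- seq(rinner0, rinner1, length.out = n_z + 1)
  ring <- function(r, z) cbind(center_xy[1] + r * cos(th), center_xy[2] + r * sin(th), z)
  vo <- do.call(rbind, lapply(seq_along(zs), function(i) ring(ro[i], zs[i])))
  vi <- do.call(rbind, lapply(seq_along(zs), function(i) ring(ri[i], zs[i])))
  verts <- rbind(vo, vi)
  n_out <- nrow(vo)
  faces <- matrix(0L, 0, 3)
  band <- function(base0, base1, flip = FALSE) {
    fs <- matrix(0L, 0, 3)
    for (k in seq_len(n_theta)) {
      k2 <- k %% n_theta + 1L
      q <- rbind(c(base0 + k, base0 + k2, base1 + k2),
                 c(base0 + k, base1 + k2, base1 + k))
      if (flip) q <- q[, c(1, 3, 2)]
      fs <- rbind(fs, q)
    }
    fs
  }
  for (i in seq_len(n_z)) {
    faces <- rbind(faces,
                   band((i - 1L) * n_theta, i * n_theta),                      # outer, outward
                   band(n_out + (i - 1L) * n_theta, n_out + i * n_theta, TRUE)) # inner, inward
  }
  # annular caps: bottom (z0, faces down), top (z1, faces up)
  bot_o <- 0L; bot_i <- n_out
  top_o <- n_z * n_theta; top_i <- n_out + n_z * n_theta
  for (k in seq_len(n_theta)) {
    k2 <- k %% n_theta + 1L
    faces <- rbind(faces,
                   c(bot_o + k, bot_i + k2, bot_o + k2),
                   c(bot_o + k, bot_i + k, bot_i + k2),
                   c(top_o + k, top_o + k2, top_i + k2),
                   c(top_o + k, top_i + k2, top_i + k))
  }
  surface_mesh(verts, faces)
}

#' Vertex normals and normal offsetting
#'
#' `mesh_vertex_normals` returns per-vertex unit normals (area-weighted
#' average of incident face normals, outward for consistently oriented
#' meshes). `mesh_offset` displaces every vertex along its normal —
#' negative distances shrink the surface. Used to compensate the
#' metal-artifact signal void, which overestimates the implant by the halo
#' radius.
#'
#' @param mesh `surface_mesh`.
#' @param distance signed offset along the outward normal, mm.
#' @return `mesh_vertex_normals`: Nx3 matrix; `mesh_offset`: `surface_mesh`.
#' @export
mesh_vertex_normals <- function(mesh) {
  td <- triangle_data(mesh)
  f <- as.vector(mesh$faces)
  fn <- td$normal[rep(seq_len(nrow(mesh$faces)), 3), , drop = FALSE]
  acc <- rowsum(fn, f)
  n <- matrix(0, nrow(mesh$vertices), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- pmax(sqrt(rowSums(n^2)), 1e-30)
  n / len
}

#' @rdname mesh_vertex_normals
#' @export
mesh_offset <- function(mesh, distance) {
  surface_mesh(mesh$vertices + distance * mesh_vertex_normals(mesh),
               mesh$faces)
}

#' Midpoint subdivision to a target edge length
#'
#' Splits every triangle into four at the edge midpoints, repeatedly,
#' until no edge exceeds `max_edge`. Keeps the geometry piecewise planar
#' while making vertex density roughly uniform over the surface — the
#' parametric reference models are refined this way so that vertex-based
#' alignment is not biased toward densely meshed features.
#'
#' @param mesh `surface_mesh`.
#' @param max_edge target maximal edge length, mm.
#' @param max_rounds safety cap on subdivision rounds.
#' @return refined `surface_mesh`.
#' @export
mesh_subdivide <- function(mesh, max_edge, max_rounds = 8L) {
  for (round in seq_len(max_rounds)) {
    v <- mesh$vertices; f <- mesh$faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    elen <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                            v[e[, 2], , drop = FALSE])^2))
    if (max(elen) <= max_edge) break
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(key)
    mid_id <- nrow(v) + match(key, uk)
    first <- !duplicated(key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    newf <- rbind(cbind(f[, 1], m12, m31),
                  cbind(m12, f[, 2], m23),
                  cbind(m31, m23, f[, 3]),
                  cbind(m12, m23, m31))
    mesh <- surface_mesh(rbind(v, mids), newf)
  }
  mesh
}
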