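#' Registration result
#'
#' A rigid transform mapping the reference-model frame into the acquisition
#' frame, with the residual RMS distance (mm), the number of points used
#' and the method tag ("landmark" or "global+icp").
#'
#' @keywords internal
registration_result <- function(transform, rms, n_points, method,
                                converged = TRUE, rms_history = numeric()) {
  assert_transform(transform)
  if (rms < 0) stop("registration error: rms must be >= 0")
  structure(list(transform = transform, rms = rms, n_points = n_points,
                 method = method, converged = converged,
                 rms_history = rms_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: rms %.4f mm over %d points%s\n",
              x$method, x$rms, x$n_points,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

subsample_rows <- function(m, n, seed) {
  if (nrow(m) <= n) return(m)
  keep <- with_seed(seed, sample.int(nrow(m), n))
  m[keep, , drop = FALSE]
}

nn_rms <- function(pts, ref) {
  sqrt(mean(cpp_nearest_neighbor(pts, ref, -1)$distance^2))
}

#' Coarse global alignment of two meshes
#'
#' Centroid matching plus principal-axes alignment, both area-weighted over
#' the triangles so vertex density does not bias the fit. Among the four
#' proper-rotation sign assignments of the first two principal axes the one
#' with the lowest subsampled nearest-neighbour RMS wins (ties broken by
#' candidate order). Shapes with two nearly equal principal moments (within
#' 1 %) are rejected as ambiguous — fall back to landmark registration for
#' those.
#'
#' @param moving,fixed `surface_mesh` objects (moving is mapped onto fixed).
#' @param n_sample vertices subsampled for candidate scoring.
#' @param seed subsampling seed.
#' @return [rigid_transform] mapping moving onto fixed.
#' @export
global_align <- function(moving, fixed, n_sample = 2000L, seed = 1L) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  axes_of <- function(mesh) {
    td <- triangle_data(mesh)
    w <- td$area / sum(td$area)
    ctr <- colSums(td$centroid * w)
    X <- sweep(td$centroid, 2, ctr)
    C <- crossprod(X * w, X)
    e <- eigen(C, symmetric = TRUE)
    if (e$values[1] <= 0) stop("ambiguous-alignment error: degenerate mesh")
    rel <- abs(diff(e$values)) / e$values[1]
    if (any(rel < 0.01)) {
      stop("ambiguous-alignment error: two principal moments within 1 %; use landmark registration")
    }
    V <- e$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    list(center = ctr, V = V)
  }
  am <- axes_of(moving); af <- axes_of(fixed)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- subsample_rows(moving$vertices, n_sample, seed)
  best <- NULL; best_rms <- Inf
  for (s in signs) {
    R <- af$V %*% diag(s) %*% t(am$V)
    tr <- rigid_transform(R, af$center - as.numeric(R %*% am$center))
    r <- nn_rms(transform_points(tr, sub), fixed$vertices)
    if (r < best_rms - 1e-12) { best_rms <- r; best <- tr }
  }
  best
}

#' Iterative closest point refinement
#'
#' Point-to-point ICP: subsampled moving vertices are matched to their
#' nearest fixed vertices, a rigid Procrustes fit updates the transform,
#' and the loop repeats until the RMS change drops below `tol_mm` or
#' `max_iter` is reached. The correspondence RMS is non-increasing across
#' iterations. Deterministic for a fixed subsample seed. Non-convergence
#' flags the result rather than raising.
#'
#' @param moving,fixed `surface_mesh` objects.
#' @param init [rigid_transform] initial guess (moving -> fixed).
#' @param max_iter,tol_mm stopping rule.
#' @param n_sample moving vertices subsampled for correspondences.
#' @param seed subsampling seed.
#' @param trim fraction of worst correspondences discarded per iteration
#'   (0 disables; use ~0.1 for artifact-cropped segmentations).
#' @return `registration_result` (method "global+icp").
#' @export
icp_refine <- function(moving, fixed, init = identity_transform(),
                       max_iter = 100L, tol_mm = 1e-4, n_sample = 2000L,
                       seed = 1L, trim = 0) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  assert_transform(init, "init")
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0) {
    stop("registration error: empty mesh")
  }
  src <- subsample_rows(moving$vertices, n_sample, seed)
  tr <- init
  hist <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- transform_points(tr, src)
    nn <- cpp_nearest_neighbor(cur, fixed$vertices, -1)
    keep <- seq_len(nrow(src))
    if (trim > 0) {
      k <- max(3L, floor(length(keep) * (1 - trim)))
      keep <- order(nn$distance)[seq_len(k)]
    }
    rms <- sqrt(mean(nn$distance[keep]^2))
    hist <- c(hist, rms)
    if (it > 1 && abs(hist[it - 1] - rms) < tol_mm) { converged <- TRUE; break }
    fit <- procrustes_rigid_fit(src[keep, , drop = FALSE],
                                fixed$vertices[nn$index[keep], , drop = FALSE])
    tr <- fit$transform
  }
  registration_result(tr, hist[length(hist)], length(keep), "global+icp",
                      converged = converged, rms_history = hist)
}

#' Landmark-based registration (manual-fit surrogate)
#'
#' Rigid Procrustes fit on matched named landmark pairs — the reproducible
#' stand-in for an expert manually fitting the prosthesis model to its
#' segmentation on landmarks such as the posterior edge and the distal
#' notch. Optionally polished by one ICP pass.
#'
#' @param model_landmarks,seg_landmarks named Nx3 matrices (same names,
#'   >= 3, non-collinear); model side in the reference frame, segmentation
#'   side in the acquisition frame.
#' @param refine run an ICP polish from the landmark fit (requires meshes).
#' @param moving_mesh,fixed_mesh meshes for the polish.
#' @param ... passed to [icp_refine].
#' @return `registration_result` (method "landmark").
#' @export
landmark_register <- function(model_landmarks, seg_landmarks, refine = FALSE,
                              moving_mesh = NULL, fixed_mesh = NULL, ...) {
  ml <- as.matrix(model_landmarks); sl <- as.matrix(seg_landmarks)
  if (is.null(rownames(ml)) || is.null(rownames(sl)) ||
      !setequal(rownames(ml), rownames(sl))) {
    stop("degenerate-configuration: landmark name sets must match on both sides")
  }
  if (nrow(ml) < 3L) stop("degenerate-configuration: need at least 3 landmarks")
  sl <- sl[rownames(ml), , drop = FALSE]
  fit <- procrustes_rigid_fit(ml, sl)
  res <- registration_result(fit$transform, fit$rms, nrow(ml), "landmark")
  if (refine) {
    if (is.null(moving_mesh) || is.null(fixed_mesh)) {
      stop("configuration error: refine = TRUE requires moving_mesh and fixed_mesh")
    }
    icp <- icp_refine(moving_mesh, fixed_mesh, init = fit$transform, ...)
    res <- registration_result(icp$transform, icp$rms, icp$n_points,
                               "landmark", converged = icp$converged,
                               rms_history = icp$rms_history)
  }
  res
}

#' Register one acquisition with one of the three strategies
#'
#' Maps the bone and implant reference models into the acquisition frame:
#' * `mmri-m` (manual surrogate): bone by global + ICP to the bone
#'   reference model; implant by landmark registration (with ICP polish).
#' * `mmri-a` (automatic, model-based): both structures by global + ICP to
#'   the reference models.
#' * `mmri-w` (automatic, model-free): both structures by global + ICP,
#'   with acquisition 1's segmentations supplied as the references.
#'
#' @param seg_bone,seg_implant segmentation `surface_mesh`es of this
#'   acquisition.
#' @param refs list with `bone` and `implant` reference meshes (for
#'   `mmri-w`: the acquisition-1 segmentations).
#' @param method "mmri-m", "mmri-a" or "mmri-w".
#' @param landmarks for `mmri-m`: list with `model` (named Nx3, reference
#'   frame) and `seg` (named Nx3, acquisition frame).
#' @param n_sample,tol_mm,max_iter,seed,trim ICP parameters.
#' @return list with `bone` and `implant` `registration_result`s.
#' @export
register_acquisition <- function(seg_bone, seg_implant, refs,
                                 method = c("mmri-a", "mmri-m", "mmri-w"),
                                 landmarks = NULL, n_sample = 2000L,
                                 tol_mm = 1e-4, max_iter = 100L, seed = 1L,
                                 trim = 0) {
  method <- match.arg(method)
  auto <- function(ref_mesh, seg_mesh) {
    init <- global_align(ref_mesh, seg_mesh, n_sample = n_sample, seed = seed)
    icp_refine(ref_mesh, seg_mesh, init = init, max_iter = max_iter,
               tol_mm = tol_mm, n_sample = n_sample, seed = seed, trim = trim)
  }
  bone <- auto(refs$bone, seg_bone)
  implant <- if (method == "mmri-m") {
    if (is.null(landmarks) || is.null(landmarks$model) || is.null(landmarks$seg)) {
      stop("configuration error: mmri-m requires implant landmarks (model + seg sides)")
    }
    landmark_register(landmarks$model, landmarks$seg, refine = TRUE,
                      moving_mesh = refs$implant, fixed_mesh = seg_implant,
                      n_sample = n_sample, tol_mm = tol_mm,
                      max_iter = max_iter, seed = seed, trim = trim)
  } else {
    auto(refs$implant, seg_implant)
  }
  list(bone = bone, implant = implant)
}
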