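#' Rigid transform in 3D
#'
#' A proper rigid-body map `x -> R x + t`: a 3x3 rotation matrix (orthonormal,
#' determinant +1 — no reflection, no scaling) plus a translation vector in mm.
#' These are the currency of the whole pipeline: registration results,
#' phantom relocations, implant-in-bone poses and per-pair migrations are all
#' rigid transforms.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation length-3 numeric, mm.
#' @param validate check orthonormality and determinant (tolerance 1e-9).
#' @return object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            validate = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)) ||
      any(!is.finite(rotation))) {
    stop("invalid-transform: rotation/translation must be finite (3x3, 3)")
  }
  if (validate) {
    err_orth <- max(abs(crossprod(rotation) - diag(3)))
    if (err_orth > 1e-9) {
      stop(sprintf("invalid-transform: rotation not orthonormal (max |R'R - I| = %.3g)",
                   err_orth))
    }
    if (abs(det(rotation) - 1) > 1e-9) {
      stop(sprintf("invalid-transform: det(R) = %.12f, expected +1 (reflection/scaling not allowed)",
                   det(rotation)))
    }
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation (mm):", paste(signif(x$t, 6), collapse = ", "), "\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

assert_transform <- function(x, what = "transform") {
  if (!is_rigid_transform(x)) stop(sprintf("invalid-transform: %s is not a rigid_transform", what))
  rigid_transform(x$R, x$t) # re-validate invariants
  invisible(x)
}

#' Identity transform
#' @return identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`compose(a, b)(x) = a(b(x))`).
#'
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  assert_transform(a, "a"); assert_transform(b, "b")
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x `rigid_transform`.
#' @return `rigid_transform` with `compose_transforms(x, invert_transform(x))`
#'   the identity.
#' @export
invert_transform <- function(x) {
  assert_transform(x)
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' Apply a rigid transform to points
#' @param x `rigid_transform`.
#' @param pts Nx3 matrix (or length-3 vector) of points, mm.
#' @return Nx3 matrix of transformed points.
#' @export
transform_points <- function(x, pts) {
  assert_transform(x)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(x$R), 2, x$t, "+")
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation about a (not necessarily unit) axis, right-handed.
#'
#' @param axis length-3 direction.
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Anatomical reporting frame
#'
#' The frame in which six-degree-of-freedom migrations are reported: an
#' origin (the implant "midpoint", mm) and three right-handed orthonormal
#' axes — medial-lateral (`axis_ml`), distal-proximal (`axis_dp`, pointing
#' proximal) and posterior-anterior (`axis_pa`, pointing anterior).
#' Right-handedness is required in the order (ml, dp, pa):
#' `axis_ml x axis_dp = axis_pa`. Flip individual axes to change sign
#' conventions; the decomposition follows the frame.
#'
#' @param origin length-3, mm.
#' @param axis_ml,axis_dp,axis_pa length-3 unit vectors.
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0),
                             axis_ml = c(-1, 0, 0),
                             axis_dp = c(0, 0, 1),
                             axis_pa = c(0, 1, 0)) {
  A <- cbind(as.numeric(axis_ml), as.numeric(axis_dp), as.numeric(axis_pa))
  if (max(abs(crossprod(A) - diag(3))) > 1e-9) {
    stop("invalid-frame: axes are not orthonormal")
  }
  cr <- c(A[2, 1] * A[3, 2] - A[3, 1] * A[2, 2],
          A[3, 1] * A[1, 2] - A[1, 1] * A[3, 2],
          A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2])
  if (max(abs(cr - A[, 3])) > 1e-9) {
    stop("invalid-frame: axes are not right-handed (axis_ml x axis_dp must equal axis_pa)")
  }
  structure(list(origin = as.numeric(origin), A = A), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  axes (columns ml, dp, pa):\n"); print(round(x$A, 6))
  invisible(x)
}

#' Serialize / deserialize a rigid transform
#'
#' JSON carries the row-major rotation, the translation, the Euler-convention
#' tag used throughout the package and optional frame metadata, so that
#' transform files are self-describing.
#'
#' @param x `rigid_transform`.
#' @param frame optional `anatomical_frame` stored as metadata.
#' @return `transform_to_list`: a plain list; `transform_from_list`: a
#'   `rigid_transform`.
#' @export
transform_to_list <- function(x, frame = NULL) {
  assert_transform(x)
  out <- list(
    rotation_row_major = as.numeric(t(x$R)),
    translation_mm = x$t,
    euler_convention = euler_convention_tag()
  )
  if (!is.null(frame)) {
    out$frame <- list(origin_mm = frame$origin,
                      axis_ml = frame$A[, 1], axis_dp = frame$A[, 2],
                      axis_pa = frame$A[, 3])
  }
  out
}

#' @rdname transform_to_list
#' @param lst list as produced by `transform_to_list` (or parsed JSON).
#' @export
transform_from_list <- function(lst) {
  rigid_transform(matrix(as.numeric(lst$rotation_row_major), 3, 3, byrow = TRUE),
                  as.numeric(lst$translation_mm))
}

euler_convention_tag <- function() {
  "fixed-axis ML->DP->PA (R = R_pa * R_dp * R_ml), degrees, right-handed"
}
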