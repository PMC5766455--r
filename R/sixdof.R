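#' Six-degree-of-freedom migration record
#'
#' One acquisition-pair migration decomposed on anatomical axes: three
#' translations in mm (medial-lateral `t_ml`, distal-proximal `t_dp`,
#' posterior-anterior `t_pa`) and three rotations in degrees
#' (flexion-extension `r_fe`, about the ML axis; external-internal `r_ei`,
#' about the DP axis; varus-valgus `r_vv`, about the PA axis).
#'
#' @param t_ml,t_dp,t_pa translations, mm.
#' @param r_fe,r_ei,r_vv rotations, degrees.
#' @param pair optional length-2 integer, the ordered (acquisition,
#'   reference acquisition) indices.
#' @return object of class `migration_record`.
#' @export
migration_record <- function(t_ml = 0, t_dp = 0, t_pa = 0,
                             r_fe = 0, r_ei = 0, r_vv = 0, pair = NULL) {
  v <- c(t_ml = t_ml, t_dp = t_dp, t_pa = t_pa,
         r_fe = r_fe, r_ei = r_ei, r_vv = r_vv)
  if (any(!is.finite(v))) stop("invalid-record: all six components must be finite")
  if (any(abs(v[4:6]) >= 180)) stop("invalid-record: |rotation| must be < 180 degrees")
  structure(c(as.list(v), list(pair = pair)), class = "migration_record")
}

#' @export
print.migration_record <- function(x, ...) {
  cat(sprintf("migration_record%s\n  t (ml, dp, pa) mm : %7.3f %7.3f %7.3f\n  r (fe, ei, vv) deg: %7.3f %7.3f %7.3f\n",
              if (!is.null(x$pair)) sprintf(" [pair %d (%d)]", x$pair[1], x$pair[2]) else "",
              x$t_ml, x$t_dp, x$t_pa, x$r_fe, x$r_ei, x$r_vv))
  invisible(x)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Decompose a rigid transform into six anatomical degrees of freedom
#'
#' Translations are the displacement of the frame origin (the implant
#' midpoint) under the transform, projected on the frame axes.
#' Rotations are fixed-axis Euler angles in the sequence ML -> DP -> PA
#' (`R = R_pa R_dp R_ml` in frame coordinates), reported in degrees.
#' The decomposition is exact for DP angles away from +-90 degrees; at
#' gimbal lock an explicit error is raised rather than silently wrapping.
#'
#' @param m `rigid_transform`.
#' @param frame `anatomical_frame`.
#' @param pair passed through to the record.
#' @return [migration_record].
#' @export
decompose_6dof <- function(m, frame, pair = NULL) {
  assert_transform(m)
  if (!inherits(frame, "anatomical_frame")) stop("invalid-frame: not an anatomical_frame")
  A <- frame$A
  disp <- as.numeric(m$R %*% frame$origin + m$t) - frame$origin
  t_loc <- as.numeric(crossprod(A, disp))
  Rf <- crossprod(A, m$R %*% A) # rotation expressed in (ml, dp, pa) basis
  # Rf = Rz(vv) Ry(ei) Rx(fe); Rf[3,1] = -sin(ei)
  s_ei <- -Rf[3, 1]
  if (abs(s_ei) > 1 - 1e-9) {
    stop("gimbal-lock: |distal-proximal rotation| at 90 degrees, decomposition undefined")
  }
  ei <- asin(max(-1, min(1, s_ei)))
  fe <- atan2(Rf[3, 2], Rf[3, 3])
  vv <- atan2(Rf[2, 1], Rf[1, 1])
  migration_record(t_loc[1], t_loc[2], t_loc[3],
                   fe * 180 / pi, ei * 180 / pi, vv * 180 / pi, pair = pair)
}

#' Compose a rigid transform from six anatomical degrees of freedom
#'
#' Exact right-inverse of [decompose_6dof] for rotation magnitudes below
#' 90 degrees; used by the phantom simulator to inject known migrations.
#'
#' @param rec [migration_record].
#' @param frame `anatomical_frame`.
#' @return [rigid_transform].
#' @export
compose_6dof <- function(rec, frame) {
  if (!inherits(rec, "migration_record")) stop("invalid-record: not a migration_record")
  if (!inherits(frame, "anatomical_frame")) stop("invalid-frame: not an anatomical_frame")
  A <- frame$A
  d2r <- pi / 180
  Rf <- rot_z(rec$r_vv * d2r) %*% rot_y(rec$r_ei * d2r) %*% rot_x(rec$r_fe * d2r)
  R <- A %*% Rf %*% t(A)
  t_world <- as.numeric(A %*% c(rec$t_ml, rec$t_dp, rec$t_pa))
  rigid_transform(R, frame$origin + t_world - as.numeric(R %*% frame$origin))
}
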