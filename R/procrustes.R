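#' Rigid orthogonal Procrustes fit
#'
#' Least-squares rigid superimposition of `source` onto `target`: the
#' rotation and translation (no scaling) minimizing the sum of squared
#' distances between corresponding points. Solved via the SVD of the
#' cross-covariance matrix with a determinant correction so that the
#' returned rotation is always proper (det +1, never a reflection), the
#' standard Kabsch/Umeyama construction.
#'
#' @param source,target Nx3 matrices, mm; rows correspond (same N >= 3).
#' @return list with `transform` (a [rigid_transform] mapping source onto
#'   target) and `rms` (root-mean-square residual, mm).
#' @export
procrustes_rigid_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!is.numeric(source) || !is.numeric(target) ||
      ncol(source) != 3L || ncol(target) != 3L) {
    stop("degenerate-configuration: point sets must be Nx3 numeric matrices")
  }
  n <- nrow(source)
  if (nrow(target) != n) stop("degenerate-configuration: point counts differ")
  if (n < 3L) stop("degenerate-configuration: need at least 3 points")
  cs <- colMeans(source); ct <- colMeans(target)
  X <- sweep(source, 2, cs); Y <- sweep(target, 2, ct)
  # collinear (or coincident) sources leave the rotation under-determined
  sv_x <- svd(X, nu = 0, nv = 0)$d
  if (sv_x[2] <= 1e-9 * max(sv_x[1], 1e-12)) {
    stop("degenerate-configuration: source points are collinear")
  }
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
  resid <- transform_points(tr, source) - target
  list(transform = tr, rms = sqrt(mean(rowSums(resid^2))))
}
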