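#' Principal-component frame of a 3-D point cloud
#'
#' Computes the centroid and the orthonormal eigenvector frame of the
#' sample covariance of `points`, with axes ordered by decreasing
#' explained variance. The eigenvector sign ambiguity is resolved by a
#' fixed convention: each axis is flipped so that its largest-magnitude
#' component is positive, and the third axis is then flipped if needed so
#' that the frame is right-handed. Downstream measurements must be (and
#' are tested to be) invariant to the underlying sign ambiguity.
#'
#' @param points numeric matrix with 3 columns (one point per row), at
#'   least 4 rows. Planar clouds are accepted (the third eigenvalue is
#'   then ~0 and the third axis is the plane normal); collinear clouds
#'   are rejected.
#' @return an object of class `pca_frame`: a list with `centroid_mm`
#'   (length-3), `axes` (3x3 matrix, axes in columns) and `eigenvalues`
#'   (length-3, descending).
#' @export
pca_frame <- function(points) {
  points <- as_points3(points)
  if (nrow(points) < 4L) stop("pca_frame() needs at least 4 points")
  centroid <- colMeans(points)
  cc <- sweep(points, 2L, centroid)
  cv <- crossprod(cc) / (nrow(points) - 1L)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (vals[2L] <= vals[1L] * 1e-12)
    stop("degenerate point cloud: points are collinear (covariance rank < 2)")
  axes <- fix_axis_signs(e$vectors)
  structure(
    list(centroid_mm = centroid, axes = axes, eigenvalues = vals),
    class = "pca_frame"
  )
}

# Sign convention shared by every PCA-based operation: largest-magnitude
# component positive per axis, then restore right-handedness on axis 3.
fix_axis_signs <- function(V) {
  for (i in 1:3) {
    if (V[which.max(abs(V[, i])), i] < 0) V[, i] <- -V[, i]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Total-least-squares plane fit
#'
#' Fits a plane through a point cloud by orthogonal (total) least
#' squares: the normal is the eigenvector of the smallest covariance
#' eigenvalue and the plane passes through the centroid. No axis is
#' privileged, which suits semicircular-canal point sets.
#'
#' @param points numeric matrix with 3 columns, at least 3 non-collinear
#'   rows.
#' @return an object of class `plane_fit`: list with unit `normal`,
#'   `centroid_mm`, and `rms_residual_mm` (root of the smallest
#'   covariance eigenvalue; 0 iff the points are exactly coplanar).
#' @export
fit_plane <- function(points) {
  points <- as_points3(points)
  if (nrow(points) < 3L) stop("fit_plane() needs at least 3 points")
  centroid <- colMeans(points)
  cc <- sweep(points, 2L, centroid)
  cv <- crossprod(cc) / max(nrow(points) - 1L, 1L)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (vals[2L] <= vals[1L] * 1e-12)
    stop("cannot fit a plane: points are collinear")
  n <- e$vectors[, 3L]
  if (n[which.max(abs(n))] < 0) n <- -n
  structure(
    list(normal = n, centroid_mm = centroid,
         rms_residual_mm = sqrt(vals[3L])),
    class = "plane_fit"
  )
}

#' Angle between two vectors
#'
#' Evaluates `theta = acos(u . v / (|u| |v|))` in degrees. With
#' `fold = TRUE` the angle is folded to `[0, 90]` as
#' `min(theta, 180 - theta)`, which makes it insensitive to the sign of
#' either vector; all inter-structure angles reported by this package
#' are folded.
#'
#' @param u,v nonzero numeric 3-vectors.
#' @param fold fold the angle into `[0, 90]` degrees?
#' @return angle in degrees, in `[0, 180]` (or `[0, 90]` folded).
#' @export
angle_between_vectors <- function(u, v, fold = FALSE) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angle is undefined for a zero vector")
  ct <- sum(u * v) / (nu * nv)
  theta <- acos(min(1, max(-1, ct))) * 180 / pi
  if (fold) min(theta, 180 - theta) else theta
}

#' Dihedral angle between two fitted planes
#'
#' Folded angle between the plane normals, in `[0, 90]` degrees;
#' symmetric in its arguments.
#'
#' @param p,q `plane_fit` objects (or lists with a `normal` field).
#' @return angle in degrees in `[0, 90]`.
#' @export
angle_between_planes <- function(p, q) {
  angle_between_vectors(p$normal, q$normal, fold = TRUE)
}

#' Rotation matrix about an axis
#'
#' Convenience constructor (Rodrigues' formula) used to pose phantoms and
#' in invariance tests.
#'
#' @param axis nonzero 3-vector, the rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) stop("rotation axis must be nonzero")
  a <- a / n
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (QR of a Gaussian matrix with
#' sign correction). Uses the current RNG state.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Validate/coerce an N x 3 numeric point matrix.
as_points3 <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

#' @export
print.pca_frame <- function(x, ...) {
  cat("PCA frame\n  centroid:", format(x$centroid_mm, digits = 4),
      "\n  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("TLS plane fit\n  normal:", format(x$normal, digits = 4),
      "\n  rms residual (mm):", format(x$rms_residual_mm, digits = 4), "\n")
  invisible(x)
}
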