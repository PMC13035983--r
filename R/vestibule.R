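#' Least-squares ellipsoid fit of a vestibular voxel cloud
#'
#' Fits the canonical axis-aligned ellipsoid
#' `(x/a)^2 + (y/b)^2 + (z/c)^2 = 1` after rotating the points into
#' their principal-component frame (which makes the ellipsoid
#' approximately axis-aligned, removing the cross terms). With the
#' substitutions `X = x^2, Y = y^2, Z = z^2` the equation becomes the
#' linear form `A X + B Y + C Z = 1`, solved by ordinary least squares
#' over the surface points; semi-axes are `1/sqrt(coef)`.
#'
#' For voxel clouds the frame and center come from the full (solid)
#' cloud, the fit uses surface voxels (those with at least one 6-neighbor
#' outside the structure), and each recovered semi-axis is enlarged by
#' half a voxel: the center of a boundary voxel sits on average half a
#' voxel inside the continuum surface, so the uncorrected fit is biased
#' low by ~`spacing/2` per radius. Set `surface = "points"` when the
#' input rows already are exact surface samples (no selection, no
#' correction).
#'
#' @param cloud a [voxel_cloud()] (solid voxel cloud) or, with
#'   `surface = "points"`, exact surface samples.
#' @param surface `"voxel"` (default; select surface voxels and apply the
#'   half-voxel radial correction) or `"points"` (fit rows as given),
#'   or `"solid"` (fit all voxels as given -- biases semi-axes low,
#'   retained for sensitivity analysis).
#' @param method `"axis_aligned"` (default, the 3-coefficient form) or
#'   `"general"` (9-parameter quadric with cross and linear terms,
#'   for sensitivity analysis).
#' @return object of class `ellipsoid_fit`: list with `center_mm`,
#'   `diameters_mm` (A >= B >= C, full axes = 2 x semi-axis),
#'   `axis_dirs` (3x3 matrix of world directions, columns paired with
#'   A/B/C), `coeffs`, and `rms_algebraic_residual`.
#' @export
fit_ellipsoid <- function(cloud,
                          surface = c("voxel", "points", "solid"),
                          method = c("axis_aligned", "general")) {
  surface <- match.arg(surface)
  method <- match.arg(method)
  if (inherits(cloud, "voxel_cloud")) {
    pts <- cloud$points_mm
    spacing <- cloud$spacing_mm[1L]
  } else {
    pts <- as_points3(cloud)
    spacing <- 0
    if (surface == "voxel") surface <- "points"
  }
  if (nrow(pts) < 10L) stop("ellipsoid fit needs at least 10 points")
  frame <- pca_frame(pts)
  correction <- 0
  fit_pts <- pts
  if (surface == "voxel") {
    fit_pts <- surface_voxels(pts, spacing)
    correction <- spacing / 2
  }
  Q <- sweep(fit_pts, 2L, frame$centroid_mm) %*% frame$axes

  if (method == "axis_aligned") {
    X <- Q^2
    cf <- tryCatch(solve(crossprod(X), crossprod(X, rep(1, nrow(X)))),
                   error = function(e) stop("singular ellipsoid system"))
    cf <- as.numeric(cf)
    if (any(cf <= 0)) stop("non-ellipsoidal fit: nonpositive coefficient")
    semi <- 1 / sqrt(cf) + correction
    resid <- X %*% cf - 1
    center <- frame$centroid_mm
    dirs <- frame$axes
  } else {
    # general quadric: Ax^2+By^2+Cz^2+Dxy+Exz+Fyz+Gx+Hy+Iz = 1
    x <- Q[, 1L]; y <- Q[, 2L]; z <- Q[, 3L]
    D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
    cf <- as.numeric(solve(crossprod(D), crossprod(D, rep(1, nrow(D)))))
    A <- matrix(c(cf[1], cf[4] / 2, cf[5] / 2,
                  cf[4] / 2, cf[2], cf[6] / 2,
                  cf[5] / 2, cf[6] / 2, cf[3]), 3L)
    ctr_q <- -solve(2 * A, cf[7:9])
    scale <- 1 + sum(ctr_q * (A %*% ctr_q))
    e <- eigen(A / scale, symmetric = TRUE)
    if (any(e$values <= 0)) stop("non-ellipsoidal fit: nonpositive coefficient")
    semi <- 1 / sqrt(e$values) + correction       # ascending semi from desc eigen
    resid <- D %*% cf - 1
    center <- frame$centroid_mm + as.numeric(frame$axes %*% ctr_q)
    dirs <- frame$axes %*% e$vectors
    cf <- e$values
  }
  o <- order(semi, decreasing = TRUE)
  structure(
    list(center_mm = center,
         diameters_mm = stats::setNames(2 * semi[o], c("A", "B", "C")),
         axis_dirs = dirs[, o, drop = FALSE],
         coeffs = cf[o],
         rms_algebraic_residual = sqrt(mean(resid^2)),
         n_fit_points = nrow(fit_pts)),
    class = "ellipsoid_fit"
  )
}

# Surface voxels of a voxel cloud: occupied voxels with at least one
# empty 6-neighbor, found by rasterizing the cloud on its own lattice.
surface_voxels <- function(pts, spacing) {
  lo <- apply(pts, 2L, min)
  idx <- round(sweep(pts, 2L, lo) / spacing) + 2L   # 1-voxel empty border
  d <- apply(idx, 2L, max) + 1L
  M <- array(FALSE, d)
  M[idx] <- TRUE
  i <- idx[, 1L]; j <- idx[, 2L]; k <- idx[, 3L]
  interior <- M[cbind(i - 1L, j, k)] & M[cbind(i + 1L, j, k)] &
    M[cbind(i, j - 1L, k)] & M[cbind(i, j + 1L, k)] &
    M[cbind(i, j, k - 1L)] & M[cbind(i, j, k + 1L)]
  pts[!interior, , drop = FALSE]
}

#' Central cross-section areas of a fitted ellipsoid
#'
#' Areas of the three central section ellipses spanned by the principal
#' diameter pairs: `area_XY = pi * (X/2) * (Y/2)`.
#'
#' @param fit an [fit_ellipsoid()] result.
#' @return named numeric vector `c(area_AB, area_AC, area_BC)` in mm^2.
#' @export
section_areas <- function(fit) {
  d <- fit$diameters_mm
  c(area_AB = pi / 4 * d[["A"]] * d[["B"]],
    area_AC = pi / 4 * d[["A"]] * d[["C"]],
    area_BC = pi / 4 * d[["B"]] * d[["C"]])
}

#' Angles between the vestibular section planes and the canal planes
#'
#' The AB plane is spanned by the A and B diameters, so its normal is the
#' C axis direction (similarly AC -> B, BC -> A). Each of the nine angles
#' is the folded angle between that normal and a canal-plane normal.
#'
#' @param fit an [fit_ellipsoid()] result.
#' @param canal_fits named list of [fit_plane()] results (`PSC`, `LSC`,
#'   `SSC`).
#' @return named numeric vector of nine angles in degrees
#'   (`AB_LSC`, ..., `BC_SSC`).
#' @export
vestibular_plane_angles <- function(fit, canal_fits) {
  stopifnot(all(c("PSC", "LSC", "SSC") %in% names(canal_fits)))
  normals <- list(AB = fit$axis_dirs[, 3L],
                  AC = fit$axis_dirs[, 2L],
                  BC = fit$axis_dirs[, 1L])
  out <- numeric(0)
  for (pl in names(normals)) {
    for (cn in c("LSC", "PSC", "SSC")) {
      out[paste(pl, cn, sep = "_")] <-
        angle_between_vectors(normals[[pl]], canal_fits[[cn]]$normal,
                              fold = TRUE)
    }
  }
  out
}

#' Measure all vestibular metrics
#'
#' Voxel-count volume (independent of the fit by design), ellipsoid
#' principal diameters, central cross-section areas, and the nine
#' section-plane-to-canal angles.
#'
#' @param cloud vestibular [voxel_cloud()].
#' @param canal_fits named list of [fit_plane()] results (`PSC`, `LSC`,
#'   `SSC`).
#' @param ... passed to [fit_ellipsoid()].
#' @return object of class `vestibular_metrics`.
#' @export
measure_vestibule <- function(cloud, canal_fits, ...) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  fit <- fit_ellipsoid(cloud, ...)
  ar <- section_areas(fit)
  ang <- vestibular_plane_angles(fit, canal_fits)
  structure(
    c(list(volume_mm3 = voxel_volume(cloud),
           length_A_mm = unname(fit$diameters_mm["A"]),
           length_B_mm = unname(fit$diameters_mm["B"]),
           length_C_mm = unname(fit$diameters_mm["C"]),
           area_AB_mm2 = unname(ar["area_AB"]),
           area_AC_mm2 = unname(ar["area_AC"]),
           area_BC_mm2 = unname(ar["area_BC"])),
      as.list(stats::setNames(ang, paste0("angle_", names(ang), "_deg"))),
      list(fit = fit)),
    class = "vestibular_metrics"
  )
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf("Ellipsoid fit: diameters A %.2f  B %.2f  C %.2f mm (%d points)\n",
              x$diameters_mm["A"], x$diameters_mm["B"], x$diameters_mm["C"],
              x$n_fit_points))
  invisible(x)
}

#' @export
print.vestibular_metrics <- function(x, ...) {
  cat("Vestibular metrics\n")
  cat(sprintf("  volume %.2f mm^3 | lengths A %.2f  B %.2f  C %.2f mm\n",
              x$volume_mm3, x$length_A_mm, x$length_B_mm, x$length_C_mm))
  cat(sprintf("  areas AB %.2f  AC %.2f  BC %.2f mm^2\n",
              x$area_AB_mm2, x$area_AC_mm2, x$area_BC_mm2))
  invisible(x)
}
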