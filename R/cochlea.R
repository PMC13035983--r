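#' Spatially calibrate a cochlear voxel cloud
#'
#' Applies PCA to the cochlear voxel coordinates to obtain the cochlear
#' coordinate system: the spiral lies in the plane of the first two
#' principal axes and the duct winds about the third (least-variance)
#' axis, which represents the modiolar axis. `coords3` are the centered
#' coordinates expressed in the PCA axes; `coords2` are their first two
#' columns.
#'
#' @param cloud a [voxel_cloud()] of the cochlea (at least 100 points).
#' @param force_basal_positive_x if `TRUE`, the first axis sign is chosen
#'   so that the side of larger planar spread beyond the centroid lies at
#'   positive x (instead of the default largest-component-positive sign
#'   convention). Angle and length measurements are invariant to this
#'   choice; only which basal end is named the round window can change.
#' @return object of class `calibrated_cochlea`: list with `coords2`,
#'   `coords3`, `frame` (a [pca_frame()]) and `modiolar_axis` (unit
#'   3-vector in world coordinates, the frame's third axis).
#' @export
calibrate_cochlea <- function(cloud, force_basal_positive_x = FALSE) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  pts <- cloud$points_mm
  if (nrow(pts) < 100L)
    stop("cochlear calibration needs at least 100 voxels")
  frame <- pca_frame(pts)
  axes <- frame$axes
  coords3 <- sweep(pts, 2L, frame$centroid_mm) %*% axes
  if (force_basal_positive_x) {
    # pick the sign putting the heavier-tailed planar side at +x
    spread_pos <- max(coords3[, 1L])
    spread_neg <- -min(coords3[, 1L])
    if (spread_neg > spread_pos) {
      axes[, 1L] <- -axes[, 1L]
      axes[, 2L] <- -axes[, 2L]          # keep handedness
      coords3[, 1L] <- -coords3[, 1L]
      coords3[, 2L] <- -coords3[, 2L]
      frame$axes <- axes
    }
  }
  structure(
    list(coords2 = coords3[, 1:2, drop = FALSE], coords3 = coords3,
         frame = frame, modiolar_axis = axes[, 3L]),
    class = "calibrated_cochlea"
  )
}

#' Round-window center in the calibrated plane
#'
#' The point with the largest first (x) coordinate of the planar
#' coordinates; exact ties are broken by the largest second (y)
#' coordinate.
#'
#' @param coords2 N x 2 matrix of calibrated planar coordinates (or a
#'   `calibrated_cochlea`).
#' @return list with `point` (length-2) and `index` (row index).
#' @export
round_window_center <- function(coords2) {
  coords2 <- planar_coords(coords2)
  mx <- max(coords2[, 1L])
  cand <- which(coords2[, 1L] == mx)
  i <- cand[which.max(coords2[cand, 2L])]
  list(point = coords2[i, ], index = i)
}

planar_coords <- function(x) {
  if (inherits(x, "calibrated_cochlea")) x <- x$coords2
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected planar (N x 2) coordinates")
  x
}

#' Basal long diameter
#'
#' The largest Euclidean distance from the round-window point to any
#' other point of the calibrated planar cloud; the far point achieving
#' it is returned (first encountered on exact ties).
#'
#' @param coords2 N x 2 calibrated planar coordinates.
#' @param rw round-window point (length-2), e.g. from
#'   [round_window_center()].
#' @return list with `BLD_mm`, `far_point` and `far_index`.
#' @export
basal_long_diameter <- function(coords2, rw) {
  coords2 <- planar_coords(coords2)
  rw <- as.numeric(rw)
  d <- sqrt((coords2[, 1L] - rw[1L])^2 + (coords2[, 2L] - rw[2L])^2)
  i <- which.max(d)
  list(BLD_mm = unname(d[i]), far_point = unname(coords2[i, ]),
       far_index = unname(i))
}

#' Basal short diameter
#'
#' The planar coordinates are rotated so that the round-window-to-far
#' line lies along the +x axis; points are then grouped into x bins of
#' width `bin_width_mm` (continuous coordinates never share an exact
#' x value) and the maximal within-bin y range over bins holding at
#' least two points is the basal short diameter.
#'
#' @param coords2 N x 2 calibrated planar coordinates.
#' @param rw,far the two basal landmarks (length-2 each), `rw != far`.
#' @param bin_width_mm x-bin width; defaults to the voxel spacing via
#'   the caller, 0.1 mm here.
#' @return `BSD_mm`.
#' @export
basal_short_diameter <- function(coords2, rw, far, bin_width_mm = 0.1) {
  coords2 <- planar_coords(coords2)
  rw <- as.numeric(rw); far <- as.numeric(far)
  v <- far - rw
  len <- sqrt(sum(v^2))
  if (len == 0) stop("round-window and far point coincide")
  ct <- v[1L] / len; st <- v[2L] / len
  # rotate so that v -> +x
  x <- ct * (coords2[, 1L] - rw[1L]) + st * (coords2[, 2L] - rw[2L])
  y <- -st * (coords2[, 1L] - rw[1L]) + ct * (coords2[, 2L] - rw[2L])
  bins <- floor(x / bin_width_mm)
  rng <- tapply(y, bins, function(yy)
    if (length(yy) >= 2L) max(yy) - min(yy) else NA_real_)
  rng <- rng[!is.na(rng)]
  if (!length(rng)) stop("no x bin holds two or more points")
  max(rng)
}

#' Cochlear height
#'
#' Axial extent of the calibrated coordinates along the modiolar (Z)
#' axis. The default `"extent"` mode returns `max(Z) - min(Z)`, the full
#' axial extent. The `"literal"` mode returns `max(|Z|) - min(|Z|)`,
#' which on centered PCA coordinates measures roughly half the extent;
#' it is retained for fidelity experiments only.
#'
#' @param coords3 N x 3 calibrated coordinates (or a
#'   `calibrated_cochlea`).
#' @param mode `"extent"` (default) or `"literal"`.
#' @return height in mm.
#' @export
cochlear_height <- function(coords3, mode = c("extent", "literal")) {
  mode <- match.arg(mode)
  if (inherits(coords3, "calibrated_cochlea")) coords3 <- coords3$coords3
  z <- as.matrix(coords3)[, 3L]
  if (mode == "extent") max(z) - min(z) else max(abs(z)) - min(abs(z))
}

#' Regression-derived cochlear duct lengths
#'
#' Affine regressions of duct lengths on the basal long diameter:
#' `CDL = 4.16 * BLD - 4`, `2TL = 3.65 * (BLD - 1)`,
#' `BTL = 2.43 * (BLD - 1)` (all mm). The CDL intercept form
#' `-4.16 * BLD - 4` found in some transcriptions yields negative
#' lengths and is refused with an explanatory error if requested.
#'
#' @param BLD_mm basal long diameter in mm, must exceed 1.
#' @param cdl_form `"corrected"` (default) or `"literal"`.
#' @return named numeric vector `c(CDL_mm, TL2_mm, BTL_mm)`.
#' @export
derived_lengths <- function(BLD_mm, cdl_form = c("corrected", "literal")) {
  cdl_form <- match.arg(cdl_form)
  if (cdl_form == "literal")
    stop("the literal CDL form -4.16 * BLD - 4 yields negative lengths ",
         "for any positive BLD; use the corrected form 4.16 * BLD - 4")
  if (!is.finite(BLD_mm) || BLD_mm <= 1)
    stop("BLD must exceed 1 mm (derived lengths would be nonpositive)")
  c(CDL_mm = 4.16 * BLD_mm - 4,
    TL2_mm = 3.65 * (BLD_mm - 1),
    BTL_mm = 2.43 * (BLD_mm - 1))
}

#' Angles between the modiolar axis and the canal planes
#'
#' For each semicircular canal, the folded angle (in `[0, 90]` degrees)
#' between the modiolar axis and the canal-plane normal from total
#' least-squares fitting.
#'
#' @param axis unit 3-vector, the modiolar axis.
#' @param canal_fits named list of three [fit_plane()] results
#'   (`PSC`, `LSC`, `SSC`).
#' @return named numeric vector of three angles in degrees.
#' @export
modiolus_canal_angles <- function(axis, canal_fits) {
  stopifnot(all(c("PSC", "LSC", "SSC") %in% names(canal_fits)))
  vapply(canal_fits[c("LSC", "PSC", "SSC")], function(f)
    angle_between_vectors(axis, f$normal, fold = TRUE), numeric(1L))
}

#' Measure all cochlear metrics
#'
#' Runs the full cochlear chain on one voxel cloud: voxel-count volume,
#' PCA calibration, round-window localization, basal long/short
#' diameters, cochlear height, regression-derived duct lengths, and the
#' modiolar-axis angles to the three canal planes.
#'
#' @param cloud cochlear [voxel_cloud()].
#' @param canal_fits named list of [fit_plane()] results for
#'   `PSC`, `LSC`, `SSC`.
#' @param bin_width_mm x-bin width for the basal short diameter;
#'   defaults to the cloud's voxel spacing.
#' @param ch_mode cochlear-height mode, see [cochlear_height()].
#' @param force_basal_positive_x see [calibrate_cochlea()].
#' @return object of class `cochlear_metrics`: a named list of scalar
#'   metrics plus the round-window / far points and the modiolar axis.
#' @export
measure_cochlea <- function(cloud, canal_fits,
                            bin_width_mm = NULL,
                            ch_mode = c("extent", "literal"),
                            force_basal_positive_x = FALSE) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  ch_mode <- match.arg(ch_mode)
  if (is.null(bin_width_mm)) bin_width_mm <- cloud$spacing_mm[1L]
  cal <- calibrate_cochlea(cloud, force_basal_positive_x)
  rw <- round_window_center(cal$coords2)
  bl <- basal_long_diameter(cal$coords2, rw$point)
  bsd <- basal_short_diameter(cal$coords2, rw$point, bl$far_point,
                              bin_width_mm)
  ch <- cochlear_height(cal$coords3, ch_mode)
  dl <- derived_lengths(bl$BLD_mm)
  ang <- modiolus_canal_angles(cal$modiolar_axis, canal_fits)
  structure(
    list(volume_mm3 = voxel_volume(cloud),
         BLD_mm = bl$BLD_mm, BSD_mm = bsd, CH_mm = ch,
         CDL_mm = unname(dl["CDL_mm"]), TL2_mm = unname(dl["TL2_mm"]),
         BTL_mm = unname(dl["BTL_mm"]),
         round_window_mm = rw$point, round_window_index = rw$index,
         basal_far_point_mm = bl$far_point,
         modiolar_axis = cal$modiolar_axis,
         angle_modiolus_LSC_deg = unname(ang["LSC"]),
         angle_modiolus_PSC_deg = unname(ang["PSC"]),
         angle_modiolus_SSC_deg = unname(ang["SSC"])),
    class = "cochlear_metrics"
  )
}

#' @export
print.cochlear_metrics <- function(x, ...) {
  cat("Cochlear metrics\n")
  cat(sprintf("  volume %.2f mm^3 | BLD %.2f  BSD %.2f  CH %.2f mm\n",
              x$volume_mm3, x$BLD_mm, x$BSD_mm, x$CH_mm))
  cat(sprintf("  CDL %.2f  2TL %.2f  BTL %.2f mm\n",
              x$CDL_mm, x$TL2_mm, x$BTL_mm))
  cat(sprintf("  modiolus angles: LSC %.1f  PSC %.1f  SSC %.1f deg\n",
              x$angle_modiolus_LSC_deg, x$angle_modiolus_PSC_deg,
              x$angle_modiolus_SSC_deg))
  invisible(x)
}
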