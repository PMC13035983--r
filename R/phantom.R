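#' Specification of a synthetic labyrinth phantom
#'
#' Describes a five-structure inner-ear phantom: a helical cochlear tube,
#' an ellipsoidal vestibule and three partial-torus semicircular canals,
#' voxelized on an isotropic grid. Defaults emulate the adult bony
#' labyrinth at 0.1 mm ultra-high-resolution CT scale: a ~9 mm basal
#' diameter, ~4 mm tall, 2.5-turn cochlea; a vestibule with principal
#' diameters ~6.1/4.6/2.2 mm; and canal planes oriented at the
#' population-mean angles to the modiolar axis (LSC 57.9 deg, PSC
#' 73.9 deg, SSC 41.5 deg).
#'
#' The cochlear tube is a conical spiral centerline swept by a sphere of
#' linearly tapering radius. Because the measurement chain defines the
#' modiolar axis *operationally* as the least-variance principal axis of
#' the voxel cloud, the generator aligns the continuous tube model's
#' second-moment principal frame (tube plus hemispherical end caps,
#' computed by numeric quadrature) with the nominal coordinate axes at
#' construction time, and solves the nominal coil height so that the
#' model's true axial extent equals `height_mm`. Ground truth is thereby
#' exact for the quantities the chain estimates: modiolar axis, axial
#' extent, and maximum basal chord.
#'
#' @param voxel_spacing_mm isotropic voxel spacing (default 0.1 mm).
#' @param cochlea list: `basal_long_diameter_mm` (target maximum basal
#'   chord), `height_mm` (true axial extent), `n_turns`,
#'   `tube_radius_base_mm`, `tube_radius_apex_mm`, `spiral_taper`
#'   (apex/base spiral-radius ratio), `modiolar_axis` (unit 3-vector,
#'   coil axis before the rigid pose).
#' @param vestibule list: `semi_axes_mm` (3, sorted descending),
#'   `center_mm`, `orientation` (3x3 rotation), `surface_noise_mm`
#'   (RMS radial perturbation, 0 = exact ellipsoid).
#' @param canals named list (`PSC`, `LSC`, `SSC`), each with
#'   `plane_normal` (unit 3-vector), `torus_major_radius_mm`,
#'   `torus_minor_radius_mm`, `arc_fraction` in (0, 1], `center_mm`.
#' @param rigid_pose list with `rotation` (3x3) and `translation`
#'   (length 3), applied to the whole assembly; ground truth is recorded
#'   after the pose.
#' @param seed integer; only consumed by the vestibular surface-noise
#'   field, so noiseless phantoms are deterministic by construction.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing_mm = 0.1,
                         cochlea = list(),
                         vestibule = list(),
                         canals = list(),
                         rigid_pose = list(rotation = diag(3),
                                           translation = c(0, 0, 0)),
                         seed = 1L) {
  coch <- utils::modifyList(list(
    basal_long_diameter_mm = 9.0,
    height_mm = 4.0,
    n_turns = 2.5,
    tube_radius_base_mm = 0.85,
    tube_radius_apex_mm = 0.5,
    spiral_taper = 0.125,
    modiolar_axis = c(0, 0, 1)
  ), cochlea)
  vest <- utils::modifyList(list(
    semi_axes_mm = c(3.07, 2.295, 1.095),
    center_mm = c(8.2, 0, 2.0),
    orientation = diag(3),
    surface_noise_mm = 0
  ), vestibule)
  can <- utils::modifyList(default_canal_specs(), canals)

  spc <- as.numeric(voxel_spacing_mm)
  if (length(spc) != 1L || spc <= 0) stop("voxel spacing must be a positive scalar")
  if (coch$n_turns <= 0) stop("cochlea must have a positive number of turns")
  if (coch$tube_radius_base_mm <= 0 || coch$tube_radius_apex_mm <= 0 ||
      coch$basal_long_diameter_mm <= 0 || coch$height_mm <= 0)
    stop("cochlear dimensions must be strictly positive")
  if (coch$height_mm <= coch$tube_radius_base_mm + coch$tube_radius_apex_mm)
    stop("cochlear height must exceed the sum of the tube end radii")
  if (2 * coch$tube_radius_apex_mm < 2 * spc)
    stop("voxel spacing too coarse to resolve the cochlear tube ",
         "(apical tube diameter < 2 voxels)")
  coch$modiolar_axis <- coch$modiolar_axis / sqrt(sum(coch$modiolar_axis^2))
  if (is.unsorted(rev(vest$semi_axes_mm))) {
    warning("vestibular semi-axes were not sorted descending; normalizing")
    vest$semi_axes_mm <- sort(vest$semi_axes_mm, decreasing = TRUE)
  }
  if (any(vest$semi_axes_mm < 3 * spc))
    stop("vestibular semi-axes must span at least 3 voxels")
  if (vest$surface_noise_mm < 0) stop("surface noise must be nonnegative")
  for (nm in names(can)) {
    ck <- can[[nm]]
    if (ck$arc_fraction <= 0 || ck$arc_fraction > 1)
      stop("canal ", nm, ": arc_fraction must be in (0, 1]")
    if (ck$torus_minor_radius_mm < 1.5 * spc)
      stop("canal ", nm, ": torus minor radius must span at least 1.5 voxels")
    can[[nm]]$plane_normal <- ck$plane_normal / sqrt(sum(ck$plane_normal^2))
  }
  check_rotation(rigid_pose$rotation)
  structure(
    list(voxel_spacing_mm = spc, cochlea = coch, vestibule = vest,
         canals = can, rigid_pose = rigid_pose, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

default_canal_specs <- function() {
  ang <- c(PSC = 73.92, LSC = 57.89, SSC = 41.52) * pi / 180
  az <- c(PSC = 120, LSC = 0, SSC = 240) * pi / 180
  ctr <- list(PSC = c(12.5, 3.2, 3.0), LSC = c(12.5, -3.2, 3.0),
              SSC = c(14.0, 0, 6.5))
  maj <- c(PSC = 3.1, LSC = 2.8, SSC = 2.9)
  mnr <- c(PSC = 0.40, LSC = 0.45, SSC = 0.42)
  out <- lapply(c("PSC", "LSC", "SSC"), function(nm) {
    list(plane_normal = c(sin(ang[[nm]]) * cos(az[[nm]]),
                          sin(ang[[nm]]) * sin(az[[nm]]),
                          cos(ang[[nm]])),
         torus_major_radius_mm = maj[[nm]],
         torus_minor_radius_mm = mnr[[nm]],
         arc_fraction = 0.75,
         center_mm = ctr[[nm]])
  })
  names(out) <- c("PSC", "LSC", "SSC")
  out
}

check_rotation <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("rigid_pose$rotation must be a proper 3x3 rotation matrix")
  invisible(R)
}

pose_points <- function(P, pose) {
  sweep(P %*% t(pose$rotation), 2L, as.numeric(pose$translation), `+`)
}

pose_vector <- function(v, pose) as.numeric(pose$rotation %*% v)

## ---------------------------------------------------------------------
## Continuous cochlear tube model

# Raw (unaligned) conical-spiral tube for a nominal coil height.
cochlea_raw_model <- function(coch, nominal_height, n_samples = 6000L) {
  tmax <- 2 * pi * coch$n_turns
  tr_b <- coch$tube_radius_base_mm
  tr_a <- coch$tube_radius_apex_mm
  taper <- coch$spiral_taper
  # spiral base radius solving the naive basal chord for the target BLD
  frac_half <- 0.5 / coch$n_turns
  tr_half <- tr_b - (tr_b - tr_a) * frac_half
  rho_b <- (coch$basal_long_diameter_mm - tr_b - tr_half) /
    (2 - (1 - taper) * frac_half)
  rho_a <- taper * rho_b
  z0 <- tr_b
  z1 <- nominal_height - tr_a
  tt <- seq(0, tmax, length.out = n_samples)
  f <- tt / tmax
  rho <- rho_b + (rho_a - rho_b) * f
  r <- tr_b + (tr_a - tr_b) * f
  z <- z0 + (z1 - z0) * f
  cl <- cbind(rho * cos(tt), rho * sin(tt), z)
  dcx <- (rho_a - rho_b) / tmax * cos(tt) - rho * sin(tt)
  dcy <- (rho_a - rho_b) / tmax * sin(tt) + rho * cos(tt)
  dcz <- rep((z1 - z0) / tmax, n_samples)
  ds <- sqrt(dcx^2 + dcy^2 + dcz^2)
  list(cl = cl, r = r, tang = cbind(dcx, dcy, dcz) / ds,
       ds = ds, dt = tt[2L] - tt[1L])
}

# First and second moments of the solid tube (disc cross-sections by
# quadrature along the centerline, hemispherical caps at both ends).
tube_moments <- function(m) {
  w <- pi * m$r^2 * m$ds * m$dt
  S0 <- sum(w)
  S1 <- colSums(w * m$cl)
  S2 <- crossprod(m$cl, w * m$cl)
  for (i in 1:3) for (j in 1:3) {
    S2[i, j] <- S2[i, j] +
      sum(w * m$r^2 / 4 * ((i == j) - m$tang[, i] * m$tang[, j]))
  }
  n <- nrow(m$cl)
  for (end in c(1L, n)) {
    out <- if (end == 1L) -m$tang[end, ] else m$tang[end, ]
    rc <- m$r[end]
    mc <- (2 / 3) * pi * rc^3
    mu <- m$cl[end, ] + (3 / 8) * rc * out
    O <- out %o% out
    covc <- rc^2 * (0.059375 * O + 0.2 * (diag(3) - O))
    S0 <- S0 + mc
    S1 <- S1 + mc * mu
    S2 <- S2 + mc * (covc + mu %o% mu)
  }
  mu <- S1 / S0
  list(mass = S0, mean = mu, cov = S2 / S0 - mu %o% mu)
}

# Moment-aligned tube model: centered on the model centroid, principal
# axes on the coordinate axes (least variance along +z).
cochlea_aligned_model <- function(coch, nominal_height) {
  m <- cochlea_raw_model(coch, nominal_height)
  mo <- tube_moments(m)
  V <- fix_axis_signs(eigen(mo$cov, symmetric = TRUE)$vectors)
  m$cl <- sweep(m$cl, 2L, mo$mean) %*% V
  m$tang <- m$tang %*% V
  m$mass <- mo$mass
  m
}

model_extent_z <- function(m) {
  max(m$cl[, 3L] + m$r) - min(m$cl[, 3L] - m$r)
}

# Full cochlear model with the nominal height solved so that the true
# axial extent equals the requested height, plus ground-truth geometry
# (still in cochlea-local coordinates, coil axis = +z).
cochlea_model <- function(coch) {
  target <- coch$height_mm
  lohi <- c(max(target * 0.6,
                coch$tube_radius_base_mm + coch$tube_radius_apex_mm + 1e-3),
            target * 1.6)
  f <- function(nh) model_extent_z(cochlea_aligned_model(coch, nh)) - target
  nom <- stats::uniroot(f, lohi, tol = 1e-6)$root
  m <- cochlea_aligned_model(coch, nom)
  # basal endpoint: tube surface point of maximal x in the aligned frame
  ix <- which.max(m$cl[, 1L] + m$r)
  rw <- m$cl[ix, ] + c(m$r[ix], 0, 0)
  # maximum basal chord from that point, in the xy-plane of the frame
  chord <- max(sqrt((m$cl[, 1L] - rw[1L])^2 + (m$cl[, 2L] - rw[2L])^2) + m$r)
  m$ground_truth <- list(
    modiolar_axis = c(0, 0, 1),
    height_mm = target,
    basal_diameter_mm = chord,
    basal_endpoint_mm = rw,
    volume_mm3 = m$mass
  )
  m
}

## ---------------------------------------------------------------------
## Voxelization

# A voxel grid: snapped origin, dims, spacing.
voxel_grid <- function(lo, hi, spacing, margin = 0.3) {
  origin <- floor((lo - margin) / spacing) * spacing
  dims <- as.integer(ceiling((hi + margin - origin) / spacing))
  list(origin_mm = origin, dims = dims, spacing_mm = rep_len(spacing, 3L))
}

grid_contains <- function(grid, lo, hi) {
  all(lo >= grid$origin_mm) &&
    all(hi <= grid$origin_mm + grid$dims * grid$spacing_mm[1L])
}

# Mark all voxels whose centers lie within radius r[k] of centers[k, ].
# The union of the stamped balls is the swept-sphere (capsule) solid.
stamp_balls <- function(grid, centers, radii) {
  h <- grid$spacing_mm[1L]
  lo <- grid$origin_mm
  dims <- grid$dims
  M <- array(FALSE, dims)
  for (k in seq_len(nrow(centers))) {
    c0 <- centers[k, ]
    rk <- radii[k]
    i0 <- pmax(1L, as.integer(floor((c0 - rk - lo) / h + 0.5)))
    i1 <- pmin(dims, as.integer(ceiling((c0 + rk - lo) / h + 0.5)))
    if (any(i0 > i1)) next
    dx2 <- (lo[1L] + (i0[1L]:i1[1L] - 0.5) * h - c0[1L])^2
    dy2 <- (lo[2L] + (i0[2L]:i1[2L] - 0.5) * h - c0[2L])^2
    dz2 <- (lo[3L] + (i0[3L]:i1[3L] - 0.5) * h - c0[3L])^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rk^2
    M[i0[1L]:i1[1L], i0[2L]:i1[2L], i0[3L]:i1[3L]] <-
      M[i0[1L]:i1[1L], i0[2L]:i1[2L], i0[3L]:i1[3L]] | sub
  }
  M
}

# Resample a polyline (with per-vertex radii) to a fixed arc-length step.
resample_polyline <- function(cl, r, step) {
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  si <- seq(0, s[length(s)], length.out = max(2L, ceiling(s[length(s)] / step)))
  list(cl = cbind(stats::approx(s, cl[, 1L], si)$y,
                  stats::approx(s, cl[, 2L], si)$y,
                  stats::approx(s, cl[, 3L], si)$y),
       r = stats::approx(s, r, si)$y)
}

#' Voxelize the cochlear phantom
#'
#' Builds the moment-aligned helical tube for `spec$cochlea`, applies the
#' modiolar-axis orientation and the rigid pose, and stamps it onto a
#' voxel grid. See [phantom_spec()] for the construction.
#'
#' @param spec a [phantom_spec()].
#' @param grid optional voxel grid (list with `origin_mm`, `dims`,
#'   `spacing_mm`) shared with other structures; default: a snug grid
#'   around the structure.
#' @return list with `mask` (logical 3-D array), `origin_mm`,
#'   `spacing_mm`, and `ground_truth` (world-coordinate true modiolar
#'   axis, axial extent, maximum basal chord, basal endpoint, and the
#'   analytic tube volume, which ignores any self-overlap of adjacent
#'   turns).
#' @export
make_cochlea_mask <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_spacing_mm
  m <- cochlea_model(spec$cochlea)
  Rm <- rotation_to_z(spec$cochlea$modiolar_axis)
  pose <- spec$rigid_pose
  cl <- pose_points(m$cl %*% t(Rm), pose)
  rs <- resample_polyline(cl, m$r, step = h / 2)
  lo <- apply(rs$cl, 2L, min) - max(m$r)
  hi <- apply(rs$cl, 2L, max) + max(m$r)
  if (is.null(grid)) {
    grid <- voxel_grid(lo, hi, h)
  } else if (!grid_contains(grid, lo, hi)) {
    stop("grid too small to contain the cochlea")
  }
  gt <- m$ground_truth
  gt$modiolar_axis <- pose_vector(Rm %*% gt$modiolar_axis, pose)
  gt$basal_endpoint_mm <- as.numeric(
    pose_points(matrix(Rm %*% gt$basal_endpoint_mm, 1L), pose))
  list(mask = stamp_balls(grid, rs$cl, rs$r),
       origin_mm = grid$origin_mm, spacing_mm = grid$spacing_mm,
       ground_truth = gt)
}

# Rotation taking +z to the given unit axis.
rotation_to_z <- function(axis) {
  z <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  v <- c(-axis[2], axis[1], 0)              # z x axis
  s <- sqrt(sum(v^2))
  d <- axis[3]
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  rotation_about_axis(v, atan2(s, d) * 180 / pi)
}

#' Voxelize the vestibular phantom
#'
#' Solid (optionally radially perturbed) ellipsoid voxelized at the spec
#' spacing. With zero surface noise every voxel center satisfies the
#' ellipsoid inequality exactly, and the analytic volume `(4/3) pi a b c`
#' is recorded as ground truth.
#'
#' @inheritParams make_cochlea_mask
#' @return list as in [make_cochlea_mask()]; ground truth holds the true
#'   center, semi-axes, world axis directions and analytic volume.
#' @export
make_vestibule_mask <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_spacing_mm
  v <- spec$vestibule
  a <- v$semi_axes_mm
  pose <- spec$rigid_pose
  Rtot <- pose$rotation %*% v$orientation    # local -> world
  ctr <- as.numeric(pose_points(matrix(v$center_mm, 1L), pose))
  pad <- max(a) + 4 * v$surface_noise_mm
  if (is.null(grid)) {
    grid <- voxel_grid(ctr - pad, ctr + pad, h)
  } else if (!grid_contains(grid, ctr - pad, ctr + pad)) {
    stop("grid too small to contain the vestibule")
  }
  noise <- if (v$surface_noise_mm > 0) {
    surface_noise_field(spec$seed, v$surface_noise_mm)
  } else NULL
  # world voxel centers within the padded bounding box of the ellipsoid
  lo <- grid$origin_mm
  i0 <- pmax(1L, as.integer(floor((ctr - pad - lo) / h + 0.5)))
  i1 <- pmin(grid$dims, as.integer(ceiling((ctr + pad - lo) / h + 0.5)))
  xs <- lo[1L] + (i0[1L]:i1[1L] - 0.5) * h
  ys <- lo[2L] + (i0[2L]:i1[2L] - 0.5) * h
  zs <- lo[3L] + (i0[3L]:i1[3L] - 0.5) * h
  G <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  L <- sweep(G, 2L, ctr) %*% Rtot              # world -> local
  if (is.null(noise)) {
    ins <- (L[, 1L] / a[1L])^2 + (L[, 2L] / a[2L])^2 + (L[, 3L] / a[3L])^2 <= 1
  } else {
    rr <- sqrt(rowSums(L^2))
    u <- L / pmax(rr, 1e-12)
    r_ell <- 1 / sqrt((u[, 1L] / a[1L])^2 + (u[, 2L] / a[2L])^2 +
                        (u[, 3L] / a[3L])^2)
    ins <- rr <= r_ell + noise(u)
  }
  M <- array(FALSE, grid$dims)
  M[i0[1L]:i1[1L], i0[2L]:i1[2L], i0[3L]:i1[3L]] <-
    array(ins, c(length(xs), length(ys), length(zs)))
  list(mask = M, origin_mm = grid$origin_mm, spacing_mm = grid$spacing_mm,
       ground_truth = list(
         center_mm = ctr,
         semi_axes_mm = a,
         axes = Rtot,
         volume_mm3 = 4 / 3 * pi * prod(a),
         surface_noise_mm = v$surface_noise_mm))
}

# Smooth random radial perturbation field on the unit sphere with RMS
# amplitude `amp` (sum of a few random low-frequency cosines).
surface_noise_field <- function(seed, amp, n_terms = 6L) {
  st <- local_seed(seed)
  on.exit(restore_seed(st))
  K <- matrix(stats::rnorm(3L * n_terms), ncol = 3L) * 1.5
  ph <- stats::runif(n_terms, 0, 2 * pi)
  am <- stats::rnorm(n_terms)
  # normalize to unit RMS over the sphere (Monte Carlo, fixed draw)
  u0 <- matrix(stats::rnorm(3000L), ncol = 3L)
  u0 <- u0 / sqrt(rowSums(u0^2))
  f0 <- cos(u0 %*% t(K) + matrix(ph, nrow(u0), n_terms, byrow = TRUE)) %*% am
  sc <- amp / stats::sd(f0)
  function(u) {
    as.numeric(cos(u %*% t(K) +
                     matrix(ph, nrow(u), n_terms, byrow = TRUE)) %*% am) * sc
  }
}

local_seed <- function(seed) {
  st <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  st
}

restore_seed <- function(st) {
  if (is.null(st)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", st, envir = globalenv())
  }
}

#' Voxelize one semicircular-canal phantom
#'
#' A partial torus (circular arc of the major circle swept by a sphere of
#' the minor radius, so the ends are hemispherical) lying exactly in the
#' specified plane before the rigid pose.
#'
#' @inheritParams make_cochlea_mask
#' @param which canal id: `"PSC"`, `"LSC"` or `"SSC"`.
#' @return list as in [make_cochlea_mask()]; ground truth holds the
#'   world-coordinate plane normal, center, radii, arc fraction and the
#'   analytic capsule volume.
#' @export
make_canal_mask <- function(spec, which = c("PSC", "LSC", "SSC"),
                            grid = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  which <- match.arg(which)
  h <- spec$voxel_spacing_mm
  ck <- spec$canals[[which]]
  n <- ck$plane_normal
  # in-plane orthonormal basis
  ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  phi <- seq(0, ck$arc_fraction * 2 * pi,
             length.out = max(8L, ceiling(ck$arc_fraction * 2 * pi *
                                            ck$torus_major_radius_mm / (h / 2))))
  cl <- matrix(ck$center_mm, length(phi), 3L, byrow = TRUE) +
    ck$torus_major_radius_mm * (cos(phi) %o% u + sin(phi) %o% v)
  pose <- spec$rigid_pose
  cl <- pose_points(cl, pose)
  r <- ck$torus_minor_radius_mm
  lo <- apply(cl, 2L, min) - r
  hi <- apply(cl, 2L, max) + r
  if (is.null(grid)) {
    grid <- voxel_grid(lo, hi, h)
  } else if (!grid_contains(grid, lo, hi)) {
    stop("grid too small to contain canal ", which)
  }
  arc_len <- ck$arc_fraction * 2 * pi * ck$torus_major_radius_mm
  vol <- pi * r^2 * arc_len +
    if (ck$arc_fraction < 1) (4 / 3) * pi * r^3 else 0
  list(mask = stamp_balls(grid, cl, rep(r, nrow(cl))),
       origin_mm = grid$origin_mm, spacing_mm = grid$spacing_mm,
       ground_truth = list(
         plane_normal = pose_vector(n, pose),
         center_mm = as.numeric(pose_points(matrix(ck$center_mm, 1L), pose)),
         torus_major_radius_mm = ck$torus_major_radius_mm,
         torus_minor_radius_mm = r,
         arc_fraction = ck$arc_fraction,
         volume_mm3 = vol))
}

# World-coordinate bounding box of one structure (before gridding).
structure_bounds <- function(spec, name) {
  pose <- spec$rigid_pose
  if (name == "cochlea") {
    m <- cochlea_model(spec$cochlea)
    cl <- pose_points(m$cl %*% t(rotation_to_z(spec$cochlea$modiolar_axis)),
                      pose)
    list(lo = apply(cl, 2L, min) - max(m$r),
         hi = apply(cl, 2L, max) + max(m$r))
  } else if (name == "vestibule") {
    ctr <- as.numeric(pose_points(matrix(spec$vestibule$center_mm, 1L), pose))
    pad <- max(spec$vestibule$semi_axes_mm) +
      4 * spec$vestibule$surface_noise_mm
    list(lo = ctr - pad, hi = ctr + pad)
  } else {
    ck <- spec$canals[[name]]
    n <- ck$plane_normal
    ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * n) * n
    u <- u / sqrt(sum(u^2))
    v <- c(n[2L] * u[3L] - n[3L] * u[2L],
           n[3L] * u[1L] - n[1L] * u[3L],
           n[1L] * u[2L] - n[2L] * u[1L])
    phi <- seq(0, ck$arc_fraction * 2 * pi, length.out = 256L)
    cl <- matrix(ck$center_mm, length(phi), 3L, byrow = TRUE) +
      ck$torus_major_radius_mm * (cos(phi) %o% u + sin(phi) %o% v)
    cl <- pose_points(cl, pose)
    r <- ck$torus_minor_radius_mm
    list(lo = apply(cl, 2L, min) - r, hi = apply(cl, 2L, max) + r)
  }
}

#' Assemble the five-structure labyrinth phantom
#'
#' Voxelizes all structures on one common grid and combines them into a
#' labeled volume. Overlapping voxels are resolved by a fixed priority:
#' cochlea > vestibule > PSC > LSC > SSC (the default geometry is
#' disjoint, so priority only matters for user-modified specs).
#'
#' @param spec a [phantom_spec()].
#' @param grid optional common voxel grid; default: a snug grid around
#'   the whole assembly. A user grid too small for any structure raises
#'   an error naming that structure.
#' @return list with `volume` (a [label_volume()]) and `ground_truth`
#'   (named list of per-structure ground-truth entries, in world
#'   coordinates after the rigid pose).
#' @export
assemble_labyrinth <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_spacing_mm
  parts <- list(
    cochlea = function(g) make_cochlea_mask(spec, g),
    vestibule = function(g) make_vestibule_mask(spec, g),
    PSC = function(g) make_canal_mask(spec, "PSC", g),
    LSC = function(g) make_canal_mask(spec, "LSC", g),
    SSC = function(g) make_canal_mask(spec, "SSC", g)
  )
  if (is.null(grid)) {
    los <- his <- NULL
    for (nm in names(parts)) {
      b <- structure_bounds(spec, nm)
      los <- rbind(los, b$lo)
      his <- rbind(his, b$hi)
    }
    grid <- voxel_grid(apply(los, 2L, min), apply(his, 2L, max), h)
  }
  lm <- default_label_map()
  vox <- array(0L, grid$dims)
  gt <- list()
  # write in increasing priority so later structures overwrite earlier
  for (nm in c("SSC", "LSC", "PSC", "vestibule", "cochlea")) {
    p <- tryCatch(parts[[nm]](grid), error = function(e)
      stop("assembly failed for structure '", nm, "': ", conditionMessage(e),
           call. = FALSE))
    vox[p$mask] <- lm[[nm]]
    gt[[nm]] <- p$ground_truth
  }
  list(volume = label_volume(vox, spacing_mm = h,
                             origin_mm = grid$origin_mm, label_map = lm),
       ground_truth = gt)
}
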