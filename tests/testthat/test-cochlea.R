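test_that("round-window rule picks max x with max-y tie break", {
  pts <- rbind(c(0, 0), c(2, 1), c(2, -1))
  expect_equal(round_window_center(pts)$point, c(2, 1))
  expect_equal(round_window_center(matrix(c(1, 5), 1))$point, c(1, 5))
})

test_that("basal long diameter is the max distance from the round window", {
  pts <- rbind(c(0, 0), c(3, 4))
  expect_equal(basal_long_diameter(pts, c(0, 0))$BLD_mm, 5)
  same <- matrix(1, 5, 2)
  expect_equal(basal_long_diameter(same, c(1, 1))$BLD_mm, 0)
})

test_that("BLD equals the brute-force maximum chord on symmetric planar sets", {
  set.seed(8)
  for (ab in list(c(4.5, 3.2), c(2, 1.5), c(5, 0.8))) {
    pts <- ellipse_points_2d(ab[1], ab[2], step = ab[1] / 20)
    pts <- pts[sample(nrow(pts), min(nrow(pts), 2000L)), ]
    # make sure the extreme points are present
    pts <- rbind(pts, c(ab[1], 0), c(-ab[1], 0))
    rw <- round_window_center(pts)
    bld <- basal_long_diameter(pts, rw$point)$BLD_mm
    oracle <- max(dist(pts))                # all-pairs brute force
    expect_equal(bld, oracle, tolerance = 1e-9)
  }
})

test_that("basal short diameter recovers the minor diameter of an ellipse", {
  pts <- ellipse_points_2d(4.5, 3.25, step = 0.05)
  rw <- round_window_center(pts)$point
  far <- basal_long_diameter(pts, rw)$far_point
  bsd <- basal_short_diameter(pts, rw, far, bin_width_mm = 0.1)
  expect_lt(abs(bsd - 6.5), 0.1)   # within one bin width
  # halving the bin width on dense data moves BSD by < 2 bin widths
  bsd2 <- basal_short_diameter(pts, rw, far, bin_width_mm = 0.05)
  expect_lt(abs(bsd2 - bsd), 0.2)
  # collinear points: zero short diameter
  line <- cbind(seq(0, 1, 0.01), 0)
  expect_equal(basal_short_diameter(line, c(0, 0), c(1, 0), 0.1), 0)
  expect_error(basal_short_diameter(pts, c(1, 1), c(1, 1), 0.1), "coincide")
})

test_that("cochlear height modes", {
  z <- seq(-2.03, 2.03, length.out = 101)
  coords3 <- cbind(0, 0, z)
  expect_equal(cochlear_height(coords3), 4.06)
  expect_equal(cochlear_height(coords3, "literal"), 2.03, tolerance = 1e-9)
  flat <- cbind(1:10, 1:10, 0)
  expect_equal(cochlear_height(flat), 0)
  expect_equal(cochlear_height(flat, "literal"), 0)
})

test_that("derived duct lengths match the published regression values", {
  dl <- derived_lengths(9.08)
  expect_equal(round(unname(dl), 2), c(33.77, 29.49, 19.63))
  expect_equal(round(unname(derived_lengths(8.98)["BTL_mm"]), 2), 19.39)
  near1 <- derived_lengths(1 + 1e-9)
  expect_lt(near1[["TL2_mm"]], 1e-6)
  expect_lt(near1[["BTL_mm"]], 1e-6)
  expect_error(derived_lengths(1), "exceed 1")
  expect_error(derived_lengths(9.08, cdl_form = "literal"), "negative")
})

test_that("modiolus-canal angles fold the arccos formula into [0, 90]", {
  fits <- list(PSC = list(normal = c(0, 0, 1)),
               LSC = list(normal = c(0, sin(pi / 6), cos(pi / 6))),
               SSC = list(normal = c(1, 0, 0)))
  ang <- modiolus_canal_angles(c(0, 0, 1), fits)
  expect_equal(unname(ang["PSC"]), 0)           # axis parallel to normal
  expect_equal(unname(ang["LSC"]), 30, tolerance = 1e-9)
  expect_equal(unname(ang["SSC"]), 90)          # axis lies in the plane
  # sign of the normal is irrelevant after folding
  fits$LSC$normal <- -fits$LSC$normal
  expect_equal(unname(modiolus_canal_angles(c(0, 0, 1), fits)["LSC"]), 30,
               tolerance = 1e-9)
})

test_that("calibration recovers the phantom modiolar frame", {
  asm <- default_assembly()
  cl <- extract_voxel_cloud(asm$volume, "cochlea")
  cal <- calibrate_cochlea(cl)
  gt <- asm$ground_truth$cochlea
  expect_lt(angle_between_vectors(cal$modiolar_axis, gt$modiolar_axis,
                                  fold = TRUE), 3)
  expect_equal(ncol(cal$coords2), 2)
  expect_equal(cal$modiolar_axis, cal$frame$axes[, 3])
  expect_error(calibrate_cochlea(voxel_cloud(matrix(rnorm(30), 10))),
               "at least 100")
})

test_that("calibration is equivariant under rotation of the phantom", {
  R <- rotation_about_axis(c(2, 1, 1), 48)
  asm <- assemble_labyrinth(
    phantom_spec(rigid_pose = list(rotation = R, translation = c(1, 2, 3))))
  cal <- calibrate_cochlea(extract_voxel_cloud(asm$volume, "cochlea"))
  expect_lt(angle_between_vectors(cal$modiolar_axis,
                                  as.numeric(R %*% c(0, 0, 1)), fold = TRUE), 3)
})

test_that("measured cochlear metrics recover the phantom ground truth", {
  asm <- default_assembly()
  gt <- asm$ground_truth$cochlea
  cm <- measure_cochlea(extract_voxel_cloud(asm$volume, "cochlea"),
                        default_canal_fits())
  expect_equal(cm$CH_mm, gt$height_mm, tolerance = 0.15 / gt$height_mm)
  expect_equal(cm$BLD_mm, gt$basal_diameter_mm,
               tolerance = 0.2 / gt$basal_diameter_mm)
  # the round window lands on the outer edge of the basal turn; the
  # max-x rule localizes it only to the lattice band of that arc
  # (~ rho * sqrt(2 h / rho) ~ 1 mm at 0.1 mm spacing; see the vignette)
  cl <- extract_voxel_cloud(asm$volume, "cochlea")
  rw_world <- cl$points_mm[cm$round_window_index, ]
  expect_lt(sqrt(sum((rw_world - gt$basal_endpoint_mm)^2)), 1.0)
  planar_r <- sqrt(sum((rw_world - c(0, 0, rw_world[3]))^2))
  expect_gt(planar_r, gt$basal_diameter_mm / 2 * 0.9)   # outer edge
})

test_that("measure_cochlea output is internally consistent", {
  asm <- default_assembly()
  cm <- measure_cochlea(extract_voxel_cloud(asm$volume, "cochlea"),
                        default_canal_fits())
  nums <- unlist(cm[c("volume_mm3", "BLD_mm", "BSD_mm", "CH_mm", "CDL_mm",
                      "TL2_mm", "BTL_mm", "angle_modiolus_LSC_deg",
                      "angle_modiolus_PSC_deg", "angle_modiolus_SSC_deg")])
  expect_true(all(is.finite(nums)))
  expect_gte(cm$BLD_mm, cm$BSD_mm)
  angs <- nums[grepl("angle", names(nums))]
  expect_true(all(angs >= 0 & angs <= 90))
  # derived lengths are exact affine functions of the reported BLD
  expect_equal(cm$CDL_mm, 4.16 * cm$BLD_mm - 4, tolerance = 1e-12)
  expect_equal(cm$TL2_mm, 3.65 * (cm$BLD_mm - 1), tolerance = 1e-12)
  expect_equal(cm$BTL_mm, 2.43 * (cm$BLD_mm - 1), tolerance = 1e-12)
  # measured angles sit near the construction angles of the canal planes
  expect_equal(cm$angle_modiolus_LSC_deg, 57.89, tolerance = 0.02)
  expect_equal(cm$angle_modiolus_PSC_deg, 73.92, tolerance = 0.02)
  expect_equal(cm$angle_modiolus_SSC_deg, 41.52, tolerance = 0.02)
})
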