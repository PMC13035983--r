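test_that("phantom generation is deterministic given the spec", {
  spec <- phantom_spec(voxel_spacing_mm = 0.2)
  m1 <- make_cochlea_mask(spec)
  m2 <- make_cochlea_mask(spec)
  expect_identical(m1$mask, m2$mask)
  v1 <- make_vestibule_mask(spec)
  v2 <- make_vestibule_mask(spec)
  expect_identical(v1$mask, v2$mask)
  # noisy vestibule is reproducible through the seed and leaves the
  # global RNG stream untouched
  spec_n <- phantom_spec(voxel_spacing_mm = 0.2,
                         vestibule = list(surface_noise_mm = 0.1), seed = 5)
  set.seed(99); before <- rnorm(1)
  n1 <- make_vestibule_mask(spec_n)
  n2 <- make_vestibule_mask(spec_n)
  expect_identical(n1$mask, n2$mask)
  set.seed(99)
  expect_identical(rnorm(1), before)
  expect_false(identical(n1$mask, v1$mask))
})

test_that("phantom_spec rejects degenerate geometry", {
  expect_error(phantom_spec(cochlea = list(n_turns = 0)), "turns")
  expect_error(phantom_spec(voxel_spacing_mm = 0.6), "too coarse")
  expect_error(phantom_spec(vestibule = list(semi_axes_mm = c(0.2, 0.1, 0.1))),
               "3 voxels")
  expect_error(phantom_spec(canals = list(LSC = modifyList(
    labyrinthometry:::default_canal_specs()$LSC, list(arc_fraction = 0)))),
    "arc_fraction")
  expect_warning(phantom_spec(vestibule = list(semi_axes_mm = c(1, 2, 3))),
                 "sorted")
})

test_that("cochlear mask has the constructed axial extent and volume scale", {
  cm <- make_cochlea_mask(phantom_spec())
  idx <- which(cm$mask, arr.ind = TRUE)
  z <- cm$origin_mm[3] + (idx[, 3] - 0.5) * cm$spacing_mm[3]
  expect_equal(max(z) - min(z), 4.0, tolerance = 0.1)
  expect_equal(cm$ground_truth$height_mm, 4.0)
  expect_equal(cm$ground_truth$modiolar_axis, c(0, 0, 1))
  # voxel volume below the analytic tube volume (turns may touch) but
  # on the same scale
  vox_vol <- sum(cm$mask) * prod(cm$spacing_mm)
  expect_lt(vox_vol, cm$ground_truth$volume_mm3 * 1.02)
  expect_gt(vox_vol, cm$ground_truth$volume_mm3 * 0.7)
})

test_that("vestibular mask matches the analytic ellipsoid volume", {
  sp <- phantom_spec(vestibule = list(semi_axes_mm = c(1.5, 1.5, 1.5),
                                      center_mm = c(0, 0, 0)))
  vm <- make_vestibule_mask(sp)
  expect_equal(sum(vm$mask) * prod(vm$spacing_mm), 4 / 3 * pi * 1.5^3,
               tolerance = 0.02)
  # realistic vestibular scale
  vm2 <- make_vestibule_mask(phantom_spec())
  expect_equal(vm2$ground_truth$volume_mm3, 4 / 3 * pi * 3.07 * 2.295 * 1.095,
               tolerance = 1e-12)
  expect_equal(sum(vm2$mask) * prod(vm2$spacing_mm),
               vm2$ground_truth$volume_mm3, tolerance = 0.02)
})

test_that("noiseless vestibular voxel centers satisfy the ellipsoid inequality", {
  sp <- phantom_spec()
  vm <- make_vestibule_mask(sp)
  idx <- which(vm$mask, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 0.5, 2, vm$spacing_mm, `*`), 2, vm$origin_mm, `+`)
  L <- sweep(pts, 2, vm$ground_truth$center_mm) %*% vm$ground_truth$axes
  a <- vm$ground_truth$semi_axes_mm
  q <- (L[, 1] / a[1])^2 + (L[, 2] / a[2])^2 + (L[, 3] / a[3])^2
  expect_lte(max(q), 1 + 1e-9)
})

test_that("canal masks lie in the specified plane and scale with arc length", {
  # canal in the z = center plane
  sp <- phantom_spec(canals = list(LSC = list(
    plane_normal = c(0, 0, 1), torus_major_radius_mm = 2.8,
    torus_minor_radius_mm = 0.3, arc_fraction = 1, center_mm = c(0, 0, 2))))
  cm <- make_canal_mask(sp, "LSC")
  idx <- which(cm$mask, arr.ind = TRUE)
  z <- cm$origin_mm[3] + (idx[, 3] - 0.5) * cm$spacing_mm[3]
  expect_lte(max(abs(z - 2)), 0.3 + 1e-9)
  # voxel count ratio full : 3/4 arc ~ 4 : 3 (within 5%)
  sp75 <- phantom_spec(canals = list(LSC = modifyList(
    sp$canals$LSC, list(arc_fraction = 0.75))))
  cm75 <- make_canal_mask(sp75, "LSC")
  expect_equal(sum(cm$mask) / sum(cm75$mask), 4 / 3, tolerance = 0.05)
})

test_that("posed canal ground-truth normal is the rotated construction normal", {
  R <- rotation_about_axis(c(1, 2, 0.5), 37)
  sp <- phantom_spec(canals = list(SSC = list(
    plane_normal = c(0, 0, 1), torus_major_radius_mm = 2.8,
    torus_minor_radius_mm = 0.4, arc_fraction = 0.8, center_mm = c(0, 0, 0))),
    rigid_pose = list(rotation = R, translation = c(1, -2, 3)))
  cm <- make_canal_mask(sp, "SSC")
  expect_equal(cm$ground_truth$plane_normal, as.numeric(R %*% c(0, 0, 1)),
               tolerance = 1e-12)
})

test_that("assembled labyrinth has five disjoint structures", {
  asm <- default_assembly()
  vol <- asm$volume
  expect_setequal(setdiff(unique(as.integer(vol$voxels)), 0L), 1:5)
  # default placement is disjoint: per-label counts equal standalone masks
  spec <- phantom_spec()
  grid <- list(origin_mm = vol$origin_mm, dims = dim(vol$voxels),
               spacing_mm = vol$spacing_mm)
  expect_equal(sum(vol$voxels == 1L), sum(make_cochlea_mask(spec, grid)$mask))
  expect_equal(sum(vol$voxels == 2L), sum(make_vestibule_mask(spec, grid)$mask))
  expect_equal(sum(vol$voxels == 4L), sum(make_canal_mask(spec, "LSC", grid)$mask))
})

test_that("assembled volume round-trips through NIfTI", {
  asm <- assemble_labyrinth(phantom_spec(voxel_spacing_mm = 0.2))
  f <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(f, sub("\\.nii\\.gz$", ".labels.json", f))))
  write_label_volume(asm$volume, f)
  r <- read_label_volume(f)
  expect_identical(r$voxels, asm$volume$voxels)
  expect_equal(r$spacing_mm, asm$volume$spacing_mm, tolerance = 1e-6)
})

test_that("a user grid too small for a structure names it", {
  spec <- phantom_spec()
  grid <- list(origin_mm = c(0, 0, 0), dims = c(10L, 10L, 10L),
               spacing_mm = rep(0.1, 3))
  expect_error(make_cochlea_mask(spec, grid), "cochlea")
  expect_error(assemble_labyrinth(spec, grid), "SSC")
})

test_that("rigid pose transports every ground-truth vector and point exactly", {
  R <- rotation_about_axis(c(1, -1, 2), 63)
  tr <- c(4, 5, -6)
  sp0 <- phantom_spec(voxel_spacing_mm = 0.2)
  sp1 <- phantom_spec(voxel_spacing_mm = 0.2,
                      rigid_pose = list(rotation = R, translation = tr))
  g0 <- assemble_labyrinth(sp0)$ground_truth
  g1 <- assemble_labyrinth(sp1)$ground_truth
  expect_equal(g1$cochlea$modiolar_axis,
               as.numeric(R %*% g0$cochlea$modiolar_axis), tolerance = 1e-9)
  expect_equal(g1$cochlea$basal_endpoint_mm,
               as.numeric(R %*% g0$cochlea$basal_endpoint_mm + tr),
               tolerance = 1e-9)
  expect_equal(g1$vestibule$center_mm,
               as.numeric(R %*% g0$vestibule$center_mm + tr), tolerance = 1e-9)
  for (nm in c("PSC", "LSC", "SSC"))
    expect_equal(g1[[nm]]$plane_normal,
                 as.numeric(R %*% g0[[nm]]$plane_normal), tolerance = 1e-9)
  # scalar ground truth unchanged by the pose
  expect_equal(g1$cochlea$basal_diameter_mm, g0$cochlea$basal_diameter_mm)
  expect_equal(g1$vestibule$volume_mm3, g0$vestibule$volume_mm3)
})
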