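test_that("isotropic resampling preserves constants, extent, and linear
           ramps", {
  # identity case
  v1 <- ct_volume(array(stats::rnorm(8^3), dim = c(8, 8, 8)), c(1, 1, 1))
  expect_identical(resample_isotropic(v1, 1), v1)
  # constant field at 2 mm -> ~doubled grid, same value
  vc <- make_constant_volume(c(30, 30, 30), hu = 100, spacing = c(2, 2, 2))
  r <- resample_isotropic(vc, 1)
  expect_true(all(abs(dim(r$voxels) - 60) <= 1))
  expect_true(all(r$voxels == 100))
  expect_equal(r$spacing, c(1, 1, 1))
  # linear HU ramp along x sampled at 2 mm: resampled values match the
  # analytic ramp at the new sample points
  ramp <- ct_volume(
    array(rep(seq(0, 290, by = 10), times = 10 * 10), dim = c(30, 10, 10)),
    spacing = c(2, 2, 2)
  )
  r2 <- resample_isotropic(ramp, 1)
  world_x <- (seq_len(dim(r2$voxels)[1]) - 1) * 1
  expect_equal(r2$voxels[, 3, 3], world_x * 5, tolerance = 1e-9)
  expect_error(resample_isotropic(vc, 0), "positive")
})

test_that("crop windowing maps HU to [0,1] and pads with air", {
  expect_equal(normalize_hu(-250), 0.5)
  expect_equal(normalize_hu(-1000), 0)
  expect_equal(normalize_hu(500), 1)
  expect_equal(normalize_hu(2000), 1)
  vol <- make_constant_volume(c(40, 40, 40), hu = -250, spacing = c(1, 1, 1))
  crop <- crop_and_normalize(vol, c(20, 20, 20))
  expect_equal(dim(crop$cube), c(50, 50, 50))
  expect_true(all(crop$cube %in% c(0, 0.5)))
  # corner centroid: still 50^3 with padding exactly 0
  corner <- crop_and_normalize(vol, c(0, 0, 0))
  expect_equal(dim(corner$cube), c(50, 50, 50))
  expect_equal(corner$cube[1, 1, 1], 0)
  expect_gt(mean(corner$cube == 0), 0.5)
  expect_error(crop_and_normalize(vol, c(200, 20, 20)), "25 mm")
  # idempotence/monotonicity of the windowing
  x <- seq(-1500, 1000, by = 10)
  y <- normalize_hu(x)
  expect_true(all(diff(y) >= 0))
  expect_equal(normalize_hu(y * 1500 - 1000), y)
})

test_that("nine views pass through the centre and axis views match central
           slices", {
  frames <- nine_plane_frames()
  expect_length(frames, 9)
  for (f in frames) {
    expect_equal(sum(f$e1 * f$e2), 0, tolerance = 1e-12)
    expect_equal(sum(f$e1 * f$normal), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(f$e1^2)), 1)
    expect_equal(sqrt(sum(f$e2^2)), 1)
  }
  # constant crop -> constant views (padding excluded for diagonals)
  vol <- make_constant_volume(c(60, 60, 60), hu = -250, spacing = c(1, 1, 1))
  crop <- crop_and_normalize(vol, c(30, 30, 30))
  vw <- extract_nine_views(crop)
  for (k in 1:3) expect_true(all(vw$planes[, , k] == 0.5))
  # axis-aligned views equal the mean of the two central slices (the grid
  # is centred on the cube's continuous centre)
  withr::with_seed(8, {
    cube <- array(stats::runif(50^3), dim = c(50, 50, 50))
  })
  crop2 <- structure(list(cube = cube), class = "nodule_crop")
  vw2 <- extract_nine_views(crop2)
  expect_equal(vw2$planes[, , 1], (cube[25, , ] + cube[26, , ]) / 2,
               tolerance = 1e-9)
  expect_equal(vw2$planes[, , 3], (cube[, , 25] + cube[, , 26]) / 2,
               tolerance = 1e-9)
  # a bright 2^3 block at the centre shows at every view's central pixel
  cube0 <- array(0, dim = c(50, 50, 50))
  cube0[25:26, 25:26, 25:26] <- 1
  vw3 <- extract_nine_views(structure(list(cube = cube0),
                                      class = "nodule_crop"))
  for (k in 1:9) expect_equal(vw3$planes[25, 25, k], 1, tolerance = 1e-9)
})

test_that("view extraction is equivariant to cube reflections", {
  withr::with_seed(14, {
    cube <- array(stats::runif(50^3), dim = c(50, 50, 50))
  })
  ns <- asNamespace("noduleclip")
  vw <- extract_nine_views(structure(list(cube = cube),
                                     class = "nodule_crop"))
  sig <- function(planes) {
    sort(apply(planes, 3, function(m) {
      paste(signif(sort(c(m)), 7)[c(1, 100, 500, 1250, 2000, 2500)],
            collapse = ",")
    }))
  }
  for (axis in 1:3) {
    flipped <- ns$flip_cube(cube, axis == 1, axis == 2, axis == 3)
    vwf <- extract_nine_views(structure(list(cube = flipped),
                                        class = "nodule_crop"))
    expect_identical(sig(vwf$planes), sig(vw$planes))
  }
})

test_that("a centred sphere yields discs of the right radius in every view", {
  sp <- make_sphere_volume(n = 64, radius = 10)
  crop <- crop_and_normalize(sp$vol, sp$centre_mm)
  vw <- extract_nine_views(crop)
  thr <- (normalize_hu(30) + normalize_hu(-850)) / 2
  for (k in 1:9) {
    area <- sum(vw$planes[, , k] > thr)
    est_r <- sqrt(area / pi)
    expect_lt(abs(est_r - sp$radius), 1)
  }
})

test_that("view stacks standardize channels and resize faithfully", {
  planes <- array(0.6, dim = c(50, 50, 9))
  st <- to_view_stack(planes)
  stats <- asNamespace("noduleclip")$clip_channel_stats()
  for (ch in 1:3) {
    expect_equal(st$views[1, 1, ch, 1], (0.6 - stats$mean[ch]) / stats$sd[ch])
    expect_equal(max(abs(st$views[, , ch, 5] - st$views[1, 1, ch, 1])), 0)
  }
  expect_equal(dim(st$views), c(224, 224, 3, 9))
  expect_error(to_view_stack(array(0, dim = c(50, 50, 7))), "9 planes")
  # resize at equal size is the identity
  withr::with_seed(3, {
    img <- matrix(stats::runif(224^2), 224, 224)
  })
  expect_identical(asNamespace("noduleclip")$resize_bilinear(img, 224, 224),
                   img)
})

test_that("zero-magnitude augmentation is the deterministic path and noise
           obeys its moments", {
  vol <- make_constant_volume(c(60, 60, 60), hu = -250, spacing = c(1, 1, 1))
  idpol <- augmentation_policy(jitter_max_mm = 0, flip_prob = 0,
                               max_rotation_deg = 0, noise_sd = 0,
                               log_gamma_range = c(0, 0))
  base <- crop_and_normalize(vol, c(30, 30, 30))
  expect_identical(augment_crop(vol, c(30, 30, 30), idpol, seed = 1)$cube,
                   base$cube)
  # determinism under a fixed seed
  pol <- augmentation_policy()
  a <- augment_crop(vol, c(30, 30, 30), pol, seed = 42)
  b <- augment_crop(vol, c(30, 30, 30), pol, seed = 42)
  expect_identical(a$cube, b$cube)
  # noise-only policy on a constant 0.5 crop: sd ~= 0.02 over 50^3 voxels
  noisepol <- augmentation_policy(jitter_max_mm = 0, flip_prob = 0,
                                  max_rotation_deg = 0, noise_sd = 0.02,
                                  log_gamma_range = c(0, 0))
  nc <- augment_crop(vol, c(30, 30, 30), noisepol, seed = 7)
  expect_lt(abs(stats::sd(nc$cube) - 0.02), 0.002)
  expect_lt(abs(mean(nc$cube) - 0.5), 0.001)
  expect_true(all(nc$cube >= 0 & nc$cube <= 1))
})

test_that("NIfTI volumes round-trip through write and read", {
  withr::with_seed(19, {
    vol <- ct_volume(array(stats::rnorm(10 * 12 * 14, -500, 100),
                           dim = c(10, 12, 14)),
                     spacing = c(1, 1, 1), origin = c(5, -3, 2))
  })
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_nifti(vol, path)
  back <- read_ct_nifti(path)
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("preprocess_nodule composes the full deterministic path", {
  sp <- make_sphere_volume(n = 40, radius = 6)
  st <- preprocess_nodule(sp$vol, sp$centre_mm)
  expect_s3_class(st, "view_stack")
  expect_equal(dim(st$views), c(224, 224, 3, 9))
  st2 <- preprocess_nodule(sp$vol, sp$centre_mm)
  expect_identical(st$views, st2$views)
})
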