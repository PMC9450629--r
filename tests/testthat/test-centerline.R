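# shared fixture: straight tube volume at 0.2 mm
tube_curve <- straight_curve(10, 51)
tube_vol <- rasterize_canal(
  tube_curve,
  phantom_spec(canal_radius_basal = 1, canal_radius_apical = 1,
               voxel_spacing = 0.2, volume_margin = 1))

test_that("segment_canal reproduces a binary tube exactly and errors on empty", {
  mask <- segment_canal(tube_vol, 0.5)
  expect_identical(mask$data, tube_vol$data >= 0.5)
  expect_identical(mask$spacing, tube_vol$spacing)
  expect_identical(mask$origin, tube_vol$origin)

  empty <- canal_volume(array(0, c(4, 4, 4)), rep(1, 3))
  expect_error(segment_canal(empty, 0.5), class = "cochleaR_segmentation_failure")
})

test_that("auto threshold on a blurred tube keeps the tube volume within 15%", {
  crv <- straight_curve(10, 51)
  sharp <- phantom_spec(canal_radius_basal = 1, canal_radius_apical = 1,
                        voxel_spacing = 0.2, volume_margin = 1)
  blurred <- phantom_spec(canal_radius_basal = 1, canal_radius_apical = 1,
                          voxel_spacing = 0.2, volume_margin = 1,
                          blur_sigma = 0.3)
  v_sharp <- rasterize_canal(crv, sharp)
  v_blur <- rasterize_canal(crv, blurred)
  m <- segment_canal(v_blur, "auto")
  expect_equal(sum(m$data), sum(v_sharp$data >= 0.5), tolerance = 0.15)
})

test_that("extract_path recovers a straight tube and respects seed contracts", {
  mask <- segment_canal(tube_vol, 0.5)
  seeds <- seed_pair(c(0, 0, 0), c(0, 0, 10))
  path <- extract_path(mask, seeds)
  expect_s3_class(path, "centerline_curve")
  # within 3% of tube length at 0.2 mm spacing
  expect_equal(curve_length(path), 10, tolerance = 0.03)
  # vestibule-first orientation
  expect_lt(path$points[1, 3], path$points[nrow(path$points), 3])

  # seed outside the snap radius
  expect_error(extract_path(mask, seed_pair(c(30, 30, 30), c(0, 0, 10))),
               class = "cochleaR_seed_error")
})

test_that("disconnected canal components raise a connectivity error", {
  d <- dim(tube_vol$data)
  cut <- tube_vol$data
  mid <- round(d[3] / 2)
  cut[, , (mid - 2):(mid + 2)] <- 0 # sever the tube
  vol2 <- canal_volume(cut, tube_vol$spacing, tube_vol$origin)
  mask2 <- segment_canal(vol2, 0.5)
  expect_error(extract_path(mask2, seed_pair(c(0, 0, 0), c(0, 0, 10))),
               class = "cochleaR_connectivity_error")
})

test_that("skeleton path stays inside the mask foreground", {
  mask <- segment_canal(tube_vol, 0.5)
  path <- extract_path(mask, seed_pair(c(0, 0, 0), c(0, 0, 10)))
  idx <- world_to_voxel(mask, path$points) + 1L
  inside <- mask$data[cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_true(all(inside))
})

test_that("phantom length recovery improves with resolution (coarse pair)", {
  # the full three-spacing experiment lives in the acceptance suite; here a
  # cheap two-point check that the pipeline is wired up and error shrinks
  ph <- default_phantom_curve(2000)
  errs <- vapply(c(0.4, 0.2), function(sp) {
    spec <- phantom_spec(voxel_spacing = sp)
    vol <- rasterize_canal(ph$curve, spec)
    mask <- segment_canal(vol, 0.5)
    path <- extract_path(mask, seed_pair(ph$curve$points[1, ],
                                         ph$curve$points[nrow(ph$curve$points), ]))
    abs(curve_length(path) - ph$truth) / ph$truth
  }, numeric(1))
  expect_lt(errs[1], 0.10)
  expect_lt(errs[2], 0.07)
  expect_lte(errs[2], errs[1])
  # extracted path length >= straight vestibule-apex distance
  expect_gt(ph$truth, sqrt(sum((ph$curve$points[1, ] -
                                ph$curve$points[nrow(ph$curve$points), ])^2)))
})

test_that("extraction is deterministic", {
  mask <- segment_canal(tube_vol, 0.5)
  seeds <- seed_pair(c(0, 0, 0), c(0, 0, 10))
  p1 <- extract_path(mask, seeds)
  p2 <- extract_path(mask, seeds)
  expect_identical(p1$points, p2$points)
})
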