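test_that("generate_centerline reproduces a planar circle", {
  spec <- phantom_spec(basal_radius = 5, taper_rate = 0, turns = 1,
                       height_rise = 0, canal_radius_basal = 1,
                       canal_radius_apical = 1)
  crv <- generate_centerline(spec, 20000L)
  expect_equal(curve_length(crv), 2 * pi * 5, tolerance = 1e-6)
  # basal end first
  expect_equal(unname(crv$points[1, ]), c(5, 0, 0))
})

test_that("generate_centerline validates arguments", {
  spec <- phantom_spec()
  expect_error(generate_centerline(spec, 1), class = "cochleaR_invalid_argument")
  expect_error(phantom_spec(basal_radius = -1), class = "cochleaR_invalid_argument")
  expect_error(phantom_spec(taper_rate = NaN), class = "cochleaR_invalid_argument")
  expect_error(phantom_spec(canal_radius_basal = 0.4, canal_radius_apical = 0.5),
               class = "cochleaR_invalid_argument")
})

test_that("polyline arc length converges to the quadrature value", {
  spec <- phantom_spec() # default cochlear-like spec, apical spiral radius 1 mm
  expect_equal(spec$basal_radius * exp(-spec$taper_rate * 2 * pi * spec$turns),
               1.0, tolerance = 1e-12)
  truth <- quadrature_arc(spec)
  crv <- generate_centerline(spec, 10000L)
  expect_equal(curve_length(crv), truth, tolerance = 1e-3) # within 0.1%

  # monotone nondecreasing in n_samples
  lens <- vapply(c(50L, 200L, 1000L, 5000L),
                 function(n) curve_length(generate_centerline(spec, n)),
                 numeric(1))
  expect_true(all(diff(lens) >= 0))
  # polyline >= straight-line gap between the ends
  gap <- sqrt(sum((crv$points[nrow(crv$points), ] - crv$points[1, ])^2))
  expect_gt(curve_length(crv), gap)
})

test_that("true_arc_length agrees with the independent quadrature oracle", {
  for (spec in list(phantom_spec(),
                    phantom_spec(basal_radius = 3, turns = 2, height_rise = 3)))
    expect_equal(true_arc_length(spec), quadrature_arc(spec), tolerance = 1e-8)
})

test_that("rasterize_canal stamps the right tube", {
  # straight tube: build a straight 'phantom' via a hand-made curve
  crv <- straight_curve(10, 51)
  spec <- phantom_spec(canal_radius_basal = 1, canal_radius_apical = 1,
                       voxel_spacing = 0.2, volume_margin = 1)
  vol <- rasterize_canal(crv, spec)
  # voxel at a centerline point is foreground; 2 mm radially away is background
  at <- world_to_voxel(vol, matrix(c(0, 0, 5), 1)) + 1L
  off <- world_to_voxel(vol, matrix(c(2, 0, 5), 1)) + 1L
  expect_identical(vol$data[at[1], at[2], at[3]], 1)
  expect_identical(vol$data[off[1], off[2], off[3]], 0)

  # exact oracle: {x : dist(x, segment) <= r} is a capsule,
  # volume pi r^2 L + 4/3 pi r^3 (digitization at 0.2 mm costs a couple %)
  fg_vol <- sum(vol$data >= 0.5) * prod(vol$spacing)
  expect_equal(fg_vol, pi * 1^2 * 10 + 4 / 3 * pi * 1^3, tolerance = 0.03)

  # slender tube: foreground volume ~ pi r^2 L within 5% (caps negligible)
  crv2 <- straight_curve(30, 61)
  spec2 <- phantom_spec(canal_radius_basal = 0.5, canal_radius_apical = 0.5,
                        voxel_spacing = 0.08, volume_margin = 1)
  vol2 <- rasterize_canal(crv2, spec2)
  fg2 <- sum(vol2$data >= 0.5) * prod(vol2$spacing)
  expect_equal(fg2, pi * 0.5^2 * 30, tolerance = 0.05)
})

test_that("rasterization is deterministic, including seeded noise", {
  spec <- phantom_spec(voxel_spacing = 0.4, noise_sd = 0.1, seed = 42L)
  crv <- generate_centerline(spec, 500L)
  v1 <- rasterize_canal(crv, spec)
  v2 <- rasterize_canal(crv, spec)
  expect_identical(v1$data, v2$data)
  # different seed, different noise
  spec2 <- phantom_spec(voxel_spacing = 0.4, noise_sd = 0.1, seed = 43L)
  v3 <- rasterize_canal(crv, spec2)
  expect_false(identical(v1$data, v3$data))
  # noise must not perturb the global RNG stream
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(rasterize_canal(crv, spec)); b <- runif(1)
  expect_identical(a, b)
})

test_that("a too-thin tube warns about possible disconnection", {
  spec <- phantom_spec(canal_radius_basal = 0.3, canal_radius_apical = 0.1,
                       voxel_spacing = 0.4)
  crv <- straight_curve(5, 11)
  expect_warning(rasterize_canal(crv, spec), "disconnect")
})
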