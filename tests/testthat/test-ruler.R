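test_that("ruler_scheme validates its contract", {
  expect_error(ruler_scheme(allowed_set = c(1, 1.5)), class = "cochleaR_invalid_argument")
  expect_error(ruler_scheme(allowed_set = numeric(0)), class = "cochleaR_invalid_argument")
  expect_error(ruler_scheme(fixed_prefix = c(2, -1)), class = "cochleaR_invalid_argument")
  expect_error(ruler_scheme(deviation_tol = 0), class = "cochleaR_invalid_argument")
  s <- ruler_scheme()
  expect_identical(s$fixed_prefix, rep(2, 6))
  expect_identical(s$allowed_set, c(2, 1.5, 1))
})

test_that("place_chord: straight, circular and infeasible cases", {
  line <- straight_curve(10, 2)
  pc <- place_chord(line, 0, 2.0)
  expect_true(pc$crossed)
  expect_equal(pc$end_arc, 2.0, tolerance = 1e-12)
  expect_equal(pc$max_deviation, 0)

  # circle chord-arc closed form: end_arc = 2R asin(L/(2R))
  circ <- circle_curve(5, 60000L, arc_frac = 0.5)
  pc2 <- place_chord(circ, 0, 2.0)
  expect_equal(pc2$end_arc, circle_chord_arc(2, 5), tolerance = 1e-4)
  # chord shorter than the arc it spans, and |E - S| equals the nominal length
  expect_lt(2.0, pc2$end_arc)
  expect_equal(sqrt(sum((pc2$end_point - pc2$start_point)^2)), 2.0,
               tolerance = 1e-9)

  # no crossing when the remaining curve is too short
  short <- straight_curve(1, 2)
  pc3 <- place_chord(short, 0, 2.0)
  expect_false(pc3$crossed)

  expect_error(place_chord(line, 10, 1), class = "cochleaR_invalid_argument")
  expect_error(place_chord(line, 0, -1), class = "cochleaR_invalid_argument")
})

test_that("chord_walk is exact on straight curves", {
  t12 <- chord_walk(straight_curve(12, 25))
  expect_identical(t12$label, paste0("R", 1:6))
  expect_identical(t12$nominal_length, rep(2, 6))
  expect_equal(sum_segments(t12), 12)
  expect_equal(attr(t12, "remainder_arc"), 0, tolerance = 1e-9)
  expect_false(attr(t12, "terminated_with_remainder"))

  t13 <- chord_walk(straight_curve(13, 25))
  expect_identical(t13$nominal_length, c(rep(2, 6), 1))
  expect_equal(sum_segments(t13), 13)
  expect_equal(attr(t13, "remainder_arc"), 0, tolerance = 1e-9)
})

test_that("chord_walk matches the closed-form circle oracle", {
  R <- 5
  circ <- circle_curve(R, 60000L, arc_frac = 0.5) # half circle, arc ~ 15.708
  scheme <- ruler_scheme(deviation_tol = 100)
  tab <- chord_walk(circ, scheme)
  oracle <- circle_walk_oracle(R, curve_length(circ), scheme)
  expect_identical(nrow(tab), length(oracle))
  expect_equal(tab$end_arc, oracle, tolerance = 1e-4)
})

test_that("chord_walk error contracts: prefix-infeasible and runaway", {
  expect_error(chord_walk(straight_curve(5, 10)),
               class = "cochleaR_prefix_infeasible")
  expect_error(chord_walk(straight_curve(50, 100),
                          ruler_scheme(max_segments = 10)),
               class = "cochleaR_runaway_walk")
})

test_that("sum_segments reproduces the packaged per-case readings", {
  # reference case 1 and case 6 columns
  case1 <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 1.5, 1.5, 1, 1)
  case6 <- c(2, 2, 2, 2, 2, 2, 1.5, 1.5, 1, 1)
  mk <- function(r) segment_table(data.frame(label = paste0("R", seq_along(r)),
                                             nominal_length = r))
  expect_equal(sum_segments(mk(case1)), 23.0)
  expect_equal(sum_segments(mk(case6)), 17.0)
  empty <- segment_table(data.frame(label = character(0),
                                    nominal_length = numeric(0)))
  expect_equal(sum_segments(empty), 0)
})

test_that("chord_bias: straight curves are exact, circles match closed form", {
  b <- chord_bias(straight_curve(13, 25))
  expect_equal(b$chord_total, b$spanned_arc, tolerance = 1e-9)
  expect_equal(b$relative_underestimate,
               b$remainder_arc / (b$spanned_arc + b$remainder_arc),
               tolerance = 1e-9)

  # circle of radius 2 walked with 2.0 mm chords: per-chord underestimate
  # 1 - L / (2R asin(L/(2R))) ~ 4.51%
  circ <- circle_curve(2, 40000L)
  scheme <- ruler_scheme(fixed_prefix = rep(2, 5), allowed_set = 2,
                         deviation_tol = 100)
  tab <- chord_walk(circ, scheme)
  per_chord <- 1 - tab$nominal_length / diff(c(0, tab$end_arc))
  expect_equal(per_chord, rep(1 - 2 / circle_chord_arc(2, 2), nrow(tab)),
               tolerance = 1e-4)
})

test_that("chord inequality and determinism on the default phantom", {
  ph <- default_phantom_curve(3000)
  tab <- chord_walk(ph$curve)
  # every chord nominal <= its spanned arc
  spans <- diff(c(0, tab$end_arc))
  expect_true(all(tab$nominal_length <= spans + 1e-12))
  # chord_total <= spanned <= total arc
  expect_lte(sum_segments(tab), tab$end_arc[nrow(tab)] + 1e-12)
  expect_lte(tab$end_arc[nrow(tab)], curve_length(ph$curve) + 1e-12)
  # |end - start| = nominal within 1e-9 relative
  elen <- sqrt((tab$x1 - tab$x0)^2 + (tab$y1 - tab$y0)^2 + (tab$z1 - tab$z0)^2)
  expect_equal(elen, tab$nominal_length, tolerance = 1e-9)
  # strictly increasing arcs
  expect_true(all(diff(tab$start_arc) > 0) && all(tab$end_arc > tab$start_arc))
  # determinism
  expect_identical(chord_walk(ph$curve), tab)
})

test_that("refinement stability: finer resampling moves the total < 1 mm", {
  ph <- default_phantom_curve(3000)
  t1 <- chord_walk(ph$curve)
  t2 <- chord_walk(resample_curve(ph$curve, 0.005))
  expect_lt(abs(sum_segments(t1) - sum_segments(t2)), 1.0)
})

test_that("halved rulers hug the curve at least as well", {
  ph <- default_phantom_curve(3000)
  fine <- ruler_scheme(fixed_prefix = rep(1, 12),
                       allowed_set = c(1, 0.75, 0.5))
  expect_gte(sum_segments(chord_walk(ph$curve, fine)),
             sum_segments(chord_walk(ph$curve)))
})
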