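#' Parametric cochlear phantom specification
#'
#' Defines a synthetic cochlea as an exponentially tapering helico-spiral --
#' the standard parametric shape of cochlear morphometry -- with a tubular
#' canal of linearly tapering radius around it. The centerline is
#' \deqn{C(\theta) = (r(\theta)\cos\theta,\; r(\theta)\sin\theta,\;
#'       h\,\theta/(2\pi T)),\qquad r(\theta) = R_0 e^{-b\theta},}
#' for \eqn{\theta \in [0, 2\pi T]}, basal end first. The phantom stands in
#' for volumetric inner-ear images: unlike a cadaver scan it has an
#' analytically known arc length ([true_arc_length()]), which is what makes
#' chord-versus-arc bias measurable.
#'
#' Defaults describe an adult-sized cochlea: basal spiral radius 4 mm tapering
#' to 1 mm over 2.5 turns, 5 mm axial rise, canal radius 0.9 mm (basal) to
#' 0.5 mm (apical). With these values the true arc length is about 34.6 mm and
#' successive turns of the canal keep ~0.9 mm clearance, so the rasterized
#' tube never merges across turns.
#'
#' @param basal_radius spiral radius at theta = 0, mm.
#' @param taper_rate exponential decay of spiral radius per radian; the
#'   default makes the apical spiral radius `basal_radius/4` at 2.5 turns.
#' @param turns total number of turns.
#' @param height_rise total axial rise over all turns, mm.
#' @param canal_radius_basal,canal_radius_apical tube radius at the basal /
#'   apical end, mm, interpolated linearly in theta; must satisfy
#'   `canal_radius_basal >= canal_radius_apical > 0`.
#' @param voxel_spacing voxel spacing for rasterization, mm (length 1 or 3).
#' @param volume_margin padding around the tube when rasterizing, mm.
#' @param blur_sigma isotropic Gaussian partial-volume smoothing, mm; 0 = none.
#' @param noise_sd additive Gaussian noise SD in intensity units; 0 = none.
#' @param seed integer seed for the noise generator (reproducibility).
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' true_arc_length(spec)
#' @export
phantom_spec <- function(basal_radius = 4.0,
                         taper_rate = log(4) / (5 * pi),
                         turns = 2.5,
                         height_rise = 5.0,
                         canal_radius_basal = 0.9,
                         canal_radius_apical = 0.5,
                         voxel_spacing = 0.2,
                         volume_margin = 1.5,
                         blur_sigma = 0,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot_scalar_number(basal_radius, "basal_radius", positive = TRUE)
  stopifnot_scalar_number(taper_rate, "taper_rate")
  stopifnot_scalar_number(turns, "turns", positive = TRUE)
  stopifnot_scalar_number(height_rise, "height_rise")
  stopifnot_scalar_number(canal_radius_basal, "canal_radius_basal", positive = TRUE)
  stopifnot_scalar_number(canal_radius_apical, "canal_radius_apical", positive = TRUE)
  if (canal_radius_basal < canal_radius_apical)
    abort_cochlear("canal_radius_basal must be >= canal_radius_apical",
                   "cochleaR_invalid_argument")
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    abort_cochlear("voxel_spacing must be 1 or 3 positive numbers",
                   "cochleaR_invalid_argument")
  stopifnot_scalar_number(volume_margin, "volume_margin")
  stopifnot_scalar_number(blur_sigma, "blur_sigma")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (blur_sigma < 0 || noise_sd < 0 || volume_margin < 0)
    abort_cochlear("volume_margin, blur_sigma and noise_sd must be >= 0",
                   "cochleaR_invalid_argument")
  structure(list(basal_radius = basal_radius, taper_rate = taper_rate,
                 turns = turns, height_rise = height_rise,
                 canal_radius_basal = canal_radius_basal,
                 canal_radius_apical = canal_radius_apical,
                 voxel_spacing = voxel_spacing, volume_margin = volume_margin,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> R0=%.2f mm, taper=%.4f/rad, %.2f turns, ",
                     "rise=%.2f mm, canal %.2f->%.2f mm\n"),
              x$basal_radius, x$taper_rate, x$turns, x$height_rise,
              x$canal_radius_basal, x$canal_radius_apical))
  invisible(x)
}

# spiral position / derivative norm / tube radius, all closed-form in theta
phantom_point <- function(spec, theta) {
  r <- spec$basal_radius * exp(-spec$taper_rate * theta)
  h <- spec$height_rise / (2 * pi * spec$turns)
  cbind(r * cos(theta), r * sin(theta), h * theta)
}

phantom_speed <- function(spec, theta) {
  r <- spec$basal_radius * exp(-spec$taper_rate * theta)
  h <- spec$height_rise / (2 * pi * spec$turns)
  sqrt(r^2 * (1 + spec$taper_rate^2) + h^2)
}

phantom_tube_radius <- function(spec, theta) {
  f <- theta / (2 * pi * spec$turns)
  spec$canal_radius_basal +
    (spec$canal_radius_apical - spec$canal_radius_basal) * f
}

#' Sample the phantom centerline
#'
#' Samples the helico-spiral at `n_samples` uniformly spaced values of theta
#' over `[0, 2*pi*turns]`; the first point is the basal (vestibule-side) end.
#'
#' @param spec a [phantom_spec()].
#' @param n_samples number of samples (>= 2).
#' @return A [centerline_curve()].
#' @export
generate_centerline <- function(spec, n_samples = 2000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n_samples) || length(n_samples) != 1L ||
      !is.finite(n_samples) || n_samples < 2)
    abort_cochlear("n_samples must be >= 2", "cochleaR_invalid_argument")
  theta <- seq(0, 2 * pi * spec$turns, length.out = as.integer(n_samples))
  centerline_curve(phantom_point(spec, theta))
}

#' Ground-truth arc length of a phantom by adaptive quadrature
#'
#' Integrates the closed-form speed \eqn{\|C'(\theta)\|} over the full
#' parameter range. This is the phantom's ground truth against which both
#' centerline recovery and chord-walk underestimation are judged.
#'
#' @param spec a [phantom_spec()].
#' @param rel.tol relative quadrature tolerance.
#' @return True arc length in mm.
#' @export
true_arc_length <- function(spec, rel.tol = 1e-10) {
  stopifnot(inherits(spec, "phantom_spec"))
  integrate(function(t) phantom_speed(spec, t), 0, 2 * pi * spec$turns,
            rel.tol = rel.tol, subdivisions = 1000L)$value
}

#' Rasterize the phantom canal into a volume
#'
#' Voxels whose center lies within the local tube radius of the centerline
#' get foreground intensity 1, the rest 0; optional isotropic Gaussian blur
#' (partial-volume emulation) and seeded additive noise follow. The grid
#' covers the tube plus `volume_margin` on every side.
#'
#' With `noise_sd = 0` the output is bit-identical across runs; with noise,
#' runs with the same `seed` are identical.
#'
#' @param curve a [centerline_curve()] (normally from [generate_centerline()];
#'   any curve works, with the tube radius interpolated along its arc).
#' @param spec the [phantom_spec()] supplying tube radii, spacing, margin,
#'   blur and noise settings.
#' @return A [canal_volume()].
#' @export
rasterize_canal <- function(curve, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!inherits(curve, "centerline_curve"))
    abort_cochlear("`curve` must be a centerline_curve",
                   "cochleaR_invalid_argument")
  sp <- spec$voxel_spacing
  if (min(spec$canal_radius_apical, spec$canal_radius_basal) < max(sp) / 2)
    warning("tube radius smaller than half the largest voxel spacing: ",
            "the rasterized canal may disconnect", call. = FALSE)

  total <- curve_length(curve)
  # dense samples along the curve; tube radius interpolated linearly in arc
  step <- min(sp) / 2
  n <- max(2L, ceiling(total / step) + 1L)
  arcs <- seq(0, total, length.out = n)
  pts <- curve_point_at(curve, arcs)
  f <- arcs / total
  rad <- spec$canal_radius_basal +
    (spec$canal_radius_apical - spec$canal_radius_basal) * f

  lo <- apply(pts - rad, 2, min) - spec$volume_margin
  hi <- apply(pts + rad, 2, max) + spec$volume_margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  a <- array(FALSE, dims)

  # stamp a ball at each sample; sample step <= spacing/2 keeps the union
  # within ~step^2/(8*radius) of the exact tube
  for (s in seq_len(n)) {
    p <- pts[s, ]; r <- rad[s]
    i0 <- pmax(1L, as.integer(floor((p - r - lo) / sp)) + 1L)
    i1 <- pmin(dims, as.integer(ceiling((p + r - lo) / sp)) + 1L)
    xs <- lo[1] + (i0[1]:i1[1] - 1L) * sp[1]
    ys <- lo[2] + (i0[2]:i1[2] - 1L) * sp[2]
    zs <- lo[3] + (i0[3]:i1[3] - 1L) * sp[3]
    dx2 <- (xs - p[1])^2; dy2 <- (ys - p[2])^2; dz2 <- (zs - p[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    a[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      a[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] | inside
  }

  img <- array(as.numeric(a), dims)
  if (spec$blur_sigma > 0) img <- gaussian_blur3(img, sp, spec$blur_sigma)
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           array(rnorm(length(img), sd = spec$noise_sd), dims))
  canal_volume(img, spacing = sp, origin = lo)
}
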