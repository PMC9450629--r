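# Oracle helpers shared across the suite. Everything here is independent of
# the code paths it checks: closed forms, quadrature, and brute-force walks.

# straight curve of given length along z, with n vertices
straight_curve <- function(len, n = 2L) {
  centerline_curve(cbind(0, 0, seq(0, len, length.out = n)))
}

# planar circle of radius R sampled with n vertices over arc [0, arc_frac*2*pi*R]
circle_curve <- function(R, n = 20000L, arc_frac = 1) {
  th <- seq(0, arc_frac * 2 * pi, length.out = n)
  centerline_curve(cbind(R * cos(th), R * sin(th), 0))
}

# closed-form arc consumed on a circle of radius R by a chord of length L
circle_chord_arc <- function(L, R) 2 * R * asin(L / (2 * R))

# independent chord-walk oracle on an ideal circle: advances by the
# closed-form chord->arc map, same greedy rule as the scheme
circle_walk_oracle <- function(R, total_arc, scheme) {
  ends <- numeric(0)
  pos <- 0
  for (L in scheme$fixed_prefix) {
    step <- circle_chord_arc(L, R)
    if (pos + step > total_arc) stop("oracle: prefix infeasible")
    pos <- pos + step
    ends <- c(ends, pos)
  }
  repeat {
    placed <- FALSE
    for (L in scheme$allowed_set) {
      step <- circle_chord_arc(L, R)
      if (pos + step <= total_arc) {
        pos <- pos + step
        ends <- c(ends, pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  ends
}

# quadrature arc length of a phantom spec, written against the closed-form
# speed directly (not via the package helper)
quadrature_arc <- function(spec) {
  h <- spec$height_rise / (2 * pi * spec$turns)
  f <- function(t) sqrt(spec$basal_radius^2 * exp(-2 * spec$taper_rate * t) *
                          (1 + spec$taper_rate^2) + h^2)
  stats::integrate(f, 0, 2 * pi * spec$turns, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

# closed-form arc length of the Archimedean spiral r = theta from 0 to T
archimedean_arc <- function(T) 0.5 * (T * sqrt(1 + T^2) + asinh(T))

# default phantom centerline + truth, computed once per test file load
default_phantom_curve <- function(n = 4000L) {
  spec <- phantom_spec()
  list(spec = spec, curve = generate_centerline(spec, n),
       truth = quadrature_arc(spec))
}
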