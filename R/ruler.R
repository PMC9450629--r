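#' Ruler scheme: the predefined chord-measurement protocol
#'
#' The measurement protocol lays digitized rulers of predefined length as
#' straight chords along the canal centerline, vestibule to apex. The first
#' six rulers (R1--R6) are mandatory 2.0 mm chords; every later ruler is the
#' largest of the allowed set (2.0, 1.5, 1.0 mm by default) whose chord both
#' crosses the remaining curve and stays within `deviation_tol` of it -- the
#' digital reconstruction of "smaller rulers to measure the cochlear
#' contours".
#'
#' @param fixed_prefix ordered chord lengths (mm) placed unconditionally at
#'   the start; default six 2.0 mm rulers.
#' @param allowed_set strictly descending chord lengths (mm) tried for every
#'   subsequent ruler.
#' @param deviation_tol maximum perpendicular distance (mm) allowed between a
#'   non-prefix chord and the sub-curve it spans; default 0.5 mm, about the
#'   apical canal radius.
#' @param max_segments guard against runaway walks.
#' @return An object of class `ruler_scheme`.
#' @export
ruler_scheme <- function(fixed_prefix = rep(2.0, 6L),
                         allowed_set = c(2.0, 1.5, 1.0),
                         deviation_tol = 0.5,
                         max_segments = 100L) {
  fixed_prefix <- as.numeric(fixed_prefix)
  allowed_set <- as.numeric(allowed_set)
  if (length(allowed_set) == 0L || any(!is.finite(allowed_set)) ||
      any(allowed_set <= 0))
    abort_cochlear("allowed_set must be positive lengths",
                   "cochleaR_invalid_argument")
  if (any(diff(allowed_set) >= 0))
    abort_cochlear("allowed_set must be strictly descending",
                   "cochleaR_invalid_argument")
  if (length(fixed_prefix) && (any(!is.finite(fixed_prefix)) ||
                               any(fixed_prefix <= 0)))
    abort_cochlear("fixed_prefix must be positive lengths",
                   "cochleaR_invalid_argument")
  stopifnot_scalar_number(deviation_tol, "deviation_tol", positive = TRUE)
  stopifnot_scalar_number(max_segments, "max_segments", positive = TRUE)
  structure(list(fixed_prefix = fixed_prefix, allowed_set = allowed_set,
                 deviation_tol = deviation_tol,
                 max_segments = as.integer(max_segments)),
            class = "ruler_scheme")
}

#' @export
print.ruler_scheme <- function(x, ...) {
  cat(sprintf("<ruler_scheme> prefix [%s] mm, allowed {%s} mm, tol %.2f mm\n",
              paste(format(x$fixed_prefix), collapse = ", "),
              paste(format(x$allowed_set), collapse = ", "), x$deviation_tol))
  invisible(x)
}

#' Place one chord along a curve
#'
#' Starting from `start_arc`, finds the smallest `end_arc > start_arc` at
#' which the straight-line (Euclidean) distance between `curve(start_arc)`
#' and `curve(end_arc)` equals `length` -- the first crossing, as a physical
#' ruler laid forward along the canal would meet it. On the piecewise-linear
#' curve the squared distance to the start point is an exact quadratic per
#' segment, so the crossing is solved in closed form. Also reports the
#' maximum perpendicular deviation of the spanned sub-curve from the chord.
#'
#' @param curve a [centerline_curve()].
#' @param start_arc arc position of the chord start, `0 <= start_arc <` total.
#' @param length chord length in mm (> 0).
#' @return A list with `crossed` (logical); when crossed, `end_arc` (mm) and
#'   `max_deviation` (mm), plus `start_point`/`end_point` world coordinates.
#'   `crossed = FALSE` means no point of the remaining curve lies at exactly
#'   `length` mm straight-line distance from the start.
#' @export
place_chord <- function(curve, start_arc, length) {
  stopifnot(inherits(curve, "centerline_curve"))
  stopifnot_scalar_number(start_arc, "start_arc")
  stopifnot_scalar_number(length, "length", positive = TRUE)
  chord_len <- length
  rm(length) # unshadow base::length
  total <- curve_length(curve)
  if (start_arc < 0 || start_arc >= total)
    abort_cochlear("start_arc must satisfy 0 <= start_arc < total arc",
                   "cochleaR_invalid_argument")

  S <- drop(curve_point_at(curve, start_arc))
  ca <- curve$cum_arc
  pts <- curve$points
  i0 <- findInterval(start_arc, ca, rightmost.closed = TRUE)
  i0 <- min(max(i0, 1L), length(ca) - 1L)

  end_arc <- NA_real_
  for (i in i0:(nrow(pts) - 1L)) {
    A <- pts[i, ]; B <- pts[i + 1L, ]
    t_lo <- if (i == i0) (start_arc - ca[i]) / (ca[i + 1L] - ca[i]) else 0
    AB <- B - A; AS <- A - S
    a <- sum(AB^2)
    b <- 2 * sum(AS * AB)
    cc <- sum(AS^2) - chord_len^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) next
    sq <- sqrt(disc)
    roots <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
    roots <- roots[roots > t_lo + 1e-15 & roots <= 1 + 1e-12]
    if (length(roots)) {
      t <- min(roots)
      end_arc <- ca[i] + t * (ca[i + 1L] - ca[i])
      break
    }
  }
  if (!is.finite(end_arc) || end_arc > total + 1e-12)
    return(list(crossed = FALSE, end_arc = NA_real_, max_deviation = NA_real_))

  E <- drop(curve_point_at(curve, end_arc))
  inner <- pts[ca > start_arc & ca < end_arc, , drop = FALSE]
  dev <- if (nrow(inner) == 0L) 0 else max(point_segment_distance(inner, S, E))
  list(crossed = TRUE, end_arc = end_arc, max_deviation = dev,
       start_point = S, end_point = E)
}

# distance from rows of P to the segment S-E; the spanned sub-curve is
# piecewise linear and distance-to-a-segment is convex, so checking vertices
# suffices for the maximum over the sub-curve
point_segment_distance <- function(P, S, E) {
  D <- E - S
  len2 <- sum(D^2)
  t <- pmin(pmax(drop(sweep(P, 2L, S) %*% D) / len2, 0), 1)
  Q <- outer(t, D) + rep(S, each = nrow(P))
  sqrt(rowSums((P - Q)^2))
}

#' Walk a centerline with the ruler scheme
#'
#' Places the mandatory prefix chords (R1, R2, ...) in order, then repeatedly
#' places the largest allowed chord that (a) has a first crossing before the
#' apex and (b) deviates from the spanned sub-curve by at most
#' `deviation_tol`. The walk terminates when no allowed ruler satisfies both;
#' any unspanned arc to the apex is recorded as the remainder (the table
#' marker "DNM" -- no further segment placed).
#'
#' @param curve a [centerline_curve()], vestibule-first.
#' @param scheme a [ruler_scheme()].
#' @return A `segment_table`: a data frame with one row per placed ruler
#'   (`label`, `nominal_length`, start/end world coordinates, `start_arc`,
#'   `end_arc`) carrying attributes `total` (mm, exact sum of nominal
#'   lengths), `remainder_arc` (mm) and `terminated_with_remainder`.
#' @export
chord_walk <- function(curve, scheme = ruler_scheme()) {
  stopifnot(inherits(curve, "centerline_curve"), inherits(scheme, "ruler_scheme"))
  total <- curve_length(curve)
  rows <- list()
  pos <- 0
  k <- 0L

  for (L in scheme$fixed_prefix) {
    if (pos >= total)
      abort_cochlear("curve exhausted before the mandatory ruler prefix was placed",
                     "cochleaR_prefix_infeasible")
    pc <- place_chord(curve, pos, L)
    if (!pc$crossed)
      abort_cochlear(sprintf("mandatory %.1f mm ruler R%d finds no crossing: curve too short for the prefix",
                             L, k + 1L),
                     "cochleaR_prefix_infeasible")
    k <- k + 1L
    rows[[k]] <- data.frame(label = paste0("R", k), nominal_length = L,
                            x0 = pc$start_point[1], y0 = pc$start_point[2],
                            z0 = pc$start_point[3],
                            x1 = pc$end_point[1], y1 = pc$end_point[2],
                            z1 = pc$end_point[3],
                            start_arc = pos, end_arc = pc$end_arc)
    pos <- pc$end_arc
  }

  repeat {
    if (k >= scheme$max_segments)
      abort_cochlear("max_segments exceeded during chord walk",
                     "cochleaR_runaway_walk")
    if (pos >= total) break
    placed <- NULL
    for (L in scheme$allowed_set) {
      pc <- place_chord(curve, pos, L)
      if (pc$crossed && pc$max_deviation <= scheme$deviation_tol) {
        placed <- pc; placed$L <- L
        break
      }
    }
    if (is.null(placed)) break
    k <- k + 1L
    rows[[k]] <- data.frame(label = paste0("R", k), nominal_length = placed$L,
                            x0 = placed$start_point[1], y0 = placed$start_point[2],
                            z0 = placed$start_point[3],
                            x1 = placed$end_point[1], y1 = placed$end_point[2],
                            z1 = placed$end_point[3],
                            start_arc = pos, end_arc = placed$end_arc)
    pos <- placed$end_arc
  }

  df <- if (k > 0L) do.call(rbind, rows) else
    data.frame(label = character(0), nominal_length = numeric(0),
               x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
               start_arc = numeric(0), end_arc = numeric(0))
  remainder <- max(0, total - pos)
  segment_table(df, remainder_arc = remainder,
                terminated_with_remainder = remainder > 1e-9 * max(1, total))
}

#' Construct a segment table
#'
#' Normally produced by [chord_walk()]; exposed so that externally recorded
#' per-ruler readings (e.g. the packaged reference cases) can be carried in
#' the same container.
#'
#' @param segments data frame with columns `label`, `nominal_length`, and
#'   (optionally `NA`) `x0,y0,z0,x1,y1,z1,start_arc,end_arc`.
#' @param remainder_arc unmeasured arc between the last ruler and the apex, mm.
#' @param terminated_with_remainder did the walk stop before the apex?
#' @return The `segment_table` object.
#' @export
segment_table <- function(segments, remainder_arc = 0,
                          terminated_with_remainder = FALSE) {
  need <- c("label", "nominal_length")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    abort_cochlear("segments must be a data frame with label and nominal_length",
                   "cochleaR_invalid_argument")
  for (col in c("x0", "y0", "z0", "x1", "y1", "z1", "start_arc", "end_arc"))
    if (is.null(segments[[col]])) segments[[col]] <- rep(NA_real_, nrow(segments))
  structure(segments,
            class = c("segment_table", "data.frame"),
            total = sum(segments$nominal_length),
            remainder_arc = remainder_arc,
            terminated_with_remainder = isTRUE(terminated_with_remainder))
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d rulers, total %.2f mm, remainder %.3f mm%s\n",
              nrow(x), attr(x, "total"), attr(x, "remainder_arc"),
              if (attr(x, "terminated_with_remainder")) " (terminated before apex)" else ""))
  if (nrow(x))
    print.data.frame(data.frame(label = x$label, length_mm = x$nominal_length,
                                end_arc_mm = round(x$end_arc, 4)), row.names = FALSE)
  invisible(x)
}

#' Total measured length: the exact sum of placed ruler lengths
#'
#' "Adding up these values yields the total length": all scheme lengths are
#' multiples of 0.5 mm, so the sum is exact.
#'
#' @param table a `segment_table` (from [chord_walk()] or [segment_table()]).
#' @return Total length in mm.
#' @export
sum_segments <- function(table) {
  stopifnot(inherits(table, "segment_table"))
  if (nrow(table) == 0L) return(0)
  sum(table$nominal_length)
}

#' Chord-versus-arc underestimation of the ruler protocol
#'
#' A straight chord is never longer than the arc it spans, so the summed
#' ruler readings systematically underestimate the true canal length on
#' curved geometry; the unmeasured remainder past the last ruler adds to the
#' gap. This quantifies both on a known curve.
#'
#' @param curve a [centerline_curve()].
#' @param scheme a [ruler_scheme()].
#' @return A list: `chord_total` (mm), `spanned_arc` (arc consumed by the
#'   rulers, mm), `remainder_arc` (mm), and `relative_underestimate`
#'   `= 1 - chord_total / (spanned_arc + remainder_arc)`.
#' @export
chord_bias <- function(curve, scheme = ruler_scheme()) {
  tab <- chord_walk(curve, scheme)
  chord_total <- sum_segments(tab)
  spanned <- if (nrow(tab)) tab$end_arc[nrow(tab)] else 0
  remainder <- attr(tab, "remainder_arc")
  list(chord_total = chord_total,
       spanned_arc = spanned,
       remainder_arc = remainder,
       relative_underestimate = 1 - chord_total / (spanned + remainder))
}
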