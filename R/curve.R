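#' Ordered 3D centerline polyline
#'
#' A `centerline_curve` is an ordered polyline in world millimetres, stored
#' vestibule-first: the first point is the basal (vestibule-side) end of the
#' canal and the last point its apex. Cumulative polyline arc length is
#' precomputed per vertex.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), at least 2
#'   rows; consecutive rows must be distinct.
#' @return An object of class `centerline_curve`: a list with `points`
#'   (n x 3 matrix) and `cum_arc` (per-vertex cumulative arc length in mm,
#'   starting at 0).
#' @examples
#' crv <- centerline_curve(cbind(c(0, 0, 0), 0, c(0, 5, 10)))
#' curve_length(crv)
#' @export
centerline_curve <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 2L)
    abort_cochlear("`points` must be a numeric matrix with 3 columns and >= 2 rows",
                   "cochleaR_invalid_argument")
  if (any(!is.finite(points)))
    abort_cochlear("curve points must be finite", "cochleaR_invalid_argument")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    abort_cochlear("consecutive curve points must be distinct",
                   "cochleaR_invalid_argument")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, cum_arc = c(0, cumsum(seg))),
            class = "centerline_curve")
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("<centerline_curve> %d points, %.3f mm polyline arc length\n",
              nrow(x$points), curve_length(x)))
  invisible(x)
}

#' Total polyline arc length of a curve
#' @param curve a [centerline_curve()].
#' @return Total cumulative arc length in mm.
#' @export
curve_length <- function(curve) {
  stopifnot(inherits(curve, "centerline_curve"))
  tail(curve$cum_arc, 1L)
}

#' Arc length between two positions along a curve
#'
#' Arc positions are interpreted on the polyline's cumulative arc-length
#' parameterization; the full-curve call returns the total polyline length.
#'
#' @param curve a [centerline_curve()].
#' @param from_arc,to_arc arc positions in mm, `0 <= from_arc <= to_arc <=`
#'   total arc length. Defaults give the whole curve.
#' @return Arc length `to_arc - from_arc` in mm.
#' @export
arc_length <- function(curve, from_arc = 0, to_arc = curve_length(curve)) {
  stopifnot(inherits(curve, "centerline_curve"))
  stopifnot_scalar_number(from_arc, "from_arc")
  stopifnot_scalar_number(to_arc, "to_arc")
  total <- curve_length(curve)
  eps <- 1e-9 * max(1, total)
  if (from_arc < -eps || to_arc > total + eps || from_arc > to_arc + eps)
    abort_cochlear("arc positions must satisfy 0 <= from_arc <= to_arc <= total arc",
                   "cochleaR_invalid_argument")
  max(0, min(to_arc, total) - max(from_arc, 0))
}

#' Point on a curve at a given arc position
#'
#' Linear interpolation on the polyline.
#'
#' @param curve a [centerline_curve()].
#' @param arc arc position(s) in mm within `[0, curve_length(curve)]`.
#' @return Numeric matrix (length(arc) x 3) of world coordinates.
#' @export
curve_point_at <- function(curve, arc) {
  stopifnot(inherits(curve, "centerline_curve"))
  total <- curve_length(curve)
  eps <- 1e-9 * max(1, total)
  if (any(!is.finite(arc)) || any(arc < -eps) || any(arc > total + eps))
    abort_cochlear("arc position out of range", "cochleaR_invalid_argument")
  arc <- pmin(pmax(arc, 0), total)
  ca <- curve$cum_arc
  i <- findInterval(arc, ca, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ca) - 1L)
  den <- ca[i + 1L] - ca[i]
  t <- (arc - ca[i]) / den
  curve$points[i, , drop = FALSE] +
    (curve$points[i + 1L, , drop = FALSE] - curve$points[i, , drop = FALSE]) * t
}

#' Resample a curve at uniform arc-length spacing
#'
#' Re-samples by linear interpolation on the polyline at uniform spacing no
#' larger than `step`; both endpoints are preserved exactly. Resampling on the
#' polyline itself can never lengthen it.
#'
#' @param curve a [centerline_curve()].
#' @param step maximum arc spacing in mm (> 0).
#' @return A new [centerline_curve()].
#' @export
resample_curve <- function(curve, step) {
  stopifnot(inherits(curve, "centerline_curve"))
  stopifnot_scalar_number(step, "step", positive = TRUE)
  total <- curve_length(curve)
  n_seg <- max(1L, ceiling(total / step))
  arcs <- seq(0, total, length.out = n_seg + 1L)
  pts <- curve_point_at(curve, arcs)
  # exact endpoints (interpolation is exact there, but avoid FP drift)
  pts[1L, ] <- curve$points[1L, ]
  pts[nrow(pts), ] <- curve$points[nrow(curve$points), ]
  centerline_curve(pts)
}

#' Project a curve onto its best-fit plane
#'
#' Planar-projection mode: points are orthogonally projected onto the
#' least-squares plane through the curve (principal-component fit), emulating
#' measurement on a single 2D projected view of the 3D reconstruction.
#' Projection shortens a non-planar curve; the mode is off by default in
#' [extract_path()] and exposed so its effect can be reported.
#'
#' @param curve a [centerline_curve()].
#' @return The projected [centerline_curve()] (still in 3D world coordinates,
#'   lying in the fitted plane).
#' @export
project_curve <- function(curve) {
  stopifnot(inherits(curve, "centerline_curve"))
  p <- curve$points
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  normal <- sv$v[, 3L]
  d <- drop(sweep(p, 2, ctr) %*% normal)
  proj <- p - outer(d, normal)
  # collapse any now-duplicated consecutive points
  keep <- c(TRUE, rowSums((proj[-1L, , drop = FALSE] -
                           proj[-nrow(proj), , drop = FALSE])^2) > 1e-24)
  centerline_curve(proj[keep, , drop = FALSE])
}
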