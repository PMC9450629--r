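#' Segment the canal by intensity thresholding
#'
#' Foreground is every voxel with intensity at or above the threshold. With
#' `threshold = "auto"` the threshold is chosen by Otsu's criterion on a
#' 256-bin histogram: the cut that maximizes between-class variance, i.e. the
#' standard bimodality split between the dark background and the bright
#' fluid-filled canal.
#'
#' @param volume a [canal_volume()].
#' @param threshold numeric intensity threshold, or `"auto"` for Otsu.
#' @return A [canal_mask()] with identical grid geometry.
#' @export
segment_canal <- function(volume, threshold = "auto") {
  stopifnot(inherits(volume, "canal_volume"))
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(volume$data)
  } else {
    stopifnot_scalar_number(threshold, "threshold")
  }
  fg <- volume$data >= threshold
  if (!any(fg))
    abort_cochlear(sprintf("segmentation produced an empty mask (threshold %g)",
                           threshold),
                   "cochleaR_segmentation_failure", threshold = threshold)
  m <- canal_mask(fg, volume$spacing, volume$origin)
  attr(m, "threshold") <- threshold
  m
}

#' Otsu threshold of an intensity array
#'
#' Maximizes between-class variance on an `nbins`-bin histogram; the returned
#' threshold is the upper edge of the chosen background bin, so `x >=
#' threshold` selects the bright class.
#'
#' @param x numeric array or vector of intensities.
#' @param nbins number of histogram bins.
#' @return Scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2])
    abort_cochlear("cannot threshold a constant image",
                   "cochleaR_segmentation_failure")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  edges[k + 1L]
}
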