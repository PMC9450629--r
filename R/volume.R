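#' 3D scalar volume with world-coordinate geometry
#'
#' Minimal medical-image container: a 3D array of intensities plus voxel
#' spacing and world origin in mm. The world coordinate of 0-based voxel
#' index `(i, j, k)` is `origin + c(i, j, k) * spacing` (right-handed axes;
#' internally R arrays are 1-based, so array element `[i+1, j+1, k+1]` sits at
#' that world position).
#'
#' @param data numeric 3D array of intensities.
#' @param spacing voxel spacing in mm, length-3, all > 0.
#' @param origin world coordinate (mm) of voxel index (0, 0, 0).
#' @return An object of class `canal_volume`.
#' @export
canal_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_cochlear("`data` must be a 3D array", "cochleaR_invalid_argument")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_cochlear("`spacing` must be 3 positive numbers",
                   "cochleaR_invalid_argument")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort_cochlear("`origin` must be 3 finite numbers",
                   "cochleaR_invalid_argument")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "canal_volume")
}

#' Binary canal mask on the same grid as its source volume
#'
#' @param data logical 3D array (foreground = canal).
#' @param spacing,origin grid geometry, as in [canal_volume()].
#' @return An object of class `canal_mask`.
#' @export
canal_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    abort_cochlear("`data` must be a logical 3D array",
                   "cochleaR_invalid_argument")
  v <- canal_volume(array(0, dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "canal_mask")
}

#' @export
print.canal_volume <- function(x, ...) {
  cat(sprintf("<canal_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.canal_mask <- function(x, ...) {
  cat(sprintf("<canal_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' World coordinates of 0-based voxel indices
#' @param vol a [canal_volume()] or [canal_mask()].
#' @param ijk0 integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk0) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3L)
  sweep(sweep(ijk0, 2L, vol$spacing, `*`), 2L, vol$origin, `+`)
}

#' Nearest 0-based voxel index of world coordinates
#' @param vol a [canal_volume()] or [canal_mask()].
#' @param xyz numeric matrix (n x 3) of world mm coordinates.
#' @return n x 3 integer matrix of 0-based voxel indices (clamped to grid).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk <- round(sweep(sweep(xyz, 2L, vol$origin, `-`), 2L, vol$spacing, `/`))
  d <- dim(vol$data)
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 0), d[a] - 1L)
  storage.mode(ijk) <- "integer"
  ijk
}

# separable Gaussian blur, sigma in world mm, truncated at 3 sigma.
# stats::filter operates columnwise, so each axis is blurred by reshaping the
# array so that axis runs along columns; edges use replicate padding.
gaussian_blur3 <- function(a, spacing, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  for (ax in 1:3) {
    sig_vox <- sigma / spacing[ax]
    half <- max(1L, ceiling(3 * sig_vox))
    k <- dnorm(seq(-half, half), sd = sig_vox)
    k <- k / sum(k)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    # replicate-pad along the filtered axis
    mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
                m[rep(nrow(m), half), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    m <- matrix(f[(half + 1L):(half + db[1]), , drop = FALSE], nrow = db[1])
    b <- array(m, db)
    a <- aperm(b, order(perm))
  }
  a
}
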