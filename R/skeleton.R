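#' Vestibule/apex seed pair
#'
#' The two user-supplied landmarks between which the canal is measured: the
#' start point on the vestibule side of the basal turn and the target at the
#' apex of the spiral. Coordinates are world mm.
#'
#' @param vestibule_point,apex_point length-3 world coordinates (mm); must be
#'   distinct.
#' @return An object of class `seed_pair`.
#' @export
seed_pair <- function(vestibule_point, apex_point) {
  v <- as.numeric(vestibule_point); a <- as.numeric(apex_point)
  if (length(v) != 3L || length(a) != 3L || any(!is.finite(c(v, a))))
    abort_cochlear("seed points must be finite length-3 coordinates",
                   "cochleaR_invalid_argument")
  if (sum((v - a)^2) == 0)
    abort_cochlear("vestibule and apex seeds must be distinct",
                   "cochleaR_invalid_argument")
  structure(list(vestibule_point = v, apex_point = a), class = "seed_pair")
}

#' Skeletonize a binary canal mask by 3D thinning
#'
#' Directional 6-subiteration thinning that deletes simple border points
#' (preserving 26-connectivity of the foreground and 6-connectivity of the
#' background) while keeping curve endpoints, until the mask is a unit-width
#' medial structure. Deterministic for a given mask.
#'
#' @param mask a [canal_mask()].
#' @return A [canal_mask()] containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "canal_mask"))
  if (!any(mask$data))
    abort_cochlear("cannot skeletonize an empty mask",
                   "cochleaR_invalid_argument")
  skel <- .thin_skeleton_cpp(mask$data, dim(mask$data))
  canal_mask(array(skel, dim(mask$data)), mask$spacing, mask$origin)
}

# skeleton voxels -> igraph with 26-connectivity and Euclidean mm weights.
# Returns list(graph, coords0) with coords0 the 0-based voxel indices.
skeleton_graph <- function(skel) {
  d <- dim(skel$data)
  lin <- which(skel$data)
  if (length(lin) == 0L)
    abort_cochlear("empty skeleton", "cochleaR_invalid_argument")
  coord <- arrayInd(lin, d) # 1-based
  id_of <- integer(prod(d)); id_of[lin] <- seq_along(lin)
  # 13 half-offsets cover each undirected 26-neighbour pair once
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- sweep(coord, 2L, o, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    hit <- id_of[nlin] > 0L
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, id_of[nlin[hit]])
    w <- c(w, rep(sqrt(sum((o * skel$spacing)^2)), sum(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(lin), directed = FALSE)
  igraph::E(g)$weight <- w
  list(graph = g, coords0 = coord - 1L)
}

# remove leaf chains shorter than prune_len voxels that end at a junction;
# chains connecting two endpoints (i.e. the main curve) are never pruned.
# Returns original vertex ids to drop.
prune_spur_vertices <- function(g, prune_len) {
  n0 <- igraph::vcount(g)
  igraph::V(g)$orig <- seq_len(n0)
  repeat {
    deg <- igraph::degree(g)
    to_del <- integer(0)
    for (leaf in which(deg == 1)) {
      chain <- leaf; cur <- leaf; prev <- 0L
      junction <- FALSE
      repeat {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nxt) == 0L) break                    # isolated stub
        if (deg[nxt[1]] >= 3) { junction <- TRUE; break } # reached a junction
        if (deg[nxt[1]] == 1) break                     # curve runs end to end
        prev <- cur; cur <- nxt[1]; chain <- c(chain, cur)
        if (length(chain) >= prune_len) break           # long enough to keep
      }
      if (junction && length(chain) < prune_len) to_del <- c(to_del, chain)
    }
    to_del <- unique(to_del)
    if (length(to_del) == 0L) break
    g <- igraph::delete_vertices(g, to_del)
  }
  setdiff(seq_len(n0), igraph::V(g)$orig)
}

#' Extract an ordered vestibule-to-apex centerline from a canal mask
#'
#' Automates the manual "pick the best view and trace the canal" step:
#' \enumerate{
#'   \item skeletonize the mask by 3D thinning ([skeletonize()]);
#'   \item prune skeleton spurs shorter than `prune_len` voxels;
#'   \item build a 26-connectivity graph over the remaining skeleton voxels
#'     with Euclidean edge weights in world mm;
#'   \item take the minimal-cost path from the skeleton voxel nearest the
#'     vestibule seed to the one nearest the apex seed;
#'   \item smooth with a centered moving average and resample at uniform arc
#'     steps.
#' }
#' The 5-point default window keeps the digital-zigzag overestimate of the
#' voxel path suppressed at every spacing, so the recovered length
#' approaches the truth from below and its error shrinks monotonically as
#' voxels shrink; a 3-point window leaves the two error terms (zigzag
#' overestimate vs. smoothing corner-cutting) in cancellation, making the
#' error non-monotone in resolution.
#' The result is vestibule-first. Seeds farther than `snap_radius` from any
#' skeleton voxel raise a seed error; seeds in different connected components
#' raise a connectivity error (the software analogue of an obstructed canal).
#'
#' @param mask a [canal_mask()].
#' @param seeds a [seed_pair()].
#' @param snap_radius maximum seed-to-skeleton snapping distance, mm.
#' @param prune_len spur-pruning threshold in skeleton voxels.
#' @param smooth_window odd moving-average window (points); 1 = no smoothing.
#' @param resample_step uniform arc resampling step in mm after smoothing;
#'   `0` disables resampling. Default: one maximal voxel spacing.
#' @param project if `TRUE`, project the path onto its best-fit plane before
#'   returning (planar-projection measurement mode; see [project_curve()]).
#' @return A [centerline_curve()].
#' @export
extract_path <- function(mask, seeds, snap_radius = 2.0, prune_len = 5L,
                         smooth_window = 5L,
                         resample_step = max(mask$spacing),
                         project = FALSE) {
  stopifnot(inherits(mask, "canal_mask"), inherits(seeds, "seed_pair"))
  stopifnot_scalar_number(snap_radius, "snap_radius", positive = TRUE)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    abort_cochlear("smooth_window must be a positive odd integer",
                   "cochleaR_invalid_argument")

  skel <- skeletonize(mask)
  sg <- skeleton_graph(skel)
  g <- sg$graph
  world <- voxel_to_world(mask, sg$coords0)

  drop <- prune_spur_vertices(g, prune_len)
  if (length(drop)) {
    keep <- setdiff(seq_len(igraph::vcount(g)), drop)
    g <- igraph::induced_subgraph(g, keep)
    world <- world[keep, , drop = FALSE]
  }

  snap <- function(p, what) {
    d2 <- colSums((t(world) - p)^2)
    i <- which.min(d2)
    if (sqrt(d2[i]) > snap_radius)
      abort_cochlear(sprintf("%s seed is %.2f mm from the skeleton (snap radius %.2f mm)",
                             what, sqrt(d2[i]), snap_radius),
                     "cochleaR_seed_error")
    i
  }
  v <- snap(seeds$vestibule_point, "vestibule")
  a <- snap(seeds$apex_point, "apex")

  comp <- igraph::components(g)$membership
  if (comp[v] != comp[a])
    abort_cochlear("vestibule and apex seeds lie in disconnected canal components",
                   "cochleaR_connectivity_error")

  sp <- igraph::shortest_paths(g, from = v, to = a, weights = igraph::E(g)$weight,
                               output = "vpath")
  path <- as.integer(sp$vpath[[1]])
  pts <- world[path, , drop = FALSE]
  if (nrow(pts) < 2L)
    abort_cochlear("degenerate skeleton path (seeds snap to the same voxel)",
                   "cochleaR_seed_error")

  pts <- smooth_polyline(pts, smooth_window)
  crv <- centerline_curve(pts)
  if (resample_step > 0) crv <- resample_curve(crv, resample_step)
  if (project) crv <- project_curve(crv)
  crv
}

# centered moving average per coordinate; the (w-1)/2 points at each end are
# kept as-is so the path endpoints are preserved exactly
smooth_polyline <- function(pts, w) {
  if (w <= 1L || nrow(pts) < w) return(dedupe_points(pts))
  half <- (w - 1L) %/% 2L
  sm <- apply(pts, 2L, function(col) {
    f <- stats::filter(col, rep(1 / w, w), sides = 2)
    f[seq_len(half)] <- col[seq_len(half)]
    n <- length(col)
    f[(n - half + 1L):n] <- col[(n - half + 1L):n]
    as.numeric(f)
  })
  dedupe_points(sm)
}

dedupe_points <- function(pts) {
  keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 0)
  pts[keep, , drop = FALSE]
}
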