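#' Displacement field sampled at 3D points
#'
#' Container for a matrix displacement field measured at scattered 3D
#' positions (typically fiducial beads in the hydrogel), in micrometres.
#'
#' @param points numeric n x 3 matrix of positions (um).
#' @param vectors numeric n x 3 matrix of displacement vectors (um).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(points, vectors) {
  points <- as.matrix(points)
  vectors <- as.matrix(vectors)
  stopifnot(ncol(points) == 3, ncol(vectors) == 3,
            nrow(points) == nrow(vectors))
  if (!all(is.finite(points)) || !all(is.finite(vectors)))
    stop("displacement field must be finite")
  structure(list(points = points, vectors = vectors),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("<displacement_field> %d points, |u| in [%.3g, %.3g] um\n",
              nrow(x$points), min(mag), max(mag)))
  invisible(x)
}

#' Skeletonize a 3D sprout mask
#'
#' Reduces a binary sprout volume to a 1-voxel-wide medial curve by
#' sequential thinning (simple-point deletion ordered by distance to the
#' background, preserving curve endpoints), then prunes spurious side
#' branches shorter than `prune_um`.
#'
#' @param mask 3D logical (or 0/1) array; must contain exactly one
#'   26-connected foreground component.
#' @param voxel_size numeric length-3, micrometres per voxel along each
#'   array axis (the confocal z-step is typically coarser than x/y).
#' @param prune_um branches whose geodesic length from their endpoint to
#'   the nearest junction is below this are removed (default 5 um).
#' @return Object of class `sprout_skeleton`: voxel indices, volume
#'   dimensions and voxel size.
#' @export
skeletonize_sprout <- function(mask, voxel_size = c(1, 1, 1), prune_um = 5) {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3, length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  if (!any(mask)) stop("mask is empty")
  if (.label3d(mask)$n != 1L) stop("mask must have exactly one connected component")
  vox <- .thin3d(mask, voxel_size)
  vox <- .prune_branches(vox, voxel_size, prune_um)
  structure(list(voxels = vox, dim = dim(mask), voxel_size = voxel_size),
            class = "sprout_skeleton")
}

.prune_branches <- function(voxels, voxel_size, prune_um) {
  for (pass in 1:3) {
    if (nrow(voxels) < 3) break
    g <- .skeleton_graph(voxels, voxel_size)
    deg <- igraph::degree(g)
    junctions <- which(deg >= 3)
    tips <- which(deg == 1)
    if (!length(junctions) || !length(tips)) break
    d <- igraph::distances(g, v = tips, to = junctions)
    drop <- integer(0)
    for (i in seq_along(tips)) {
      j <- which.min(d[i, ])
      if (d[i, j] < prune_um) {
        p <- igraph::shortest_paths(g, from = tips[i], to = junctions[j])$vpath[[1]]
        drop <- c(drop, as.integer(p)[-length(p)]) # keep the junction
      }
    }
    if (!length(drop)) break
    voxels <- voxels[-unique(drop), , drop = FALSE]
  }
  voxels
}

#' @export
print.sprout_skeleton <- function(x, ...) {
  cat(sprintf("<sprout_skeleton> %d voxels in a %s volume\n",
              nrow(x$voxels), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Select base and tip of a sprout skeleton
#'
#' Automated stand-in for manual endpoint picking: the base is the
#' skeleton endpoint nearest `reference_point` (e.g. the spheroid or
#' carrier-bead centre) and the tip is the endpoint at maximal geodesic
#' distance from the base. Explicit `base`/`tip` points (um) override
#' the automation and are snapped to the nearest skeleton voxel.
#'
#' @param skeleton a `sprout_skeleton`.
#' @param reference_point length-3 position in um (required unless both
#'   manual points are given).
#' @param base,tip optional manual points in um.
#' @return list with `base` and `tip` vertex indices (rows of
#'   `skeleton$voxels`) and their physical positions `base_um`, `tip_um`.
#' @export
select_endpoints <- function(skeleton, reference_point = NULL,
                             base = NULL, tip = NULL) {
  stopifnot(inherits(skeleton, "sprout_skeleton"))
  coords <- .voxel_um(skeleton$voxels, skeleton$voxel_size)
  snap <- function(p) .nn_search(matrix(p, 1), coords)$index
  if (!is.null(base) && !is.null(tip)) {
    bi <- snap(base); ti <- snap(tip)
  } else {
    g <- .skeleton_graph(skeleton$voxels, skeleton$voxel_size)
    ends <- which(igraph::degree(g) <= 1)
    if (!length(ends)) stop("skeleton has no endpoints (cyclic skeleton)")
    if (is.null(reference_point))
      stop("reference_point is required for automated endpoint selection")
    d_ref <- sqrt(colSums((t(coords[ends, , drop = FALSE]) -
                             as.numeric(reference_point))^2))
    bi <- ends[which.min(d_ref)]
    gd <- igraph::distances(g, v = bi, to = ends)
    ti <- ends[which.max(gd)]
  }
  list(base = bi, tip = ti,
       base_um = coords[bi, ], tip_um = coords[ti, ])
}

#' Geodesic path along a skeleton
#'
#' Shortest path between two skeleton voxels along the 26-connected
#' skeleton, with steps weighted by their physical (possibly
#' anisotropic) length.
#'
#' @param skeleton a `sprout_skeleton`.
#' @param base,tip vertex indices (as returned by [select_endpoints()])
#'   or length-3 points in um (snapped to the nearest skeleton voxel).
#' @return Object of class `sprout_path`: ordered n x 3 matrix of
#'   physical coordinates (um) base to tip, with attribute `arc_length`.
#' @export
geodesic_path <- function(skeleton, base, tip) {
  stopifnot(inherits(skeleton, "sprout_skeleton"))
  coords <- .voxel_um(skeleton$voxels, skeleton$voxel_size)
  as_vertex <- function(p) {
    if (length(p) == 1) as.integer(p) else .nn_search(matrix(p, 1), coords)$index
  }
  bi <- as_vertex(base); ti <- as_vertex(tip)
  g <- .skeleton_graph(skeleton$voxels, skeleton$voxel_size)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = bi, to = ti, output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0 || vp[length(vp)] != ti)
    stop("base and tip are not connected on the skeleton")
  path <- coords[vp, , drop = FALSE]
  steps <- if (nrow(path) > 1) sqrt(rowSums(diff(path)^2)) else numeric(0)
  structure(path, class = "sprout_path", arc_length = sum(steps))
}

#' Principal growth direction of a sprout path
#'
#' First principal axis of the mean-centred path coordinates, oriented
#' so that it points from base to tip (positive dot product with
#' tip - base).
#'
#' @param path a `sprout_path` (or n x 3 matrix ordered base to tip).
#' @return unit length-3 vector.
#' @export
growth_direction <- function(path) {
  p <- unclass(path)
  stopifnot(is.matrix(p), ncol(p) == 3)
  if (nrow(p) < 3) stop("path needs at least 3 points")
  if (all(apply(p, 2, function(v) diff(range(v))) < 1e-12))
    stop("degenerate path: no spatial extent")
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  g <- pc$rotation[, 1]
  chord <- p[nrow(p), ] - p[1, ]
  if (sum(g * chord) < 0) g <- -g
  g / sqrt(sum(g^2))
}

#' Near-surface shell of field points around a sprout
#'
#' Field points lying outside the mask whose Euclidean distance to the
#' mask surface falls within `[d_min, d_max]` micrometres. Surface
#' distance is measured to the centres of the boundary voxels of the
#' mask; a point whose containing voxel belongs to the mask is inside
#' and excluded.
#'
#' @param mask 3D logical array.
#' @param field a `displacement_field`.
#' @param voxel_size micrometres per voxel (length 3).
#' @param d_min,d_max distance band in um (defaults 0-5, the band used
#'   for near-sprout displacement averages).
#' @return list with `index` (rows of the field), `dist` (um),
#'   `points`, `vectors` of the selected subset.
#' @export
surface_shell <- function(mask, field, voxel_size = c(1, 1, 1),
                          d_min = 0, d_max = 5) {
  stopifnot(inherits(field, "displacement_field"), d_max > d_min, d_min >= 0)
  mask <- array(as.logical(mask), dim(mask))
  surf <- which(.surface_voxels(mask))
  if (!length(surf)) stop("mask has no surface voxels")
  surf_um <- .voxel_um(arrayInd(surf, dim(mask)), voxel_size)
  vox <- round(sweep(field$points, 2, voxel_size, "/")) + 1
  inside <- rep(FALSE, nrow(vox))
  ok <- vox[, 1] >= 1 & vox[, 1] <= dim(mask)[1] &
    vox[, 2] >= 1 & vox[, 2] <= dim(mask)[2] &
    vox[, 3] >= 1 & vox[, 3] <= dim(mask)[3]
  inside[ok] <- mask[cbind(vox[ok, 1], vox[ok, 2], vox[ok, 3])]
  nn <- .nn_search(field$points, surf_um, cell = max(voxel_size) * 2,
                   max_dist = d_max)
  sel <- which(!inside & nn$dist >= d_min & nn$dist <= d_max)
  if (!length(sel))
    stop("no field points in the surface shell; widen the distance band")
  list(index = sel, dist = nn$dist[sel],
       points = field$points[sel, , drop = FALSE],
       vectors = field$vectors[sel, , drop = FALSE])
}

#' Mean near-surface displacement magnitude
#'
#' Arithmetic mean of the displacement magnitudes over the points of a
#' surface shell, the scalar summary used to compare overall pulling
#' around sprouts.
#'
#' @param field a `displacement_field`.
#' @param shell result of [surface_shell()].
#' @return mean |u| in um.
#' @export
mean_shell_displacement <- function(field, shell) {
  stopifnot(length(shell$index) > 0)
  mean(sqrt(rowSums(field$vectors[shell$index, , drop = FALSE]^2)))
}

#' Sprout geometry: skeleton, endpoints, geodesic path, growth direction
#'
#' Convenience builder running [skeletonize_sprout()],
#' [select_endpoints()], [geodesic_path()] and [growth_direction()].
#'
#' @inheritParams skeletonize_sprout
#' @inheritParams select_endpoints
#' @return Object of class `sprout_geometry` with fields `mask`,
#'   `voxel_size`, `skeleton`, `path`, `base_um`, `tip_um`,
#'   `growth_dir`.
#' @export
sprout_geometry <- function(mask, voxel_size = c(1, 1, 1),
                            reference_point = NULL, base = NULL, tip = NULL,
                            prune_um = 5) {
  skel <- skeletonize_sprout(mask, voxel_size, prune_um)
  ep <- select_endpoints(skel, reference_point, base, tip)
  path <- geodesic_path(skel, ep$base, ep$tip)
  structure(list(mask = array(as.logical(mask), dim(mask)),
                 voxel_size = voxel_size, skeleton = skel, path = path,
                 base_um = ep$base_um, tip_um = ep$tip_um,
                 growth_dir = growth_direction(path)),
            class = "sprout_geometry")
}

#' @export
print.sprout_geometry <- function(x, ...) {
  cat(sprintf("<sprout_geometry> path length %.1f um, growth direction (%.2f, %.2f, %.2f)\n",
              attr(x$path, "arc_length"), x$growth_dir[1], x$growth_dir[2],
              x$growth_dir[3]))
  invisible(x)
}

# Arc-length stations (um from base) and their interpolated positions.
.path_stations <- function(path, step) {
  p <- unclass(path)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  st <- seq(0, L, by = step)
  if (L - st[length(st)] > 1e-9) st <- c(st, L)
  pos <- sapply(1:3, function(k) stats::approx(s, p[, k], xout = st)$y)
  list(arc = st, pos = matrix(pos, ncol = 3), length = L)
}

#' Signed displacement line scan along a sprout
#'
#' Walks the geodesic path in `step`-micrometre arc-length stations from
#' base to tip. Each near-surface field point (shell band `band` um) is
#' assigned to its nearest station; the displacement vectors at each
#' station are averaged and reduced to a signed magnitude
#' `s = |u_mean| * sign(u_mean . g)` where `g` is the base-to-tip growth
#' direction. Negative values therefore mean the matrix is displaced
#' back towards the sprout origin. Stations with no points are reported
#' as missing (`NA`), not as zero.
#'
#' @param field a `displacement_field`.
#' @param geometry a `sprout_geometry`.
#' @param step station spacing in um (default 1).
#' @param band shell half-width in um (default 5).
#' @return Object of class `displacement_profile`: data.frame with
#'   columns `arc_length_um`, `lambda` (0 at base, 1 at tip),
#'   `signed_disp_um`, `n_points`.
#' @export
signed_profile <- function(field, geometry, step = 1, band = 5) {
  stopifnot(inherits(geometry, "sprout_geometry"), step > 0)
  st <- .path_stations(geometry$path, step)
  shell <- surface_shell(geometry$mask, field, geometry$voxel_size, 0, band)
  assign <- .nn_search(shell$points, st$pos)$index
  g <- geometry$growth_dir
  n <- length(st$arc)
  s_val <- rep(NA_real_, n)
  n_pts <- integer(n)
  for (i in seq_len(n)) {
    sel <- assign == i
    n_pts[i] <- sum(sel)
    if (n_pts[i] > 0) {
      u <- colMeans(shell$vectors[sel, , drop = FALSE])
      mag <- sqrt(sum(u^2))
      s_val[i] <- mag * ifelse(sum(u * g) < 0, -1, 1)
    }
  }
  out <- data.frame(arc_length_um = st$arc,
                    lambda = if (st$length > 0) st$arc / st$length else st$arc,
                    signed_disp_um = s_val, n_points = n_pts)
  structure(out, class = c("displacement_profile", "data.frame"),
            growth_dir = g, path_length = st$length)
}

#' Average signed profiles on a normalized axis
#'
#' Each profile's arc length is normalized to 0 (base) - 1 (tip) so
#' sprouts of different length are comparable; missing stations are
#' linearly interpolated, each profile is resampled onto a common
#' `lambda` grid, and the pointwise mean and standard deviation are
#' returned.
#'
#' @param profiles list of `displacement_profile` objects.
#' @param n_out number of grid points (default 51).
#' @return data.frame with `lambda`, `mean_disp_um`, `sd_disp_um`, `n`.
#' @export
normalize_and_average <- function(profiles, n_out = 51) {
  stopifnot(length(profiles) >= 1)
  grid <- seq(0, 1, length.out = n_out)
  cols <- list()
  for (p in profiles) {
    ok <- !is.na(p$signed_disp_um)
    if (sum(ok) < 2) {
      warning("profile with fewer than 2 populated stations excluded")
      next
    }
    cols[[length(cols) + 1]] <-
      stats::approx(p$lambda[ok], p$signed_disp_um[ok], xout = grid,
                    rule = 2)$y
  }
  if (!length(cols)) stop("no usable profiles")
  m <- do.call(cbind, cols)
  data.frame(lambda = grid,
             mean_disp_um = rowMeans(m),
             sd_disp_um = apply(m, 1, stats::sd),
             n = ncol(m))
}

#' Maximum near-surface displacement of a sprout
#'
#' Largest displacement magnitude among the field points within `band`
#' micrometres of the sprout surface (the per-sprout summary plotted
#' alongside the averaged line scans).
#'
#' @inheritParams signed_profile
#' @return max |u| in um.
#' @export
max_displacement <- function(field, geometry, band = 5) {
  shell <- surface_shell(geometry$mask, field, geometry$voxel_size, 0, band)
  max(sqrt(rowSums(shell$vectors^2)))
}

#' Match fiducial beads between stressed and relaxed states
#'
#' Mutual-nearest-neighbour pairing of bead positions imaged in the
#' stressed state and after cytoskeletal relaxation; the displacement at
#' each matched bead is stressed minus relaxed. Beads without a mutual
#' match within `max_match_um` are dropped (count reported via
#' `message()`).
#'
#' @param stressed,relaxed n x 3 matrices of bead positions (um).
#' @param max_match_um maximum pairing distance in um.
#' @return a `displacement_field` at the matched stressed positions.
#' @export
match_beads <- function(stressed, relaxed, max_match_um = 5) {
  stressed <- as.matrix(stressed)
  relaxed <- as.matrix(relaxed)
  stopifnot(nrow(stressed) > 0, nrow(relaxed) > 0)
  sr <- .nn_search(stressed, relaxed, max_dist = max_match_um)
  rs <- .nn_search(relaxed, stressed, max_dist = max_match_um)
  mutual <- which(!is.na(sr$index) &
                    rs$index[ifelse(is.na(sr$index), 1L, sr$index)] ==
                      seq_len(nrow(stressed)) &
                    sr$dist <= max_match_um)
  if (!length(mutual)) stop("no bead pairs matched within max_match_um")
  dropped <- (nrow(stressed) - length(mutual)) + (nrow(relaxed) - length(mutual))
  if (dropped > 0)
    message(sprintf("match_beads: %d unmatched bead(s) dropped", dropped))
  out <- displacement_field(points = stressed[mutual, , drop = FALSE],
                            vectors = stressed[mutual, , drop = FALSE] -
                              relaxed[sr$index[mutual], , drop = FALSE])
  attr(out, "stressed_index") <- mutual
  attr(out, "relaxed_index") <- sr$index[mutual]
  out
}
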