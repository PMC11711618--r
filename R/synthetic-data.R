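# Seeded generators with programmed ground truth. Each generator draws
# from its own seeded stream and restores the caller's RNG state, so a
# fixed seed gives bit-identical output regardless of surrounding code.

#' Synthetic spheroid sprouting time-lapse
#'
#' Renders a circular spheroid body with radially growing sprouts as a
#' brightfield-like time-lapse. The spheroid interior carries
#' multiplicative speckle (grain ~2 px, heterogeneous intensity) while
#' the background varies smoothly, so a local standard-deviation filter
#' separates the two -- the premise of the segmentation pipeline. The
#' exact generating masks and analytic kinetics are returned alongside
#' the rendered frames.
#'
#' Sprout `k` at frame `t` (0-based) is a rectangle of the programmed
#' width extending `growth_rate_px_per_frame * t` pixels beyond the
#' spheroid surface, so the programmed tip-cell distance at frame `t` is
#' `growth_rate_px_per_frame * t * pixel_size` and the programmed
#' invasion area is the pixel count the rasterized sprouts add.
#'
#' @param radius_px spheroid radius in pixels (> 0).
#' @param sprout_specs list of `c(angle_rad, width_px)` pairs; widths
#'   below 2 px are rejected as unsegmentable.
#' @param growth_rate_px_per_frame sprout elongation per frame (px).
#' @param n_frames number of frames (>= 1).
#' @param noise_level sd of additive Gaussian camera noise (image units,
#'   frames are ~0-1).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval_h hours between frames (default 6).
#' @param seed integer seed.
#' @return Object of class `spheroid_scene`: `stack` (a
#'   [timelapse_stack()]), `true_masks`, `true_tc_distance` (um),
#'   `true_invasion_area` (um^2), `pixel_size`, `seed`.
#' @export
make_spheroid_timelapse <- function(radius_px = 70,
                                    sprout_specs = list(c(0.4, 6),
                                                        c(2.5, 7),
                                                        c(4.6, 6)),
                                    growth_rate_px_per_frame = 2,
                                    n_frames = 10,
                                    noise_level = 0.05,
                                    pixel_size = 0.65,
                                    frame_interval_h = 6,
                                    seed = 1) {
  stopifnot(radius_px > 0, n_frames >= 1, growth_rate_px_per_frame >= 0,
            noise_level >= 0, pixel_size > 0)
  specs <- lapply(sprout_specs, function(s) {
    stopifnot(length(s) == 2)
    if (s[2] < 2) stop("sprout width < 2 px is unsegmentable")
    s
  })
  max_len <- growth_rate_px_per_frame * (n_frames - 1)
  half <- ceiling(radius_px + max_len) + 24
  n <- 2L * half
  ctr <- half + 0.5
  xs <- matrix(seq_len(n) - ctr, n, n)
  ys <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  rr <- sqrt(xs^2 + ys^2)
  body <- rr <= radius_px

  mask_at <- function(t) {
    m <- body
    L <- growth_rate_px_per_frame * t
    if (L > 0) {
      for (s in specs) {
        a <- s[1]; w <- s[2]
        along <- xs * cos(a) + ys * sin(a)
        perp <- -xs * sin(a) + ys * cos(a)
        m <- m | (along >= 0 & along <= radius_px + L & abs(perp) <= w / 2)
      }
    }
    m
  }

  .with_seed(seed, {
    # speckle texture, grain 2 px, multiplicative around a 0.5 base level
    cg <- ceiling(n / 2)
    coarse <- matrix(stats::runif(cg * cg, 0.35, 1.65), cg, cg)
    speckle <- coarse[rep(seq_len(cg), each = 2)[seq_len(n)],
                      rep(seq_len(cg), each = 2)[seq_len(n)]]
    bgr <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = 6)
    bgr <- 0.5 + 0.04 * bgr / stats::sd(bgr)

    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    for (t in seq_len(n_frames) - 1L) {
      m <- mask_at(t)
      img <- bgr
      img[m] <- 0.5 * speckle[m]
      if (noise_level > 0)
        img <- img + matrix(stats::rnorm(n * n, 0, noise_level), n, n)
      frames[[t + 1L]] <- pmin(pmax(img, 0), 1)
      masks[[t + 1L]] <- m
    }
    area0 <- sum(masks[[1]])
    true_area <- vapply(masks, function(m) (sum(m) - area0) * pixel_size^2,
                        numeric(1))
    true_tc <- if (length(specs)) {
      growth_rate_px_per_frame * (seq_len(n_frames) - 1) * pixel_size
    } else {
      rep(0, n_frames)
    }
    structure(list(stack = timelapse_stack(frames, pixel_size,
                                           frame_interval_h),
                   true_masks = masks,
                   true_tc_distance = true_tc,
                   true_invasion_area = true_area,
                   pixel_size = pixel_size,
                   seed = seed),
              class = "spheroid_scene")
  })
}

#' @export
print.spheroid_scene <- function(x, ...) {
  cat(sprintf("<spheroid_scene> %d frames of %s px, final TC distance %.1f um\n",
              length(x$true_masks),
              paste(dim(x$true_masks[[1]]), collapse = "x"),
              x$true_tc_distance[length(x$true_tc_distance)]))
  invisible(x)
}

#' Synthetic contractile sprout phantom with fiducial beads
#'
#' Builds a capsule-shaped sprout mask (cylinder with hemispherical
#' caps) along a given axis inside a gel volume, a displacement field
#' that pulls the matrix towards the sprout base and decays
#' exponentially with distance from the tip cap, and uniformly scattered
#' fiducial beads outside the sprout. The "relaxed" bead set is the
#' stressed set minus the field sampled at the bead positions, the
#' configuration a cytoskeleton-relaxing treatment would reveal.
#'
#' The field is `u(x) = -peak * exp(-d_tip(x) / decay) * g` with `g` the
#' unit base-to-tip axis and `d_tip(x)` the distance to the surface of
#' the tip cap, so `|u| = peak` exactly at the tip surface and `u . g < 0`
#' everywhere (matrix pulled towards the origin of the sprout).
#'
#' @param length_um sprout length (> 2 * radius_um).
#' @param radius_um sprout radius.
#' @param axis growth axis (any length-3 vector, normalized internally).
#' @param peak_magnitude_um displacement magnitude at the tip surface.
#' @param decay_length_um exponential decay length of the field.
#' @param n_beads number of fiducial beads.
#' @param voxel_size um per voxel, length 3, all > 0.
#' @param margin_um gel margin around the sprout (default 12).
#' @param seed integer seed.
#' @return Object of class `sprout_phantom`.
#' @export
make_sprout_phantom <- function(length_um = 40, radius_um = 5,
                                axis = c(1, 0, 0), peak_magnitude_um = 2,
                                decay_length_um = 10, n_beads = 2000,
                                voxel_size = c(1, 1, 1), margin_um = 12,
                                seed = 1) {
  stopifnot(length_um > 2 * radius_um, peak_magnitude_um >= 0,
            decay_length_um > 0, n_beads >= 0)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  g <- axis / sqrt(sum(axis^2))
  base <- margin_um + radius_um + pmax(0, -length_um * g)
  tip <- base + length_um * g
  hi <- pmax(base, tip) + radius_um + margin_um
  dm <- as.integer(ceiling(hi / voxel_size)) + 1L

  # capsule: distance to the segment between the two cap centres
  c1 <- base + radius_um * g
  c2 <- base + (length_um - radius_um) * g
  capsule_dist <- function(p) {
    rel <- sweep(p, 2, c1)
    t <- pmin(pmax(rel %*% g, 0), length_um - 2 * radius_um)
    sqrt(rowSums((rel - t %*% t(g))^2))
  }
  grid <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                z = seq_len(dm[3])))
  gum <- .voxel_um(grid, voxel_size)
  mask <- array(capsule_dist(gum) <= radius_um, dm)

  field_at <- function(p) {
    d_tip <- pmax(sqrt(rowSums(sweep(p, 2, c2)^2)) - radius_um, 0)
    (-peak_magnitude_um * exp(-d_tip / decay_length_um)) %*% t(g)
  }

  .with_seed(seed, {
    beads <- matrix(numeric(0), 0, 3)
    while (nrow(beads) < n_beads) {
      cand <- cbind(stats::runif(n_beads, 0, hi[1]),
                    stats::runif(n_beads, 0, hi[2]),
                    stats::runif(n_beads, 0, hi[3]))
      cand <- cand[capsule_dist(cand) > radius_um, , drop = FALSE]
      beads <- rbind(beads, cand)
    }
    beads <- beads[seq_len(n_beads), , drop = FALSE]
    u <- field_at(beads)
    structure(list(mask = mask, voxel_size = voxel_size,
                   true_axis = g, true_base = base, true_tip = tip,
                   field = displacement_field(beads, u),
                   bead_positions_stressed = beads,
                   bead_positions_relaxed = beads - u,
                   peak_magnitude = peak_magnitude_um,
                   decay_length = decay_length_um,
                   seed = seed),
              class = "sprout_phantom")
  })
}

#' @export
print.sprout_phantom <- function(x, ...) {
  cat(sprintf("<sprout_phantom> %s voxels, %d beads, peak %.2f um\n",
              paste(dim(x$mask), collapse = "x"),
              nrow(x$bead_positions_stressed), x$peak_magnitude))
  invisible(x)
}

#' Parameters for synthetic Brownian-with-drift tracks
#'
#' @param n_tracks,n_frames counts (`n_frames >= 2`).
#' @param drift length-2 `(vx, vy)` in px/frame.
#' @param diffusion diffusion coefficient D in px^2/frame (>= 0).
#' @param frame_interval frames between consecutive points (default 1).
#' @param seed integer seed.
#' @return Object of class `track_params`.
#' @export
track_params <- function(n_tracks, n_frames, drift = c(0, 0), diffusion = 0,
                         frame_interval = 1, seed = 1) {
  stopifnot(n_tracks >= 1, n_frames >= 2, length(drift) == 2,
            diffusion >= 0, frame_interval >= 1)
  structure(list(n_tracks = as.integer(n_tracks),
                 n_frames = as.integer(n_frames),
                 drift = as.numeric(drift), diffusion = diffusion,
                 frame_interval = as.integer(frame_interval),
                 seed = as.integer(seed)),
            class = "track_params")
}

#' Simulate Brownian-with-drift cell tracks
#'
#' Each step adds the drift plus independent Gaussian noise of variance
#' `2 * D` per axis, so the ensemble mean-square displacement is
#' `4 * D * t`: the convention under which the diffusivity estimator of
#' the migration module is consistent by construction.
#'
#' @param params a [track_params()] object.
#' @return a `track_set` (see [track_set()]); the generating parameters
#'   are stored in `attr(, "truth")`.
#' @export
make_tracks <- function(params) {
  stopifnot(inherits(params, "track_params"))
  p <- params
  .with_seed(p$seed, {
    n_steps <- p$n_frames - 1L
    sd_step <- sqrt(2 * p$diffusion)
    coords <- lapply(1:2, function(ax) {
      steps <- matrix(stats::rnorm(p$n_tracks * n_steps, p$drift[ax], sd_step),
                      p$n_tracks, n_steps)
      x0 <- stats::runif(p$n_tracks, 0, 100)
      cbind(x0, x0 + t(apply(steps, 1, cumsum)))
    })
    frames <- (seq_len(p$n_frames) - 1L) * p$frame_interval
    df <- data.frame(
      track_id = rep(seq_len(p$n_tracks), each = p$n_frames),
      frame = rep(frames, times = p$n_tracks),
      x = as.vector(t(coords[[1]])),
      y = as.vector(t(coords[[2]])))
    ts <- track_set(df)
    attr(ts, "truth") <- list(drift = p$drift, diffusion = p$diffusion)
    ts
  })
}

#' Convex cell body with spike-like protrusions
#'
#' Rasterizes an ellipse or disk and adds thin radial spikes at seeded
#' random angles, emulating a protrusive cell versus the smooth
#' "bullet-like" morphology of a protrusion-free one. Solidity strictly
#' decreases as spikes are added or lengthened, since spikes extend the
#' convex hull while adding little mask area.
#'
#' @param base_shape `"ellipse"` or `"disk"`.
#' @param semi_axes semi-axes in px (length 2 for ellipse, scalar radius
#'   for disk); both must be >= 20 px.
#' @param n_spikes number of spikes (>= 0).
#' @param spike_length_px spike length beyond the body surface.
#' @param spike_width_px spike thickness (default 2).
#' @param size optional canvas side; when given, spikes reaching beyond
#'   the canvas margin are rejected.
#' @param seed integer seed.
#' @return logical matrix mask.
#' @export
make_spiky_mask <- function(base_shape = c("ellipse", "disk"),
                            semi_axes = c(50, 30), n_spikes = 0,
                            spike_length_px = 20, spike_width_px = 2,
                            size = NULL, seed = 1) {
  base_shape <- match.arg(base_shape)
  if (base_shape == "disk") semi_axes <- rep(semi_axes[1], 2)
  stopifnot(length(semi_axes) == 2, n_spikes >= 0, spike_length_px >= 0)
  if (min(semi_axes) < 20) stop("base shape axes must be >= 20 px")
  need_half <- max(semi_axes) + (if (n_spikes > 0) spike_length_px else 0) + 3
  if (is.null(size)) {
    size <- 2L * ceiling(need_half)
  } else if (size / 2 < need_half) {
    stop("spikes longer than the image margin")
  }
  ctr <- (size + 1) / 2
  xs <- matrix(seq_len(size) - ctr, size, size)
  ys <- matrix(seq_len(size) - ctr, size, size, byrow = TRUE)
  mask <- (xs / semi_axes[1])^2 + (ys / semi_axes[2])^2 <= 1
  if (n_spikes > 0) {
    .with_seed(seed, {
      angles <- stats::runif(n_spikes, 0, 2 * pi)
      for (a in angles) {
        # ellipse boundary radius along direction a
        rb <- 1 / sqrt((cos(a) / semi_axes[1])^2 + (sin(a) / semi_axes[2])^2)
        p0 <- 0.9 * rb * c(cos(a), sin(a))
        p1 <- (rb + spike_length_px) * c(cos(a), sin(a))
        seg <- p1 - p0
        len2 <- sum(seg^2)
        t <- pmin(pmax(((xs - p0[1]) * seg[1] + (ys - p0[2]) * seg[2]) / len2,
                       0), 1)
        d2 <- (xs - p0[1] - t * seg[1])^2 + (ys - p0[2] - t * seg[2])^2
        mask <- mask | (d2 <= (spike_width_px / 2)^2)
      }
    })
  }
  mask
}

#' Two-compartment intensity image with an exact membrane fraction
#'
#' Given a cell mask, splits it into a peripheral membrane band (the
#' mask minus its erosion by `membrane_width_px`) and an interior, and
#' assigns constant intensities so that the membrane band holds exactly
#' `membrane_fraction` of the total intensity. Ground truth for the
#' membrane/whole-cell intensity-ratio readout.
#'
#' @param cell_mask logical matrix with one cell.
#' @param membrane_width_px band width in px.
#' @param membrane_fraction fraction of total intensity in the band,
#'   in `[0, 1]`.
#' @return list with `image`, `membrane_mask`, `cell_mask`.
#' @export
make_two_compartment_image <- function(cell_mask, membrane_width_px = 3,
                                       membrane_fraction = 0.5) {
  cell_mask <- cell_mask > 0
  stopifnot(membrane_fraction >= 0, membrane_fraction <= 1,
            membrane_width_px >= 1)
  if (!any(cell_mask)) stop("cell mask is empty")
  brush <- EBImage::makeBrush(2 * membrane_width_px + 1, shape = "disc")
  interior <- EBImage::erode(cell_mask + 0, brush) > 0
  membrane <- cell_mask & !interior
  if (!any(membrane)) stop("membrane band is empty")
  n_m <- sum(membrane)
  n_i <- sum(cell_mask) - n_m
  if (n_i == 0 && membrane_fraction < 1)
    stop("membrane band covers the whole cell; cannot place interior intensity")
  img <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  img[membrane] <- membrane_fraction / n_m
  if (n_i > 0) img[cell_mask & !membrane] <- (1 - membrane_fraction) / n_i
  list(image = img, membrane_mask = membrane, cell_mask = cell_mask)
}
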