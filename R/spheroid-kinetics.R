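#' Time-lapse stack of grayscale frames
#'
#' @param frames list of 2D numeric matrices, all of the same shape.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval hours between frames.
#' @return Object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, pixel_size, frame_interval = 6) {
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0,
            frame_interval > 0)
  dm <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f)) stop("frames must be 2D grayscale matrices")
    if (!identical(dim(f), dm)) stop("all frames must have the same shape")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  cat(sprintf("<timelapse_stack> %d frames of %s px, %.3g um/px, %g h/frame\n",
              length(x$frames), paste(dim(x$frames[[1]]), collapse = "x"),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Segment a spheroid (body plus sprouts) from a brightfield frame
#'
#' The spheroid presents heterogeneous intensity variations while the
#' background changes smoothly, so a local standard-deviation filter
#' enhances the structure. Pipeline: std filter (window
#' `std_window_px`) -> Otsu threshold -> morphological closing (disc
#' radius `morph_radius_px`) -> hole filling -> largest connected
#' component.
#'
#' @param frame 2D numeric matrix.
#' @param std_window_px odd window of the std filter (default 9).
#' @param morph_radius_px closing radius in px (default 3).
#' @return logical mask.
#' @export
segment_spheroid <- function(frame, std_window_px = 9, morph_radius_px = 3) {
  stopifnot(is.matrix(frame), std_window_px >= 3)
  sd_img <- .std_filter(frame, std_window_px)
  rng <- range(sd_img)
  if (diff(rng) < 1e-12) stop("no spheroid detected: flat std-filter response")
  sdn <- (sd_img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sdn), range = c(0, 1))
  mask <- sdn > thr
  if (!any(mask)) stop("no spheroid detected: empty foreground")
  if (morph_radius_px >= 1) {
    brush <- EBImage::makeBrush(2 * morph_radius_px + 1, shape = "disc")
    mask <- EBImage::closing(mask + 0, brush) > 0
  }
  mask <- EBImage::fillHull(mask + 0) > 0
  lab <- EBImage::bwlabel(mask + 0)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  matrix(mask, nrow(frame), ncol(frame))
}

# Local standard deviation via box means of x and x^2.
.std_filter <- function(x, window) {
  k <- matrix(1 / window^2, window, window)
  m1 <- EBImage::filter2(x, k, boundary = "replicate")
  m2 <- EBImage::filter2(x^2, k, boundary = "replicate")
  sqrt(pmax(m2 - m1^2, 0))
}

# Outline of a 2D mask: mask minus its erosion (3x3 cross).
.outline2d <- function(mask) {
  er <- EBImage::erode(mask + 0, EBImage::makeBrush(3, shape = "diamond")) > 0
  mask & !er
}

# Distance-to-initial-outline map in pixels, with interior clipping:
# pixels inside the t=0 body are set to 0, so the maximum measures
# outgrowth beyond the original surface rather than the body radius.
.tc_distance_map <- function(mask_0) {
  if (!any(mask_0)) stop("mask_0 is empty")
  dt <- .edt(.outline2d(mask_0))
  dt[mask_0] <- 0
  dt
}

#' Tip-cell distance of a spheroid mask
#'
#' Maximum of the Euclidean distance transform of the first-timepoint
#' spheroid outline, evaluated over the current mask and scaled to
#' micrometres. Distances of pixels inside the initial body are clipped
#' to zero, so the value measures how far the leading tip cell has
#' migrated beyond the original spheroid surface (and is exactly 0 when
#' nothing has grown out).
#'
#' @param mask_t current binary mask.
#' @param mask_0 first-timepoint binary mask (same shape, nonempty).
#' @param pixel_size micrometres per pixel.
#' @return distance in um.
#' @export
tc_distance <- function(mask_t, mask_0, pixel_size = 1) {
  stopifnot(identical(dim(mask_t), dim(mask_0)))
  if (!any(mask_t)) stop("mask_t is empty")
  dt <- .tc_distance_map(mask_0 > 0)
  max(dt[mask_t > 0]) * pixel_size
}

#' Invasion area of a spheroid mask
#'
#' Area of the current mask minus the area of the first-timepoint mask,
#' in um^2. Negative values (a shrinking spheroid) are reported as-is.
#'
#' @inheritParams tc_distance
#' @return area difference in um^2.
#' @export
invasion_area <- function(mask_t, mask_0, pixel_size = 1) {
  stopifnot(identical(dim(mask_t), dim(mask_0)))
  (sum(mask_t > 0) - sum(mask_0 > 0)) * pixel_size^2
}

#' Kinetics from a mask series
#'
#' Per-frame tip-cell distance and invasion area relative to the first
#' frame.
#'
#' @param masks list of binary masks (same shape).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval hours between frames.
#' @return data.frame `frame`, `time_h`, `tc_distance_um`,
#'   `invasion_area_um2`.
#' @export
kinetics_from_masks <- function(masks, pixel_size = 1, frame_interval = 6) {
  stopifnot(length(masks) >= 1)
  dt <- .tc_distance_map(masks[[1]] > 0)
  a0 <- sum(masks[[1]] > 0)
  n <- length(masks)
  tc <- numeric(n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    m <- masks[[i]] > 0
    if (!any(m)) stop(sprintf("empty mask at frame %d", i))
    tc[i] <- max(dt[m]) * pixel_size
    area[i] <- (sum(m) - a0) * pixel_size^2
  }
  data.frame(frame = seq_len(n) - 1L,
             time_h = (seq_len(n) - 1L) * frame_interval,
             tc_distance_um = tc, invasion_area_um2 = area)
}

#' Sprouting kinetics curves from time-lapse stacks
#'
#' Segments every frame of one or more replicate stacks and computes
#' tip-cell distance and invasion area per frame. With several
#' replicates, the mean curve and its standard-deviation band are
#' returned; `normalize = TRUE` additionally reports the invasion area
#' divided by the maximum of the replicate mean curve.
#'
#' @param stacks a `timelapse_stack` or a list of replicate stacks of
#'   equal length.
#' @param std_window_px,morph_radius_px passed to [segment_spheroid()].
#' @param normalize report `normalized_area` as mean invasion area over
#'   its maximum.
#' @return Object of class `kinetics_series`: list with `per_replicate`
#'   (list of per-frame data.frames), `summary` (mean and sd curves) and
#'   `masks` (per-replicate segmented masks).
#' @export
kinetics_curves <- function(stacks, std_window_px = 9, morph_radius_px = 3,
                            normalize = FALSE) {
  if (inherits(stacks, "timelapse_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1,
            all(vapply(stacks, inherits, logical(1), "timelapse_stack")))
  n_frames <- vapply(stacks, function(s) length(s$frames), integer(1))
  if (length(unique(n_frames)) != 1)
    stop("replicate stacks have different numbers of frames")
  if (n_frames[1] < 2) stop("need at least 2 frames")
  reps <- vector("list", length(stacks))
  all_masks <- vector("list", length(stacks))
  for (r in seq_along(stacks)) {
    st <- stacks[[r]]
    masks <- lapply(st$frames, segment_spheroid, std_window_px = std_window_px,
                    morph_radius_px = morph_radius_px)
    reps[[r]] <- kinetics_from_masks(masks, st$pixel_size, st$frame_interval)
    all_masks[[r]] <- masks
  }
  tc <- sapply(reps, `[[`, "tc_distance_um")
  ar <- sapply(reps, `[[`, "invasion_area_um2")
  tc <- matrix(tc, ncol = length(reps))
  ar <- matrix(ar, ncol = length(reps))
  sd0 <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(0, nrow(m))
  summary <- data.frame(frame = reps[[1]]$frame, time_h = reps[[1]]$time_h,
                        tc_distance_um = rowMeans(tc), tc_sd = sd0(tc),
                        invasion_area_um2 = rowMeans(ar), area_sd = sd0(ar))
  if (normalize) {
    denom <- max(summary$invasion_area_um2)
    summary$normalized_area <- if (denom > 0)
      summary$invasion_area_um2 / denom else summary$invasion_area_um2
  }
  structure(list(per_replicate = reps, summary = summary, masks = all_masks),
            class = "kinetics_series")
}

#' @export
print.kinetics_series <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf(paste0("<kinetics_series> %d replicate(s), %d frames; final TC ",
                     "distance %.1f um, final invasion area %.0f um^2\n"),
              length(x$per_replicate), n, x$summary$tc_distance_um[n],
              x$summary$invasion_area_um2[n]))
  invisible(x)
}

#' Time-coded outline overlay of a mask series
#'
#' Integer label image in which the outline of frame t carries label t
#' (later outlines drawn over earlier ones), the usual visual QC of
#' sprouting progression.
#'
#' @param masks list of binary masks.
#' @return integer matrix; 0 is background.
#' @export
outline_overlay <- function(masks) {
  if (!length(masks)) stop("empty mask series")
  out <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) {
    o <- .outline2d(masks[[i]] > 0)
    out[o] <- i
  }
  out
}

#' Plot kinetics curves
#'
#' Base-graphics plot of the mean tip-cell distance and invasion area
#' with standard-deviation bands.
#'
#' @param x a `kinetics_series`.
#' @param ... unused.
#' @export
plot.kinetics_series <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  band <- function(t, m, sd, ylab) {
    graphics::plot(t, m, type = "l", xlab = "time (h)", ylab = ylab, lwd = 2,
                   ylim = range(c(m - sd, m + sd)))
    graphics::polygon(c(t, rev(t)), c(m - sd, rev(m + sd)), border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(t, m, lwd = 2)
  }
  band(s$time_h, s$tc_distance_um, s$tc_sd, "TC distance (um)")
  band(s$time_h, s$invasion_area_um2, s$area_sd, "invasion area (um^2)")
  invisible(x)
}
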