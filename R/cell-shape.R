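#' Cell solidity (mask area over convex-hull area)
#'
#' Solidity is the ratio between the area of the cell mask and the area
#' of its convex hull (the smallest convex set containing the mask). A
#' protrusion-free circular or elliptical cell has solidity 1; filopodia
#' and other protrusions lower it. Grayscale ROIs are first contrast
#' stretched (2-98 percentiles), Otsu-binarized and morphologically
#' smoothed (opening then closing, radius `smooth_radius_px`); binary
#' input passes through directly. The hull area is the pixel count of
#' the rasterized filled hull, so solidity is exactly 1 for convex
#' digital shapes.
#'
#' @param roi 2D matrix: binary mask or grayscale ROI containing one
#'   cell.
#' @param smooth_radius_px radius of the smoothing elements (default 2).
#' @param stretch_quantiles contrast-stretch percentiles for grayscale
#'   input (default `c(0.02, 0.98)`).
#' @return Object of class `solidity_result`: `solidity`, `mask_area`
#'   (px^2), `hull_area` (px^2), `mask`.
#' @export
solidity <- function(roi, smooth_radius_px = 2,
                     stretch_quantiles = c(0.02, 0.98)) {
  stopifnot(is.matrix(roi))
  vals <- unique(as.vector(roi))
  if (all(vals %in% c(0, 1, TRUE, FALSE))) {
    mask <- roi > 0
  } else {
    q <- stats::quantile(roi, stretch_quantiles, names = FALSE)
    if (q[2] <= q[1]) stop("flat ROI: cannot contrast stretch")
    img <- pmin(pmax((roi - q[1]) / (q[2] - q[1]), 0), 1)
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    mask <- img > thr
    if (smooth_radius_px >= 1) {
      brush <- EBImage::makeBrush(2 * smooth_radius_px + 1, shape = "disc")
      mask <- EBImage::opening(mask + 0, brush) > 0
      mask <- EBImage::closing(mask + 0, brush) > 0
    }
  }
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(mask + 0)
  tab <- tabulate(lab[lab > 0])
  mask <- matrix(lab == which.max(tab), nrow(roi), ncol(roi))
  area <- sum(mask)
  hull_area <- .hull_pixel_area(mask)
  structure(list(solidity = area / hull_area, mask_area = area,
                 hull_area = hull_area, mask = mask),
            class = "solidity_result")
}

#' @export
print.solidity_result <- function(x, ...) {
  cat(sprintf("<solidity_result> solidity %.4f (area %d px^2, hull %d px^2)\n",
              x$solidity, x$mask_area, x$hull_area))
  invisible(x)
}

# Pixel count of the rasterized filled convex hull of the mask's pixel
# centres. Inclusive half-space tests keep boundary pixels, so the hull
# always contains every mask pixel and solidity <= 1.
.hull_pixel_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  verts <- pts[h, , drop = FALSE]
  if (nrow(verts) < 3) return(nrow(pts)) # degenerate (point or segment)
  # candidate pixels: bounding box of the hull
  ri <- range(verts[, 1]); ci <- range(verts[, 2])
  cand <- as.matrix(expand.grid(r = ri[1]:ri[2], c = ci[1]:ci[2]))
  n <- nrow(verts)
  nxt <- c(seq_len(n)[-1], 1L)
  signed2 <- sum(verts[, 1] * verts[nxt, 2] - verts[nxt, 1] * verts[, 2])
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(n)) {
    a <- verts[i, ]
    b <- verts[nxt[i], ]
    cross <- (b[1] - a[1]) * (cand[, 2] - a[2]) -
      (b[2] - a[2]) * (cand[, 1] - a[1])
    inside <- inside & if (signed2 > 0) cross >= -1e-9 else cross <= 1e-9
  }
  sum(inside)
}

#' Leading-edge intensity profiles
#'
#' Samples one or more channels along user-specified lines running from
#' the cell periphery inward (bilinear interpolation at 1-px steps),
#' min-max normalizes each channel per cell, and averages the profiles
#' across cells pointwise with a standard-deviation band. Lines leaving
#' the image are truncated with a warning; cells are averaged over the
#' distance range covered by all of them.
#'
#' @param images list (one element per cell) of named lists of channel
#'   matrices.
#' @param line_specs data.frame with `cell_id`, `x0`, `y0`, `x1`, `y1`
#'   (pixel coordinates, 0-based; the start lies on the periphery).
#' @param pixel_size micrometres per pixel (default 1).
#' @return Object of class `intensity_profile`: data.frame with
#'   `distance_um` and, per channel, `<ch>_mean` and `<ch>_sd`.
#' @export
edge_profile <- function(images, line_specs, pixel_size = 1) {
  stopifnot(length(images) >= 1,
            all(c("cell_id", "x0", "y0", "x1", "y1") %in% names(line_specs)))
  channels <- names(images[[1]])
  if (is.null(channels)) stop("each cell needs named channel matrices")
  per_cell <- list()
  for (i in seq_len(nrow(line_specs))) {
    spec <- line_specs[i, ]
    cell <- images[[spec$cell_id]]
    dm <- dim(cell[[1]])
    len <- sqrt((spec$x1 - spec$x0)^2 + (spec$y1 - spec$y0)^2)
    n <- floor(len) + 1L
    t <- (seq_len(n) - 1L) / max(len, 1)
    xs <- spec$x0 + t * (spec$x1 - spec$x0)
    ys <- spec$y0 + t * (spec$y1 - spec$y0)
    ok <- xs >= 0 & xs <= dm[2] - 1 & ys >= 0 & ys <= dm[1] - 1
    if (!all(ok)) {
      warning(sprintf("line for cell %s truncated at the image border",
                      spec$cell_id))
      keep <- seq_len(match(FALSE, ok) - 1L)
      xs <- xs[keep]; ys <- ys[keep]
    }
    prof <- sapply(channels, function(ch) {
      v <- .bilinear(cell[[ch]], xs, ys)
      rng <- range(v)
      if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    })
    per_cell[[i]] <- matrix(prof, ncol = length(channels),
                            dimnames = list(NULL, channels))
  }
  n_common <- min(vapply(per_cell, nrow, integer(1)))
  out <- data.frame(distance_um = (seq_len(n_common) - 1L) * pixel_size)
  for (ch in channels) {
    m <- sapply(per_cell, function(p) p[seq_len(n_common), ch])
    m <- matrix(m, nrow = n_common)
    out[[paste0(ch, "_mean")]] <- rowMeans(m)
    out[[paste0(ch, "_sd")]] <- if (ncol(m) > 1) apply(m, 1, stats::sd) else 0
  }
  structure(out, class = c("intensity_profile", "data.frame"),
            n_cells = length(per_cell))
}

# Bilinear interpolation of matrix `img` at 0-based (x = column,
# y = row) positions.
.bilinear <- function(img, xs, ys) {
  c0 <- floor(xs); r0 <- floor(ys)
  fc <- xs - c0; fr <- ys - r0
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) img[cbind(pmin(pmax(r, 0), nr - 1) + 1,
                                 pmin(pmax(c, 0), nc - 1) + 1)]
  (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) + fr * fc * at(r0 + 1, c0 + 1)
}

#' Membrane over whole-cell intensity ratio
#'
#' Total pixel intensity inside the membrane ROI divided by the total
#' intensity over the whole cell, as a percentage; the readout used for
#' membrane-recruitment biosensors.
#'
#' @param image intensity matrix.
#' @param membrane_mask,cell_mask logical matrices; the membrane must be
#'   a subset of the cell.
#' @return percentage in `[0, 100]`.
#' @export
membrane_cytosol_ratio <- function(image, membrane_mask, cell_mask) {
  membrane_mask <- membrane_mask > 0
  cell_mask <- cell_mask > 0
  stopifnot(identical(dim(image), dim(cell_mask)),
            identical(dim(image), dim(membrane_mask)))
  if (any(membrane_mask & !cell_mask))
    stop("membrane mask must be contained in the cell mask")
  total <- sum(image[cell_mask])
  if (total <= 0) stop("zero total cell intensity")
  100 * sum(image[membrane_mask]) / total
}

#' Filopodia density per 100 um of free edge
#'
#' Normalizes a filopodia count to the length of the free edge at the
#' migrating front (detection itself is delegated to external tooling;
#' this is the normalization step only).
#'
#' @param n_filopodia count (>= 0).
#' @param edge_length_um free-edge length in um (> 0).
#' @return filopodia per 100 um.
#' @export
filopodia_density <- function(n_filopodia, edge_length_um) {
  stopifnot(n_filopodia >= 0)
  if (edge_length_um <= 0) stop("edge length must be positive")
  100 * n_filopodia / edge_length_um
}
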