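#' Track set
#'
#' Collection of cell trajectories as a long-format table with columns
#' `track_id`, `frame`, `x`, `y` (pixels and frames). Rows are sorted by
#' track then frame; duplicate `(track, frame)` entries are rejected.
#'
#' @param df data.frame with the four mandatory columns.
#' @return Object of class `track_set` (a data.frame).
#' @export
track_set <- function(df) {
  need <- c("track_id", "frame", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing track columns: ", paste(missing, collapse = ", "))
  df <- df[order(df$track_id, df$frame), need]
  dup <- duplicated(df[c("track_id", "frame")])
  if (any(dup))
    stop("duplicate (track_id, frame) rows: e.g. track ",
         df$track_id[which(dup)[1]], " frame ", df$frame[which(dup)[1]])
  rownames(df) <- NULL
  structure(df, class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d points\n",
              length(unique(x$track_id)), nrow(x)))
  invisible(x)
}

#' Number of tracks in a track set
#' @param ts a `track_set`.
#' @return integer count.
#' @export
n_tracks <- function(ts) length(unique(ts$track_id))

#' Read tracks from CSV or a TrackMate-style XML subset
#'
#' CSV files need a `track_id,frame,x,y` header (comment lines starting
#' with `#` are skipped). The XML reader understands the minimal
#' TrackMate layout: `Spot` nodes with `ID`, `POSITION_X`, `POSITION_Y`
#' and `FRAME` attributes, and `Track` nodes whose `Edge` children
#' reference spot IDs; a spot's track is the track whose edges mention
#' it.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"trackmate"`.
#' @return a `track_set`.
#' @export
read_tracks <- function(path, format = c("auto", "csv", "trackmate")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "trackmate" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, comment.char = "#")
    if (nrow(df) == 0)
      return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                  x = numeric(0), y = numeric(0))))
    return(track_set(df))
  }
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  if (!length(spots))
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x = numeric(0), y = numeric(0))))
  sid <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  sf <- as.integer(xml2::xml_attr(spots, "FRAME"))
  tracks <- xml2::xml_find_all(doc, ".//Track")
  spot2track <- character(0)
  for (tr in tracks) {
    tid <- xml2::xml_attr(tr, "TRACK_ID")
    edges <- xml2::xml_find_all(tr, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    spot2track[ids] <- tid
  }
  keep <- sid %in% names(spot2track)
  track_set(data.frame(track_id = as.integer(spot2track[sid[keep]]),
                       frame = sf[keep], x = sx[keep], y = sy[keep]))
}

#' Write tracks as CSV
#'
#' @param ts a `track_set`.
#' @param path output file; written with the mandatory
#'   `track_id,frame,x,y` header.
#' @export
write_tracks <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by minimum length
#'
#' Keeps tracks with strictly more than `min_frames` points (a 15-frame
#' track is dropped at the default, a 16-frame track kept).
#'
#' @param ts a `track_set`.
#' @param min_frames strict lower bound on track length (default 15).
#' @return filtered `track_set`.
#' @export
filter_tracks <- function(ts, min_frames = 15) {
  stopifnot(min_frames >= 2)
  n <- table(ts$track_id)
  keep <- names(n)[n > min_frames]
  out <- ts[as.character(ts$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ts))
}

# least-squares polynomial fit y ~ 1 + t + ... + t^degree
.polyfit <- function(t, y, degree) {
  X <- outer(t - mean(t), 0:degree, "^") # centring keeps the fit well-conditioned
  fit <- stats::lm.fit(X, y)
  if (fit$rank < degree + 1) stop("rank-deficient polynomial fit")
  fit
}

#' Directed migration velocity in y
#'
#' Velocity towards the wound, estimated by least-squares polynomial
#' fitting of the y-position against frame; the reported value is the
#' mean derivative of the fitted polynomial over the track's frame span
#' (for degree 1, the slope).
#'
#' @param track data.frame with `frame` and `y` (one track).
#' @param degree polynomial degree (default 1).
#' @return velocity in px/frame.
#' @export
velocity_y <- function(track, degree = 1) {
  t <- track$frame
  if (length(t) <= degree + 1) stop("track too short for the requested degree")
  fit <- .polyfit(t, track$y, degree)
  yhat <- fit$fitted.values
  span <- max(t) - min(t)
  (yhat[which.max(t)] - yhat[which.min(t)]) / span
}

#' Random-migration diffusivity in x and y
#'
#' Removes the fitted polynomial drift from both coordinates and
#' estimates the diffusion coefficient from the variance of the
#' residual frame-to-frame displacements,
#' `D = (var(dx) + var(dy)) / 4` per frame -- consistent with a 2D
#' random walk whose mean-square displacement is `4 D t`, and invariant
#' to constant drift by construction. Displacements are only taken
#' between consecutive frames; gapped pairs are skipped.
#' `method = "position"` instead reads the dispersion of the
#' drift-corrected positions themselves,
#' `(var(x_res) + var(y_res)) / (2 * span)`, a cruder single-number
#' alternative retained for comparison.
#'
#' @param track data.frame with `frame`, `x`, `y` (one track).
#' @param degree drift polynomial degree (default 1).
#' @param method `"displacement"` (default) or `"position"`.
#' @return diffusivity in px^2/frame (>= 0).
#' @export
diffusivity_xy <- function(track, degree = 1,
                           method = c("displacement", "position")) {
  method <- match.arg(method)
  t <- track$frame
  stopifnot(length(t) >= 4)
  res <- sapply(c("x", "y"), function(ax)
    stats::residuals(.polyfit(t, track[[ax]], degree)))
  if (method == "displacement") {
    step <- diff(t)
    ok <- step == min(step) # consecutive frames only
    dx <- diff(res[, "x"])[ok]
    dy <- diff(res[, "y"])[ok]
    (stats::var(dx) + stats::var(dy)) / 4
  } else {
    span <- max(t) - min(t)
    (stats::var(res[, "x"]) + stats::var(res[, "y"])) / (2 * span)
  }
}

#' Per-track migration components
#'
#' Applies [velocity_y()] and [diffusivity_xy()] to every track of a
#' set.
#'
#' @param ts a `track_set`.
#' @param degree drift polynomial degree.
#' @param method diffusivity estimator, see [diffusivity_xy()].
#' @return data.frame `track_id`, `n_frames`, `v_y`, `D_xy`.
#' @export
migration_components <- function(ts, degree = 1,
                                 method = c("displacement", "position")) {
  method <- match.arg(method)
  ids <- unique(ts$track_id)
  out <- data.frame(track_id = ids, n_frames = NA_integer_,
                    v_y = NA_real_, D_xy = NA_real_)
  for (i in seq_along(ids)) {
    tr <- ts[ts$track_id == ids[i], ]
    out$n_frames[i] <- nrow(tr)
    out$v_y[i] <- velocity_y(tr, degree)
    out$D_xy[i] <- diffusivity_xy(tr, degree, method)
  }
  out
}

#' Time-averaged mean square displacement
#'
#' MSD over all frame pairs at each lag,
#' `MSD(tau) = mean((x(t+tau)-x(t))^2 + (y(t+tau)-y(t))^2)`. An optional
#' linear fit over the first `fit_lags` lags returns `slope / 4` as a
#' 2D diffusion coefficient.
#'
#' @param track data.frame with `frame`, `x`, `y` (one track).
#' @param max_lag largest lag in frames (< track length).
#' @param fit_lags if given, number of initial lags for the linear fit.
#' @return data.frame `lag`, `msd`, `n_pairs`; when `fit_lags` is set,
#'   the fitted diffusivity is in `attr(, "D")`.
#' @export
msd <- function(track, max_lag, fit_lags = NULL) {
  t <- track$frame
  stopifnot(max_lag >= 1, max_lag < length(t))
  lookup <- new.env()
  for (i in seq_along(t)) assign(as.character(t[i]), i, envir = lookup)
  lags <- seq_len(max_lag)
  msd_v <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  base_step <- min(diff(sort(unique(t))))
  for (k in lags) {
    tau <- k * base_step
    j <- vapply(as.character(t + tau), function(key)
      if (exists(key, envir = lookup, inherits = FALSE))
        get(key, envir = lookup) else NA_integer_, integer(1))
    ok <- !is.na(j)
    n_pairs[k] <- sum(ok)
    if (n_pairs[k] > 0) {
      msd_v[k] <- mean((track$x[j[ok]] - track$x[ok])^2 +
                         (track$y[j[ok]] - track$y[ok])^2)
    } else {
      msd_v[k] <- NA_real_
    }
  }
  out <- data.frame(lag = lags * base_step, msd = msd_v, n_pairs = n_pairs)
  if (!is.null(fit_lags)) {
    k <- seq_len(min(fit_lags, max_lag))
    fit <- stats::lm(msd ~ lag, data = out[k, ])
    attr(out, "D") <- unname(stats::coef(fit)["lag"]) / 4
  }
  out
}

#' Welch two-sample comparison
#'
#' Two-sided two-sample t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom). When both groups have zero
#' variance, equal means give `t = 0, p = 1` by convention and unequal
#' means `p = 0`.
#'
#' @param values_a,values_b numeric vectors (each `n >= 2`).
#' @return list with `statistic`, `df`, `p.value`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(statistic = if (equal) 0 else sign(mean(values_a) -
                                                     mean(values_b)) * Inf,
                df = NA_real_, p.value = if (equal) 1 else 0,
                method = "Welch two-sample t-test (degenerate)"))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = ht$method)
}
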