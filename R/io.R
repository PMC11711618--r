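# Shared readers/writers and the configuration object binding the
# analysis modules together.

#' Analysis configuration
#'
#' Central home for the measurement parameters: the 0-5 um near-surface
#' band and 1 um station spacing of the displacement line scans, the
#' strict 15-frame track-length filter, and the segmentation defaults.
#'
#' @param pixel_size um per pixel of 2D images.
#' @param voxel_size um per voxel of 3D volumes (length 3).
#' @param band near-surface shell width in um (default 5).
#' @param step line-scan station spacing in um (default 1).
#' @param min_frames strict track-length threshold (default 15).
#' @param std_window std-filter window in px (default 9).
#' @param morph_radius closing radius in px (default 3).
#' @param frame_interval hours between frames (default 6).
#' @param seed integer seed for any stochastic stage.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(pixel_size = 0.65, voxel_size = c(1, 1, 1),
                            band = 5, step = 1, min_frames = 15,
                            std_window = 9, morph_radius = 3,
                            frame_interval = 6, seed = 1) {
  stopifnot(pixel_size > 0, length(voxel_size) == 3, all(voxel_size > 0),
            band > 0, step > 0, min_frames >= 2, std_window >= 3,
            frame_interval > 0)
  structure(list(pixel_size = pixel_size, voxel_size = voxel_size,
                 band = band, step = step, min_frames = min_frames,
                 std_window = std_window, morph_radius = morph_radius,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [analysis_config()]; unknown fields are rejected.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Short hash of a configuration
#'
#' Stamped into every CSV the pipeline writes so results are traceable
#' to the parameters that produced them.
#'
#' @param config an `analysis_config` (or any R object).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) .fnv1a(unclass(config))

#' Write a CSV with a configuration stamp
#'
#' First line is a `#` comment carrying the config hash, then a regular
#' header and the data. Readers in this package skip `#` lines.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config configuration stamped into the comment line.
#' @export
write_csv_stamped <- function(df, path, config = analysis_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sproutlab config_hash=%s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a TIFF stack as a time-lapse or a 3D volume
#'
#' Frames are read in file order. Whether the third axis is time or z
#' is told by `mode`, never guessed. Metadata comes from the arguments
#' or from a YAML sidecar (`<path>.yaml` with `pixel_size` /
#' `frame_interval` fields); a time-lapse without a pixel size is an
#' error. RGB input is rejected unless `as_gray = TRUE` (channel mean).
#'
#' @param path TIFF file.
#' @param mode `"timelapse"` or `"volume"`.
#' @param pixel_size um per pixel (time-lapse; overrides the sidecar).
#' @param frame_interval hours per frame (time-lapse).
#' @param as_gray average RGB channels instead of rejecting them.
#' @return a [timelapse_stack()] or a 3D array (axes: row, column,
#'   plane).
#' @export
load_stack <- function(path, mode = c("timelapse", "volume"),
                       pixel_size = NULL, frame_interval = NULL,
                       as_gray = FALSE) {
  mode <- match.arg(mode)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) {
      if (!as_gray) stop("RGB input: pass as_gray = TRUE to convert")
      f <- apply(f, c(1, 2), mean)
    }
    f
  })
  if (mode == "volume") {
    return(array(unlist(frames),
                 c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames))))
  }
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval %||% 6
  if (is.null(pixel_size))
    stop("pixel_size missing: pass it or provide a YAML sidecar")
  timelapse_stack(frames, pixel_size, frame_interval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a list of frames (or a 3D array) as a multi-page TIFF
#'
#' @param frames list of matrices in `[0, 1]`, or a 3D array (third
#'   axis becomes pages).
#' @param path output file.
#' @param bits bits per sample (default 16).
#' @export
write_stack <- function(frames, path, bits = 16) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k] * 1)
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0), 1)),
                  path, bits.per.sample = bits)
  invisible(path)
}

#' Read a displacement field from CSV
#'
#' Expects columns `x_um,y_um,z_um,ux_um,uy_um,uz_um` (comment lines
#' starting with `#` are skipped).
#'
#' @param path CSV file.
#' @return a [displacement_field()].
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x_um", "y_um", "z_um", "ux_um", "uy_um", "uz_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing field columns: ", paste(missing, collapse = ", "))
  displacement_field(as.matrix(df[, need[1:3]]), as.matrix(df[, need[4:6]]))
}

#' Write a displacement field as CSV
#'
#' @param field a `displacement_field`.
#' @param path output path.
#' @param config configuration stamped into the header comment.
#' @export
write_field_csv <- function(field, path, config = analysis_config()) {
  df <- data.frame(field$points, field$vectors)
  names(df) <- c("x_um", "y_um", "z_um", "ux_um", "uy_um", "uz_um")
  write_csv_stamped(df, path, config)
}

#' Write a synthetic spheroid scene to disk
#'
#' Frames and generating masks as multi-page TIFFs plus a YAML sidecar
#' with the programmed ground truth.
#'
#' @param scene a `spheroid_scene`.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "spheroid_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_frames <- file.path(dir, "frames.tif")
  p_masks <- file.path(dir, "true_masks.tif")
  p_truth <- file.path(dir, "truth.yaml")
  write_stack(scene$stack$frames, p_frames)
  write_stack(lapply(scene$true_masks, function(m) m + 0), p_masks, bits = 8)
  yaml::write_yaml(list(pixel_size = scene$pixel_size,
                        frame_interval = scene$stack$frame_interval,
                        seed = scene$seed,
                        true_tc_distance_um = as.numeric(scene$true_tc_distance),
                        true_invasion_area_um2 = as.numeric(scene$true_invasion_area)),
                   p_truth)
  yaml::write_yaml(list(pixel_size = scene$pixel_size,
                        frame_interval = scene$stack$frame_interval),
                   paste0(p_frames, ".yaml"))
  list(frames = p_frames, masks = p_masks, truth = p_truth)
}

# run a pipeline stage, prefixing errors with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run an analysis pipeline end to end
#'
#' Thin orchestration over the module functions, used by the command
#' line interface. Outputs are deterministic given a fixed configuration
#' and seed; the log (via `message()`) records parameters and exclusion
#' counts.
#'
#' @param subcommand one of `"simulate"`, `"kinetics"`, `"profile"`,
#'   `"solidity"`, `"migration"`, `"ratio"`.
#' @param config an [analysis_config()].
#' @param input named list of input paths (subcommand-specific:
#'   `stack`, `tracks`, `mask`, `field`, `roi`, `image`,
#'   `membrane_mask`, `cell_mask`, `reference`).
#' @param out output file (or directory for `simulate`).
#' @param dry_run validate the configuration and inputs only.
#' @return invisibly, the main result object of the stage.
#' @export
run_pipeline <- function(subcommand, config = analysis_config(),
                         input = list(), out = NULL, dry_run = FALSE) {
  subcommand <- match.arg(subcommand, c("simulate", "kinetics", "profile",
                                        "solidity", "migration", "ratio"))
  stopifnot(inherits(config, "analysis_config"))
  message(sprintf("sproutlab %s | config %s", subcommand, config_hash(config)))
  if (dry_run) return(invisible(NULL))
  if (is.null(out)) stop("an output path is required")
  switch(subcommand,
    simulate = .stage("simulate", {
      scene <- make_spheroid_timelapse(pixel_size = config$pixel_size,
                                       frame_interval_h = config$frame_interval,
                                       seed = config$seed)
      paths <- write_scene(scene, out)
      tr <- make_tracks(track_params(50, 60, drift = c(0, 0.5),
                                     diffusion = 0.5, seed = config$seed))
      write_tracks(tr, file.path(out, "tracks.csv"))
      invisible(scene)
    }),
    kinetics = .stage("kinetics", {
      stack <- load_stack(input$stack, "timelapse",
                          pixel_size = config$pixel_size,
                          frame_interval = config$frame_interval)
      ks <- kinetics_curves(stack, config$std_window, config$morph_radius)
      write_csv_stamped(ks$per_replicate[[1]], out, config)
      invisible(ks)
    }),
    profile = .stage("profile", {
      vol <- load_stack(input$mask, "volume") > 0.5
      field <- read_field_csv(input$field)
      ref <- as.numeric(strsplit(input$reference %||% "0,0,0", ",")[[1]])
      geom <- sprout_geometry(vol, config$voxel_size, reference_point = ref)
      prof <- signed_profile(field, geom, step = config$step,
                             band = config$band)
      message(sprintf("profile: %d/%d stations populated",
                      sum(!is.na(prof$signed_disp_um)), nrow(prof)))
      write_csv_stamped(as.data.frame(prof), out, config)
      invisible(prof)
    }),
    solidity = .stage("solidity", {
      roi <- load_stack(input$roi, "volume")[, , 1]
      res <- solidity(roi)
      write_csv_stamped(data.frame(solidity = res$solidity,
                                   mask_area_px2 = res$mask_area,
                                   hull_area_px2 = res$hull_area),
                        out, config)
      invisible(res)
    }),
    migration = .stage("migration", {
      ts <- read_tracks(input$tracks)
      kept <- filter_tracks(ts, config$min_frames)
      message(sprintf("migration: %d of %d tracks pass the >%d-frame filter",
                      n_tracks(kept), n_tracks(ts), config$min_frames))
      comp <- migration_components(kept)
      write_csv_stamped(comp, out, config)
      invisible(comp)
    }),
    ratio = .stage("ratio", {
      img <- load_stack(input$image, "volume")[, , 1]
      mem <- load_stack(input$membrane_mask, "volume")[, , 1] > 0.5
      cel <- load_stack(input$cell_mask, "volume")[, , 1] > 0.5
      res <- membrane_cytosol_ratio(img, mem, cel)
      write_csv_stamped(data.frame(membrane_ratio_pct = res), out, config)
      invisible(res)
    })
  )
}
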