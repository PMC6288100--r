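#' Analysis control parameters
#'
#' Collects every tunable of the per-cell pipeline with its default.
#'
#' @param corner_window_px side of each corner background window, px.
#' @param despeckle_radius_px median-filter radius, px.
#' @param min_cell_area_px smallest acceptable cell area, px.
#' @param donor_floor absolute donor intensity floor for ratio pixels;
#'   `NULL` (default) uses twice the per-frame corner-pixel standard
#'   deviation, a noise-scale proxy.
#' @param segment_channel channel segmented for the cell mask.
#' @param mask_propagation reuse the previous frame's mask when a frame has
#'   no component above `min_cell_area_px`.
#' @param n_bins flow-axis bins (the standard analysis uses 50).
#' @param n_edge_regions bins averaged at each extreme for the up/down
#'   summaries.
#' @param alpha significance level of the polarity call.
#' @param t_variant `"welch"` or `"student"` two-sample t-test.
#' @param weighting per-bin weights: `"ratio"` (ratio values, default) or
#'   `"intensity"` (despeckled FRET intensities).
#' @param edges `"per_frame"` recomputes bin edges from each frame's mask
#'   extent (cells deform under flow); `"fixed"` reuses frame 1's extent.
#' @param keep_maps retain per-frame ratio maps in the result object.
#' @return A list of class `"fret_control"`.
#' @export
fret_control <- function(corner_window_px = 8,
                         despeckle_radius_px = 1,
                         min_cell_area_px = 200,
                         donor_floor = NULL,
                         segment_channel = c("donor", "fret", "sum"),
                         mask_propagation = FALSE,
                         n_bins = 50,
                         n_edge_regions = 5,
                         alpha = 0.05,
                         t_variant = c("welch", "student"),
                         weighting = c("ratio", "intensity"),
                         edges = c("per_frame", "fixed"),
                         keep_maps = TRUE) {
  structure(list(corner_window_px = corner_window_px,
                 despeckle_radius_px = despeckle_radius_px,
                 min_cell_area_px = min_cell_area_px,
                 donor_floor = donor_floor,
                 segment_channel = match.arg(segment_channel),
                 mask_propagation = isTRUE(mask_propagation),
                 n_bins = n_bins,
                 n_edge_regions = n_edge_regions,
                 alpha = alpha,
                 t_variant = match.arg(t_variant),
                 weighting = match.arg(weighting),
                 edges = match.arg(edges),
                 keep_maps = isTRUE(keep_maps)),
            class = "fret_control")
}

#' Fit the spatio-temporal FRET polarity model to one acquisition
#'
#' Runs the full per-cell pipeline: per-frame, per-channel corner background
#' estimation and subtraction, median despeckling, Otsu segmentation of the
#' cell, per-pixel FRET/donor ratio maps, the baseline-normalized whole-cell
#' ratio time series, equal-width flow-axis profiles with per-bin baseline
#' normalization, and the bin-by-time spatio-temporal map.  The analysis
#' contains no random step: identical input and control give identical
#' output.
#'
#' @param stack an [read_stack()] / [generate_stack()] acquisition.
#' @param control a [fret_control()].
#' @return An object of class `"fret_analysis"`: list with `series`
#'   (`"ratio_series"`), `profiles` (normalized `"spatial_profile"`s), `map`
#'   (`"spatiotemporal_map"`), `masks`, `ratio_maps` (if kept),
#'   `backgrounds` (`T x 2`), `donor_floors`, `excluded_px`, `meta`,
#'   `control`, `call`.
#' @examples
#' stk <- generate_stack(fret_truth(seed = 3), n_frames = 10, dim = c(96, 96))
#' fit <- fret_analysis(stk)
#' print(fit)
#' @export
fret_analysis <- function(stack, control = fret_control()) {
  stopifnot(inherits(stack, "acquisition_stack"), inherits(control, "fret_control"))
  meta <- stack$meta
  T_ <- dim(stack$donor)[3]
  backgrounds <- matrix(NA_real_, T_, 2, dimnames = list(NULL, c("donor", "fret")))
  floors <- numeric(T_)
  masks <- vector("list", T_)
  maps <- vector("list", T_)
  profiles <- vector("list", T_)
  prev_mask <- NULL
  proj_range <- NULL
  for (f in seq_len(T_)) {
    d_raw <- stack$donor[, , f]
    f_raw <- stack$fret[, , f]
    bg_d <- estimate_background(d_raw, control$corner_window_px)
    bg_f <- estimate_background(f_raw, control$corner_window_px)
    backgrounds[f, ] <- c(bg_d$value, bg_f$value)
    d_sub <- despeckle(subtract_background(d_raw, bg_d),
                       control$despeckle_radius_px)
    f_sub <- despeckle(subtract_background(f_raw, bg_f),
                       control$despeckle_radius_px)
    seg_img <- switch(control$segment_channel,
                      donor = d_sub, fret = f_sub, sum = d_sub + f_sub)
    mask <- segment_cell(seg_img, control$min_cell_area_px,
                         previous_mask = if (control$mask_propagation) prev_mask)
    mask$frame_index <- f
    prev_mask <- mask
    floors[f] <- control$donor_floor %||% (2 * corner_sd(d_raw, bg_d))
    rmap <- compute_ratio_map(f_sub, d_sub, mask, donor_floor = floors[f])
    if (control$edges == "fixed" && f == 1L)
      proj_range <- range(flow_projection(rmap$valid, meta$flow_direction))
    profiles[[f]] <- bin_along_flow(
      rmap, meta$flow_direction, control$n_bins,
      weight = if (control$weighting == "intensity") f_sub,
      proj_range = proj_range)
    masks[[f]] <- mask
    maps[[f]] <- rmap
  }
  series <- whole_cell_series(maps, meta)
  profiles <- normalize_profiles(profiles, meta$stimulus_onset_frame)
  st_map <- assemble_map(profiles, meta)
  structure(list(series = series,
                 profiles = profiles,
                 map = st_map,
                 masks = masks,
                 ratio_maps = if (control$keep_maps) maps,
                 backgrounds = backgrounds,
                 donor_floors = floors,
                 excluded_px = vapply(maps, function(m) m$n_excluded, integer(1)),
                 meta = meta,
                 control = control,
                 call = match.call()),
            class = "fret_analysis")
}

corner_sd <- function(image, bg) {
  w <- bg$corner_window_px
  H <- nrow(image); W <- ncol(image)
  v <- image[c(1:w, (H - w + 1L):H), c(1:w, (W - w + 1L):W)]
  sd(as.numeric(v))
}

#' @export
print.fret_analysis <- function(x, ...) {
  T_ <- length(x$series$frame)
  cat(sprintf("FRET flow-response analysis: %d frames, stimulus at frame %d\n",
              T_, x$meta$stimulus_onset_frame))
  cat(sprintf("  baseline ratio %.4f; final normalized ratio %.4f (%+.1f%%)\n",
              x$series$baseline, x$series$normalized_ratio[T_],
              100 * (x$series$normalized_ratio[T_] - 1)))
  ud <- updown_summary(x$profiles[[T_]], x$control$n_edge_regions)
  cat(sprintf("  final frame edge summaries: downstream %.4f, upstream %.4f\n",
              ud["down_mean"], ud["up_mean"]))
  invisible(x)
}

#' @export
summary.fret_analysis <- function(object, ...) {
  T_ <- length(object$series$frame)
  ud <- t(vapply(object$profiles,
                 function(p) updown_summary(p, object$control$n_edge_regions),
                 numeric(2)))
  out <- list(n_frames = T_,
              stimulus_onset_frame = object$meta$stimulus_onset_frame,
              baseline = object$series$baseline,
              final_normalized_ratio = object$series$normalized_ratio[T_],
              mean_cell_area_px = mean(vapply(object$masks, `[[`, numeric(1), "area_px")),
              mean_background = colMeans(object$backgrounds),
              total_excluded_px = sum(object$excluded_px),
              updown = ud)
  class(out) <- "summary.fret_analysis"
  out
}

#' @export
print.summary.fret_analysis <- function(x, ...) {
  cat(sprintf("Frames: %d (stimulus at %d); mean cell area %.0f px\n",
              x$n_frames, x$stimulus_onset_frame, x$mean_cell_area_px))
  cat(sprintf("Mean background: donor %.2f, fret %.2f; %d px excluded by donor floor\n",
              x$mean_background["donor"], x$mean_background["fret"],
              x$total_excluded_px))
  cat(sprintf("Baseline ratio %.4f; final normalized ratio %.4f\n",
              x$baseline, x$final_normalized_ratio))
  cat(sprintf("Final down/up 5-bin means: %.4f / %.4f\n",
              x$updown[x$n_frames, 1], x$updown[x$n_frames, 2]))
  invisible(x)
}

#' @export
plot.fret_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$series, main = "whole-cell ratio")
  plot(x$map, main = "spatio-temporal map")
  invisible(x)
}

#' Cross-cell polarity test at a chosen time point
#'
#' Extracts the per-cell downstream and upstream edge summaries at the frame
#' closest to `time_min` after stimulus onset (30 min in the reference
#' analysis) from a list of fitted cells and runs [polarity_test()].
#'
#' @param analyses list of [fret_analysis()] objects (>= 2 cells).
#' @param time_min minutes after stimulus onset at which to compare.
#' @param alpha,variant passed to [polarity_test()].
#' @return A [polarity_test()] result with the per-cell values attached as
#'   `attr(, "cells")`.
#' @export
cohort_polarity <- function(analyses, time_min = 30, alpha = 0.05,
                            variant = c("welch", "student")) {
  stopifnot(length(analyses) >= 2L,
            all(vapply(analyses, inherits, logical(1), "fret_analysis")))
  ud <- t(vapply(analyses, function(a) {
    target_s <- (a$meta$stimulus_onset_frame - 1) * a$meta$frame_interval_s +
      time_min * 60
    f <- which.min(abs(a$series$times_s - target_s))
    updown_summary(a$profiles[[f]], a$control$n_edge_regions)
  }, numeric(2)))
  res <- polarity_test(ud[, "up_mean"], ud[, "down_mean"], alpha = alpha,
                       variant = match.arg(variant))
  attr(res, "cells") <- data.frame(cell = seq_len(nrow(ud)),
                                   down_mean = ud[, "down_mean"],
                                   up_mean = ud[, "up_mean"])
  res
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

require_keys <- function(config, keys) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
}

control_from_config <- function(config) {
  ctl_args <- intersect(names(config), names(formals(fret_control)))
  do.call(fret_control, config[ctl_args])
}

#' Run the full analysis from a configuration
#'
#' Reads a two-channel acquisition, fits [fret_analysis()], and writes the
#' result bundle into `out_dir`: `series.csv`, `profiles.csv` (raw and
#' normalized per-bin percentages), `map.csv`, `ratio.tif` (float32 ratio
#' stack, NaN outside the cell), `map.png`, the effective `config.yaml`, and
#' `log.txt` with stage timings and pixel-exclusion counts.  The CSV/JSON
#' outputs are deterministic: identical config and inputs give identical
#' bytes.
#'
#' @param config a list or path to a YAML file.  Required keys:
#'   `donor_path`, `fret_path`, `flow_direction_row`, `flow_direction_col`,
#'   `stimulus_onset_frame`, `frame_interval_s`, `out_dir`; optional:
#'   `pixel_size_um` plus any [fret_control()] argument.
#' @return The fitted [fret_analysis()], invisibly.
#' @export
run_analysis <- function(config) {
  config <- load_config(config)
  require_keys(config, c("donor_path", "fret_path", "flow_direction_row",
                         "flow_direction_col", "stimulus_onset_frame",
                         "frame_interval_s", "out_dir"))
  t_start <- proc.time()[["elapsed"]]
  log_lines <- character()
  stage <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%8.3fs] %s",
                                       proc.time()[["elapsed"]] - t_start, msg))
  }
  meta <- acquisition_meta(c(config$flow_direction_row, config$flow_direction_col),
                           config$stimulus_onset_frame,
                           config$frame_interval_s,
                           pixel_size_um = config$pixel_size_um)
  stack <- read_stack(config$donor_path, config$fret_path, meta)
  stage(sprintf("read stack: %d frames %d x %d px",
                dim(stack)[3], dim(stack)[1], dim(stack)[2]))
  control <- control_from_config(config)
  fit <- fret_analysis(stack, control)
  stage(sprintf("analysis done; donor-floor exclusions per frame: %s",
                paste(fit$excluded_px, collapse = " ")))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(fit$series), file.path(out_dir, "series.csv"),
            row.names = FALSE)
  write.csv(profiles_frame(fit$profiles), file.path(out_dir, "profiles.csv"),
            row.names = FALSE)
  write_map_csv(fit$map, file.path(out_dir, "map.csv"))
  write_ratio_stack(fit$ratio_maps %||% stop("keep_maps must be TRUE for export"),
                    file.path(out_dir, "ratio.tif"))
  render_map(fit$map, file.path(out_dir, "map.png"))
  cfg_echo <- config
  # absolute input paths so the echoed config resolves from any directory
  cfg_echo$donor_path <- normalizePath(config$donor_path)
  cfg_echo$fret_path <- normalizePath(config$fret_path)
  cfg_echo$effective_control <- unclass(control)
  cfg_echo$effective_control$donor_floor <- fit$donor_floors
  yaml::write_yaml(cfg_echo, file.path(out_dir, "config.yaml"))
  stage("bundle written")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(fit)
}

# long-format per-frame profile table: one row per frame, raw then normalized
profiles_frame <- function(profiles) {
  n <- length(profiles[[1]]$percentages)
  raw <- t(vapply(profiles, function(p) p$percentages, numeric(n)))
  nrm <- t(vapply(profiles, function(p) p$normalized_percentages, numeric(n)))
  colnames(raw) <- sprintf("bin_%02d", seq_len(n))
  colnames(nrm) <- sprintf("bin_%02d_norm", seq_len(n))
  data.frame(frame = seq_along(profiles), raw, nrm, check.names = FALSE)
}

#' Simulate a cohort to disk
#'
#' Generates `n_cells` synthetic acquisitions and writes, per cell, float32
#' TIFF pairs (`donor_###.tif`, `fret_###.tif`), a metadata sidecar
#' (`meta_###.yaml`) and the ground-truth record (`truth_###.json`) into
#' `out_dir`.  Reproducible: the same config (including `seed`) writes
#' identical files.
#'
#' @param config list or YAML path.  Required: `out_dir`, `seed`; optional:
#'   `n_cells` (default 1), `n_frames` (default 36), `height`/`width`
#'   (default 128), `frame_interval_s`, `flow_direction_row`/`_col`,
#'   `between_cell_sd`, plus any [fret_truth()] argument.
#' @return Character vector of the files written, invisibly.
#' @export
run_simulation <- function(config) {
  config <- load_config(config)
  require_keys(config, c("out_dir", "seed"))
  n_cells <- config$n_cells %||% 1L
  n_frames <- config$n_frames %||% 36L
  dims <- c(config$height %||% 128L, config$width %||% 128L)
  flow <- c(config$flow_direction_row %||% 0, config$flow_direction_col %||% 1)
  interval <- config$frame_interval_s %||% 60
  truth_args <- intersect(names(config), names(formals(fret_truth)))
  truth <- do.call(fret_truth, config[truth_args])
  truth$seed <- as.integer(config$seed)
  stacks <- if (n_cells == 1L) {
    list(generate_stack(truth, n_frames, dims, interval, flow))
  } else {
    generate_cohort(truth, n_cells, n_frames, dims,
                    between_cell_sd = config$between_cell_sd %||% 0.03,
                    frame_interval_s = interval, flow_direction = flow,
                    master_seed = truth$seed)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- unlist(lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]
    dp <- file.path(config$out_dir, sprintf("donor_%03d.tif", i))
    fp <- file.path(config$out_dir, sprintf("fret_%03d.tif", i))
    mp <- file.path(config$out_dir, sprintf("meta_%03d.yaml", i))
    tp <- file.path(config$out_dir, sprintf("truth_%03d.json", i))
    write_float_tiff(lapply(seq_len(dim(s)[3]), function(f) s$donor[, , f]), dp)
    write_float_tiff(lapply(seq_len(dim(s)[3]), function(f) s$fret[, , f]), fp)
    write_meta(s$meta, mp, donor_path = basename(dp), fret_path = basename(fp))
    write_truth_json(attr(s, "truth"), tp)
    c(dp, fp, mp, tp)
  }))
  invisible(files)
}
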