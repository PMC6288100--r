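#' Assemble per-frame profiles into a bin-by-time map
#'
#' Stacks the normalized per-bin percentages of consecutive frames into an
#' `n_bins x T` matrix (bin 1 = downstream), the tabular form of the
#' three-dimensional spatio-temporal graph.  Invalid bins and (optionally)
#' missing frames are carried as `NA`, never zero-filled — zero is a
#' meaningful percentage.
#'
#' @param profiles list of [normalize_profiles()]d per-frame profiles.
#' @param meta an [acquisition_meta()].
#' @param allow_gaps if `TRUE`, a missing frame becomes an all-`NA` column;
#'   if `FALSE` (default) a gap in frame indices is an error.
#' @return An object of class `"spatiotemporal_map"`: list with `values`
#'   (`n_bins x T`), `times_s`, `bin_axis`, `stimulus_onset_s`.
#' @export
assemble_map <- function(profiles, meta, allow_gaps = FALSE) {
  stopifnot(inherits(meta, "acquisition_meta"), length(profiles) >= 1L)
  if (is.null(profiles[[1]]$normalized_percentages))
    stop("profiles must be normalized first (normalize_profiles)")
  n_bins <- length(profiles[[1]]$percentages)
  idx <- vapply(profiles, function(p) as.integer(p$frame_index), integer(1))
  if (anyNA(idx)) idx <- seq_along(profiles)
  T_ <- max(idx)
  missing_frames <- setdiff(seq_len(T_), idx)
  if (length(missing_frames) && !allow_gaps)
    stop("gap in frame indices at frame(s) ",
         paste(missing_frames, collapse = ", "),
         "; set allow_gaps = TRUE to carry them as missing columns")
  values <- matrix(NA_real_, n_bins, T_)
  for (i in seq_along(profiles))
    values[, idx[i]] <- profiles[[i]]$normalized_percentages
  structure(list(values = values,
                 times_s = (seq_len(T_) - 1) * meta$frame_interval_s,
                 bin_axis = seq_len(n_bins),
                 stimulus_onset_s = (meta$stimulus_onset_frame - 1) *
                   meta$frame_interval_s),
            class = "spatiotemporal_map")
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat(sprintf("Spatio-temporal map: %d bins x %d frames (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.spatiotemporal_map <- function(x, ...) {
  z <- t(x$values)  # time on x, bins on y
  graphics::image(x = x$times_s / 60, y = x$bin_axis, z = z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (min)",
                  ylab = "bin (1 = downstream ... upstream)", ...)
  graphics::abline(v = x$stimulus_onset_s / 60, lty = 2, col = "white", lwd = 2)
  invisible(x)
}

#' Render a spatio-temporal map to an image file
#'
#' Writes a heatmap of the map with the bin axis labeled downstream to
#' upstream and a dashed marker at stimulus onset.  PNG output is rendered
#' through the cairo backend, SVG through the cairo SVG device; given the
#' same map and style the output is deterministic.  Purely presentational.
#'
#' @param map a [assemble_map()] result.
#' @param out_path output file; extension selects the format (`.png`/`.svg`).
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @return `out_path`, invisibly.
#' @export
render_map <- function(map, out_path, width = NULL, height = NULL) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    grDevices::svg(out_path, width = width %||% 7, height = height %||% 5)
  } else if (ext == "png") {
    grDevices::png(out_path, width = width %||% 840, height = height %||% 600,
                   type = "cairo")
  } else {
    stop("unsupported figure format: .", ext)
  }
  on.exit(grDevices::dev.off())
  plot(map, main = "normalized FRET ratio percentage")
  invisible(out_path)
}

#' Export a spatio-temporal map as a CSV matrix
#'
#' Rows are bins (1 = downstream), columns are frames; cell values are
#' normalized percentages, missing entries left empty.
#'
#' @param map a [assemble_map()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  df <- as.data.frame(map$values)
  names(df) <- sprintf("t_%gs", map$times_s)
  df <- cbind(bin = map$bin_axis, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
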