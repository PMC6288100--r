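#' Acquisition metadata
#'
#' Describes one two-channel time-lapse acquisition: the direction of applied
#' flow in image coordinates, when the stimulus started, and the temporal and
#' spatial sampling.  Every downstream operation takes its conventions from
#' this object; in particular the flow direction is metadata and is never
#' assumed to point along an image axis.
#'
#' @param flow_direction numeric length-2 vector `(d_row, d_col)` giving the
#'   direction of flow in image coordinates (row-major, origin top-left).
#'   Any nonzero vector is accepted and normalized to unit length.
#' @param stimulus_onset_frame 1-based index of the first frame acquired with
#'   the stimulus applied.  Must be at least 2 so that at least one
#'   pre-stimulus frame exists for baseline normalization.
#' @param frame_interval_s frame interval in seconds (> 0); the acquisitions
#'   this models are sampled once per 60 s.
#' @param pixel_size_um pixel size in micrometers (optional, informational).
#' @param channel_names ordered pair of channel names, donor first.
#' @param excitation_nm,donor_emission_nm,acceptor_emission_nm wavelengths in
#'   nm; defaults match an ECFP/YPet pair (420 nm excitation, 475 nm donor
#'   and 535 nm acceptor emission).
#'
#' @return An object of class `"acquisition_meta"`.
#' @examples
#' acquisition_meta(c(0, 1), stimulus_onset_frame = 6)
#' @export
acquisition_meta <- function(flow_direction,
                             stimulus_onset_frame,
                             frame_interval_s = 60,
                             pixel_size_um = NULL,
                             channel_names = c("ECFP", "FRET"),
                             excitation_nm = 420,
                             donor_emission_nm = 475,
                             acceptor_emission_nm = 535) {
  flow_direction <- as.numeric(flow_direction)
  if (length(flow_direction) != 2L || any(!is.finite(flow_direction)))
    stop("flow_direction must be a finite numeric 2-vector (d_row, d_col)")
  nrm <- sqrt(sum(flow_direction^2))
  if (nrm == 0) stop("flow_direction must be nonzero")
  flow_direction <- flow_direction / nrm
  stimulus_onset_frame <- as.integer(stimulus_onset_frame)
  if (is.na(stimulus_onset_frame) || stimulus_onset_frame < 2L)
    stop("stimulus_onset_frame must be >= 2 (at least one pre-stimulus frame)")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0")
  structure(
    list(
      flow_direction = flow_direction,
      stimulus_onset_frame = stimulus_onset_frame,
      frame_interval_s = as.numeric(frame_interval_s),
      pixel_size_um = if (is.null(pixel_size_um)) NA_real_ else as.numeric(pixel_size_um),
      channel_names = as.character(channel_names),
      excitation_nm = excitation_nm,
      donor_emission_nm = donor_emission_nm,
      acceptor_emission_nm = acceptor_emission_nm
    ),
    class = "acquisition_meta"
  )
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("Acquisition metadata\n")
  cat(sprintf("  flow direction (row, col): (%.4f, %.4f)\n",
              x$flow_direction[1], x$flow_direction[2]))
  cat(sprintf("  stimulus onset frame:      %d\n", x$stimulus_onset_frame))
  cat(sprintf("  frame interval:            %g s\n", x$frame_interval_s))
  if (!is.na(x$pixel_size_um))
    cat(sprintf("  pixel size:                %g um\n", x$pixel_size_um))
  cat(sprintf("  channels:                  %s (donor), %s (acceptor)\n",
              x$channel_names[1], x$channel_names[2]))
  invisible(x)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF file: ", path)
  # as.is=TRUE keeps integer TIFFs on their native count scale, but is
  # rejected for float samples, which are already read unscaled
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    storage.mode(p) <- "double"
    p
  })
}

#' Read a two-channel acquisition from multi-page TIFF files
#'
#' Reads one multi-page TIFF per channel (donor and FRET), page order taken as
#' chronological order, and returns the intensities exactly as stored: integer
#' TIFFs are not rescaled to \[0, 1\] and floating TIFFs are passed through,
#' so a 16-bit pixel of 65535 stays 65535.
#'
#' @param donor_path,fret_path paths to multi-page TIFF files with identical
#'   page counts and dimensions.
#' @param meta an [acquisition_meta()] object.
#' @return An object of class `"acquisition_stack"`: a list with `donor` and
#'   `fret` (numeric `H x W x T` arrays, frames along the third dimension)
#'   and `meta`.
#' @export
read_stack <- function(donor_path, fret_path, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  donor <- read_tiff_pages(donor_path)
  fret <- read_tiff_pages(fret_path)
  if (length(donor) != length(fret))
    stop(sprintf("channel page counts differ: donor %d vs fret %d",
                 length(donor), length(fret)))
  dims <- unique(lapply(c(donor, fret), dim))
  if (length(dims) != 1L)
    stop("all pages of both channels must share the same dimensions")
  new_acquisition_stack(
    donor = array(unlist(donor), dim = c(dims[[1]], length(donor))),
    fret = array(unlist(fret), dim = c(dims[[1]], length(fret))),
    meta = meta
  )
}

new_acquisition_stack <- function(donor, fret, meta) {
  if (!identical(dim(donor), dim(fret)))
    stop("donor and fret arrays must have identical dimensions")
  if (length(dim(donor)) != 3L || dim(donor)[3] < 2L)
    stop("an acquisition needs at least 2 frames")
  if (any(!is.finite(donor)) || any(!is.finite(fret)))
    stop("intensities must be finite")
  if (min(donor) < 0 || min(fret) < 0)
    stop("negative intensities are not valid acquisition data")
  if (meta$stimulus_onset_frame > dim(donor)[3])
    stop("stimulus_onset_frame lies beyond the last frame")
  structure(list(donor = donor, fret = fret, meta = meta),
            class = "acquisition_stack")
}

#' @export
print.acquisition_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("Two-channel acquisition: %d frames of %d x %d px\n",
              d[3], d[1], d[2]))
  cat(sprintf("  donor range %g..%g, fret range %g..%g\n",
              min(x$donor), max(x$donor), min(x$fret), max(x$fret)))
  print(x$meta)
  invisible(x)
}

#' @export
dim.acquisition_stack <- function(x) dim(x$donor)

# Minimal uncompressed little-endian multi-page TIFF writer for 32-bit IEEE
# float samples.  Needed because no installed writer preserves float samples
# outside [0, 1]; values (including NaN) are stored bit-exactly at float32
# precision, one strip per page.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  offset <- 8L                     # running file offset after the header
  w4(offset + 0L)                  # first IFD immediately follows header
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    H <- nrow(m); W <- ncol(m)
    nbytes <- 4L * H * W
    data_off <- offset + ifd_size
    w2(n_entries)
    entry(256L, 4L, 1L, W)                 # ImageWidth
    entry(257L, 4L, 1L, H)                 # ImageLength
    entry(258L, 3L, 1L, 32L)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)          # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, H)                 # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)            # StripByteCounts
    entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
    next_ifd <- if (i < length(pages)) data_off + nbytes else 0L
    w4(next_ifd)
    # row-major pixel stream
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Write ratio maps as a 32-bit float multi-page TIFF
#'
#' Pixels outside each map's valid set are written as NaN so that downstream
#' viewers can distinguish "no cell" from a ratio of zero.  Values round-trip
#' through [tiff::readTIFF()] at float32 precision in page order.
#'
#' @param ratio_maps a single ratio map or list of ratio maps from
#'   [compute_ratio_map()] (plain matrices are also accepted, written as-is).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_ratio_stack <- function(ratio_maps, path) {
  if (inherits(ratio_maps, "ratio_map") || is.matrix(ratio_maps))
    ratio_maps <- list(ratio_maps)
  if (length(ratio_maps) == 0L) stop("no ratio maps to write")
  pages <- lapply(ratio_maps, function(m) {
    if (inherits(m, "ratio_map")) {
      out <- m$ratio
      out[!m$valid] <- NaN
      out
    } else {
      as.matrix(m)
    }
  })
  if (length(unique(lapply(pages, dim))) != 1L)
    stop("all ratio maps must share the same dimensions")
  pages <- lapply(pages, function(p) { p[is.na(p)] <- NaN; p })
  write_float_tiff(pages, path)
  invisible(path)
}

#' Read and write sidecar acquisition metadata
#'
#' Metadata travels in a flat key-value YAML sidecar (keys:
#' `flow_direction_row`, `flow_direction_col`, `stimulus_onset_frame`,
#' `frame_interval_s`, `pixel_size_um`, `donor_path`, `fret_path`), since
#' TIFF tags for these fields are nonstandard.
#'
#' @param path path to the YAML sidecar file.
#' @return `read_meta()` returns a list with element `meta`
#'   (an [acquisition_meta()]) and the `donor_path`/`fret_path` entries,
#'   resolved relative to the sidecar's directory when not absolute.
#' @export
read_meta <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("flow_direction_row", "flow_direction_col",
                "stimulus_onset_frame", "frame_interval_s")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("metadata file is missing required key(s): ",
         paste(missing, collapse = ", "))
  meta <- acquisition_meta(
    flow_direction = c(raw$flow_direction_row, raw$flow_direction_col),
    stimulus_onset_frame = raw$stimulus_onset_frame,
    frame_interval_s = raw$frame_interval_s,
    pixel_size_um = raw$pixel_size_um
  )
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p) || grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(dirname(path), p)
  }
  list(meta = meta,
       donor_path = resolve(raw$donor_path),
       fret_path = resolve(raw$fret_path))
}

#' @param meta an [acquisition_meta()] object.
#' @param donor_path,fret_path optional image paths recorded in the sidecar.
#' @rdname read_meta
#' @export
write_meta <- function(meta, path, donor_path = NULL, fret_path = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"))
  out <- list(
    flow_direction_row = meta$flow_direction[1],
    flow_direction_col = meta$flow_direction[2],
    stimulus_onset_frame = meta$stimulus_onset_frame,
    frame_interval_s = meta$frame_interval_s
  )
  if (!is.na(meta$pixel_size_um)) out$pixel_size_um <- meta$pixel_size_um
  if (!is.null(donor_path)) out$donor_path <- donor_path
  if (!is.null(fret_path)) out$fret_path <- fret_path
  yaml::write_yaml(out, path)
  invisible(path)
}
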