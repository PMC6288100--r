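#' Per-pixel FRET/donor ratio map
#'
#' Divides the background-subtracted FRET frame by the donor frame on the
#' cell mask.  Pixels whose donor intensity falls below `donor_floor` (or is
#' zero) are removed from the valid set rather than producing unstable or
#' infinite ratios at dim cell edges; the number removed is recorded.
#'
#' @param fret_frame,donor_frame background-subtracted `H x W` matrices.
#' @param mask a [segment_cell()] `"cell_mask"` (or logical matrix).
#' @param donor_floor minimum donor intensity for a pixel to enter the map.
#'   The pipeline default is twice the corner-pixel noise scale of the frame.
#' @return An object of class `"ratio_map"`: list with `ratio` (`H x W`
#'   numeric, `NA` off the valid set), `valid` (logical), `frame_index`,
#'   `n_excluded` (mask pixels dropped by the donor floor).
#' @examples
#' m <- matrix(TRUE, 4, 4)
#' r <- compute_ratio_map(matrix(30, 4, 4), matrix(20, 4, 4), m)
#' unique(r$ratio[r$valid])  # 1.5
#' @export
compute_ratio_map <- function(fret_frame, donor_frame, mask, donor_floor = 0) {
  msk <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(is.logical(msk), identical(dim(msk), dim(donor_frame)),
            identical(dim(fret_frame), dim(donor_frame)))
  if (!is.numeric(donor_floor) || length(donor_floor) != 1L || donor_floor < 0)
    stop("donor_floor must be a single non-negative value")
  valid <- msk & donor_frame > 0 & donor_frame >= donor_floor
  if (!any(valid))
    stop("no valid pixels: the whole mask falls below the donor floor")
  ratio <- matrix(NA_real_, nrow(donor_frame), ncol(donor_frame))
  ratio[valid] <- fret_frame[valid] / donor_frame[valid]
  structure(list(ratio = ratio,
                 valid = valid,
                 frame_index = if (inherits(mask, "cell_mask")) mask$frame_index else NA_integer_,
                 n_excluded = sum(msk) - sum(valid)),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf("Ratio map: %d valid px (%d excluded by donor floor), range %.4g..%.4g\n",
              sum(x$valid), x$n_excluded,
              min(x$ratio[x$valid]), max(x$ratio[x$valid])))
  invisible(x)
}

#' Whole-cell ratio time series with baseline normalization
#'
#' The whole-cell value at each frame is the unweighted mean of the valid
#' per-pixel ratios.  The baseline is the mean of these values over all
#' pre-stimulus frames (frames strictly before `stimulus_onset_frame`), and
#' the normalized series divides by it, so the normalized pre-stimulus mean
#' is exactly 1.
#'
#' @param ratio_maps list of per-frame [compute_ratio_map()] results, in
#'   chronological order.
#' @param meta an [acquisition_meta()].
#' @return An object of class `"ratio_series"`: list with `frame`, `times_s`,
#'   `mean_ratio`, `normalized_ratio`, `n_valid_px`, `baseline`,
#'   `stimulus_onset_frame`.  Frames without valid pixels carry `NA` and a
#'   warning is raised.
#' @export
whole_cell_series <- function(ratio_maps, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  T_ <- length(ratio_maps)
  onset <- meta$stimulus_onset_frame
  if (onset < 2L || onset > T_)
    stop("stimulus_onset_frame must leave at least one pre-stimulus frame")
  mean_ratio <- vapply(ratio_maps, function(m) {
    v <- m$ratio[m$valid]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  n_valid <- vapply(ratio_maps, function(m) sum(m$valid), integer(1))
  if (anyNA(mean_ratio))
    warning("frame(s) without valid pixels excluded from the series: ",
            paste(which(is.na(mean_ratio)), collapse = ", "))
  pre <- mean_ratio[seq_len(onset - 1L)]
  if (all(is.na(pre))) stop("no usable pre-stimulus frame for the baseline")
  baseline <- mean(pre, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive")
  structure(list(frame = seq_len(T_),
                 times_s = (seq_len(T_) - 1) * meta$frame_interval_s,
                 mean_ratio = mean_ratio,
                 normalized_ratio = mean_ratio / baseline,
                 n_valid_px = n_valid,
                 baseline = baseline,
                 stimulus_onset_frame = onset),
            class = "ratio_series")
}

#' @export
as.data.frame.ratio_series <- function(x, ...) {
  data.frame(frame = x$frame, time_s = x$times_s, mean_ratio = x$mean_ratio,
             normalized_ratio = x$normalized_ratio, n_valid_px = x$n_valid_px)
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf("Whole-cell ratio series: %d frames, baseline %.4f\n",
              length(x$frame), x$baseline))
  cat(sprintf("  final normalized ratio: %.4f (%.1f%% change)\n",
              x$normalized_ratio[length(x$frame)],
              100 * (x$normalized_ratio[length(x$frame)] - 1)))
  invisible(x)
}

#' @export
plot.ratio_series <- function(x, ...) {
  plot(x$times_s / 60, x$normalized_ratio, type = "b", pch = 16,
       xlab = "time (min)", ylab = "normalized FRET/donor ratio", ...)
  graphics::abline(v = (x$stimulus_onset_frame - 1) *
                     diff(x$times_s[1:2]) / 60, lty = 2, col = "grey40")
  invisible(x)
}

#' Read a fluorescence emission spectrum
#'
#' Reads a plain-text two-column table (wavelength in nm, intensity); comma,
#' tab or whitespace separated.  Wavelengths must be strictly ascending and
#' intensities non-negative.
#'
#' @param path path to the spectrum file.
#' @return An object of class `"emission_spectrum"`: data frame with columns
#'   `wavelength_nm` and `intensity`.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- read.table(path, sep = sep, header = header, strip.white = TRUE)
  if (ncol(df) < 2L) stop("spectrum file must have two columns")
  emission_spectrum(df[[1]], df[[2]])
}

#' @param wavelength_nm,intensity numeric vectors of equal length.
#' @rdname read_spectrum
#' @export
emission_spectrum <- function(wavelength_nm, intensity) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity) || length(wavelength_nm) < 2L)
    stop("wavelength and intensity must be equal-length vectors (>= 2 samples)")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly ascending")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
            class = c("emission_spectrum", "data.frame"))
}

#' In-vitro spectral FRET ratio
#'
#' FRET readout of a purified-biosensor emission spectrum as the ratio of
#' donor to acceptor emission intensity, each obtained by linear
#' interpolation between the bracketing spectral samples.  The defaults
#' (475 nm / 515 nm) correspond to a CFP/YFP-family spectrofluorometer
#' readout; the microscope filter pair (475/535) can be selected instead.
#'
#' @param spectrum an [emission_spectrum()].
#' @param donor_nm,acceptor_nm readout wavelengths; both must lie within the
#'   sampled range.
#' @return The scalar intensity ratio `I(donor_nm) / I(acceptor_nm)`.
#' @examples
#' sp <- emission_spectrum(seq(450, 530, 5), rep(100, 17))
#' spectral_fret_ratio(sp)  # 1 for a flat spectrum
#' @export
spectral_fret_ratio <- function(spectrum, donor_nm = 475, acceptor_nm = 515) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  rng <- range(spectrum$wavelength_nm)
  if (donor_nm < rng[1] || donor_nm > rng[2] ||
      acceptor_nm < rng[1] || acceptor_nm > rng[2])
    stop("readout wavelengths must lie within the sampled spectrum")
  i_d <- approx(spectrum$wavelength_nm, spectrum$intensity, xout = donor_nm)$y
  i_a <- approx(spectrum$wavelength_nm, spectrum$intensity, xout = acceptor_nm)$y
  if (i_a == 0) stop("acceptor-band intensity is zero; ratio undefined")
  i_d / i_a
}
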