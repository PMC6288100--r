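#' Estimate background intensity from the four image corners
#'
#' The camera/optical background is taken as the arithmetic mean of all
#' pixels in four square windows anchored at the image corners, every pixel
#' weighted equally.  Estimated per frame and per channel by the pipeline so
#' slow illumination drift over a 30-60 min run is tracked.
#'
#' @param image numeric `H x W` intensity matrix.
#' @param corner_window_px side length of each corner window in pixels.  The
#'   windows must not overlap or cover the image.
#' @return An object of class `"background_estimate"`: list with `value` (the
#'   mean corner intensity) and `corner_window_px`.
#' @examples
#' img <- matrix(100, 8, 8)
#' img[c(1:2, 7:8), c(1:2, 7:8)] <- 10
#' estimate_background(img, 2)$value  # 10
#' @export
estimate_background <- function(image, corner_window_px = 8) {
  w <- as.integer(corner_window_px)
  H <- nrow(image); W <- ncol(image)
  if (is.na(w) || w < 1L) stop("corner_window_px must be >= 1")
  if (2L * w > min(H, W) || 4 * w^2 >= H * W)
    stop("corner windows are too large for a ", H, " x ", W, " image")
  rows <- c(1:w, (H - w + 1L):H)
  cols <- c(1:w, (W - w + 1L):W)
  corners <- image[rows, cols]  # 2w x 2w block = exactly the four windows
  structure(list(value = mean(corners), corner_window_px = w),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("Background estimate: %g (four %d x %d px corner windows)\n",
              x$value, x$corner_window_px, x$corner_window_px))
  invisible(x)
}

#' Subtract a background level, clamping at zero
#'
#' Pixels that fall below the background after subtraction are clamped to 0
#' rather than left negative, so that downstream ratios stay defined.
#'
#' @param image numeric intensity matrix.
#' @param background a [estimate_background()] result or a numeric scalar.
#' @return The background-subtracted matrix.
#' @export
subtract_background <- function(image, background) {
  value <- if (inherits(background, "background_estimate")) background$value
           else as.numeric(background)
  if (length(value) != 1L || !is.finite(value) || value < 0)
    stop("background must be a single non-negative value")
  pmax(image - value, 0)
}

#' Remove speckle noise with a median filter
#'
#' Replaces each pixel with the median of its `(2r+1) x (2r+1)` neighborhood,
#' with edge-replicated borders.  The window always holds an odd number of
#' samples, so the output is an exact order statistic of the input values.
#'
#' @param image numeric intensity matrix.
#' @param radius_px neighborhood radius; the default 1 gives the standard
#'   3 x 3 speckle filter.
#' @return The filtered matrix.
#' @export
despeckle <- function(image, radius_px = 1) {
  r <- as.integer(radius_px)
  if (is.na(r) || r < 1L) stop("radius_px must be >= 1")
  .median_filter_cpp(image, r)
}

# Otsu threshold computed on the nonzero intensities only: after background
# subtraction the clamped zeros would otherwise dominate the histogram.
otsu_nonzero <- function(image, levels = 256L) {
  v <- image[image > 0]
  if (length(v) == 0L) stop("image has no positive pixels")
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1] / 2)  # two-level image: split below the level
  EBImage::otsu(matrix(v, ncol = 1L), range = rng, levels = levels)
}

#' Segment the single cell in a frame
#'
#' Global Otsu threshold on the nonzero intensities, then keep the largest
#' 4-connected component above threshold and fill its interior holes.  The
#' result is invariant to uniform intensity scaling of the input.  Intended
#' to run on the background-subtracted, despeckled donor frame (the channel
#' is configurable in the pipeline).
#'
#' @param image background-subtracted, despeckled intensity matrix with at
#'   least one positive pixel.
#' @param min_cell_area_px smallest component area accepted as a cell.
#' @param previous_mask optional `"cell_mask"` from the previous frame; when
#'   supplied, a frame in which no component reaches `min_cell_area_px`
#'   inherits this mask (flagged `propagated`) instead of failing.
#' @return An object of class `"cell_mask"`: list with `mask` (`H x W`
#'   logical), `area_px`, `frame_index` (filled by the pipeline),
#'   `threshold`, and `propagated`.
#' @export
segment_cell <- function(image, min_cell_area_px = 200, previous_mask = NULL) {
  thr <- otsu_nonzero(image)
  binary <- image > thr
  labels <- EBImage::bwlabel(binary)
  sizes <- tabulate(labels[labels > 0])
  fail <- function() {
    if (!is.null(previous_mask)) {
      stopifnot(inherits(previous_mask, "cell_mask"))
      out <- previous_mask
      out$propagated <- TRUE
      return(out)
    }
    stop(sprintf("no cell found: largest component has %d px (minimum %d)",
                 if (length(sizes)) max(sizes) else 0L,
                 as.integer(min_cell_area_px)))
  }
  if (length(sizes) == 0L || max(sizes) < min_cell_area_px) return(fail())
  keep <- which.max(sizes)
  comp <- labels == keep
  storage.mode(comp) <- "integer"
  filled <- EBImage::fillHull(comp) > 0
  structure(list(mask = matrix(as.logical(filled), nrow(image), ncol(image)),
                 area_px = sum(filled),
                 frame_index = NA_integer_,
                 threshold = as.numeric(thr),
                 propagated = FALSE),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("Cell mask: %d px%s%s\n", x$area_px,
              if (!is.na(x$frame_index)) sprintf(" (frame %d)", x$frame_index) else "",
              if (isTRUE(x$propagated)) " [propagated from previous frame]" else ""))
  invisible(x)
}
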