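#' Ground truth for a synthetic two-channel acquisition
#'
#' Parameter record for the forward model used by [generate_stack()]: a
#' single elliptical cell of uniform donor expression on a dark background,
#' whose FRET/donor ratio field is
#' \deqn{R(x,t) = R_0 \, [1 - d\,E(t)] \, [1 + g\,u(x)\,G(t)]}
#' where `E(t) = 1 - exp(-(t - t0)/tau)` after stimulus onset (0 before),
#' `u(x)` is the normalized flow-axis coordinate inside the cell
#' (`+0.5` at the downstream edge, `-0.5` upstream), and `G(t)` is `E(t)`
#' when the spatial gradient develops with the stimulus
#' (`gradient_mode = "stimulus"`, the default — a flow-induced polarized
#' response, which baseline normalization can detect) or constant 1 for a
#' static, pre-existing gradient (`"static"`, which normalization cancels by
#' construction).  Channels receive a common background offset, optional
#' per-channel exponential photobleaching, shot noise (variance = mean) and
#' additive Gaussian read noise.
#'
#' Defaults emulate the magnitudes of the live-cell recordings this pipeline
#' was designed around: a whole-cell ratio decrease of about 25% of baseline
#' developing over minutes after flow onset, 60-s frames, a few hundred
#' counts of signal on a cooled CCD.
#'
#' @param decay_amplitude fractional whole-cell ratio decrease at plateau,
#'   `d` in `[0, 1)`.
#' @param decay_tau_s exponential time constant of the response, seconds.
#' @param gradient_slope fractional ratio difference per unit normalized
#'   flow-axis position, `g` in `(-1, 1)`; `+g` means downstream-high.
#' @param gradient_mode `"stimulus"` (gradient rises with `E(t)`) or
#'   `"static"` (constant in time).
#' @param donor_baseline donor intensity inside the cell, counts.
#' @param ratio_baseline pre-stimulus FRET/donor ratio `R_0` (> 0).
#' @param background_offset per-channel additive offset, counts; scalar or
#'   named vector `c(donor=, fret=)`.
#' @param bleach_rate per-channel fractional intensity loss per frame;
#'   scalar or `c(donor=, fret=)`; default 0 (off).
#' @param photon_noise logical; Poisson shot noise on each pixel.
#' @param read_noise_sd additive Gaussian read noise, counts.
#' @param stimulus_onset_frame 1-based first stimulated frame (>= 2).
#' @param cell_center,semi_axes,orientation_deg ellipse geometry in pixels /
#'   degrees; `NULL` centers the cell and scales it to the frame.
#' @param seed integer RNG seed for this acquisition.
#' @return An object of class `"fret_truth"`.
#' @export
fret_truth <- function(decay_amplitude = 0.25,
                       decay_tau_s = 300,
                       gradient_slope = 0,
                       gradient_mode = c("stimulus", "static"),
                       donor_baseline = 500,
                       ratio_baseline = 1.8,
                       background_offset = 100,
                       bleach_rate = 0,
                       photon_noise = TRUE,
                       read_noise_sd = 3,
                       stimulus_onset_frame = 6,
                       cell_center = NULL,
                       semi_axes = NULL,
                       orientation_deg = 0,
                       seed = 1) {
  gradient_mode <- match.arg(gradient_mode)
  d <- decay_amplitude; g <- gradient_slope
  if (d < 0 || d >= 1) stop("decay_amplitude must be in [0, 1)")
  if (abs(g) * 0.5 >= 1) stop("gradient_slope too steep: ratio would be nonpositive")
  if ((1 - d) * (1 - abs(g) * 0.5) <= 0 || ratio_baseline <= 0)
    stop("parameters would produce a nonpositive ratio field")
  if (donor_baseline <= 0) stop("donor_baseline must be positive")
  two <- function(x, what) {
    x <- if (length(x) == 1L) c(donor = unname(x), fret = unname(x))
         else c(donor = unname(x[["donor"]]), fret = unname(x[["fret"]]))
    if (any(x < 0)) stop(what, " must be non-negative")
    x
  }
  structure(list(decay_amplitude = d,
                 decay_tau_s = decay_tau_s,
                 gradient_slope = g,
                 gradient_mode = gradient_mode,
                 donor_baseline = donor_baseline,
                 ratio_baseline = ratio_baseline,
                 background_offset = two(background_offset, "background_offset"),
                 bleach_rate = two(bleach_rate, "bleach_rate"),
                 photon_noise = isTRUE(photon_noise),
                 read_noise_sd = read_noise_sd,
                 stimulus_onset_frame = as.integer(stimulus_onset_frame),
                 cell_center = cell_center,
                 semi_axes = semi_axes,
                 orientation_deg = orientation_deg,
                 seed = as.integer(seed)),
            class = "fret_truth")
}

#' @export
print.fret_truth <- function(x, ...) {
  cat(sprintf(paste0("Synthetic ground truth: d = %g (tau %gs), g = %g (%s),\n",
                     "  donor %g cts, ratio %g, offset %g/%g cts, ",
                     "noise %s + sd %g, seed %d\n"),
              x$decay_amplitude, x$decay_tau_s, x$gradient_slope,
              x$gradient_mode, x$donor_baseline, x$ratio_baseline,
              x$background_offset["donor"], x$background_offset["fret"],
              if (x$photon_noise) "shot" else "none", x$read_noise_sd, x$seed))
  invisible(x)
}

# ellipse support and normalized flow coordinate for a given frame geometry
ellipse_geometry <- function(truth, dim, flow_direction, corner_margin_px) {
  H <- dim[1]; W <- dim[2]
  ctr <- truth$cell_center %||% c((H + 1) / 2, (W + 1) / 2)
  # auto geometry: fill the frame while honoring the corner margin
  ax <- truth$semi_axes %||%
    (c(0.80, 0.95) * (c(H, W) / 2 - corner_margin_px - 2))
  th <- truth$orientation_deg * pi / 180
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  xr <- (rr - ctr[1]) * cos(th) + (cc - ctr[2]) * sin(th)
  xc <- -(rr - ctr[1]) * sin(th) + (cc - ctr[2]) * cos(th)
  mask <- (xr / ax[1])^2 + (xc / ax[2])^2 <= 1
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ellipse contains no pixels")
  if (min(idx[, 1]) <= corner_margin_px || max(idx[, 1]) > H - corner_margin_px ||
      min(idx[, 2]) <= corner_margin_px || max(idx[, 2]) > W - corner_margin_px)
    stop("cell must keep a ", corner_margin_px,
         "-px margin so corner windows stay background")
  p <- (idx[, 1] - 1) * flow_direction[1] + (idx[, 2] - 1) * flow_direction[2]
  rngp <- range(p)
  u <- (p - (rngp[1] + rngp[2]) / 2) / (rngp[2] - rngp[1])  # [-0.5, 0.5]
  u_img <- matrix(0, H, W)
  u_img[mask] <- u
  list(mask = mask, u = u_img, center = ctr, semi_axes = ax)
}

stim_envelope <- function(truth, n_frames, frame_interval_s) {
  t0 <- truth$stimulus_onset_frame
  f <- seq_len(n_frames)
  E <- ifelse(f >= t0, 1 - exp(-((f - t0) * frame_interval_s) / truth$decay_tau_s), 0)
  E
}

#' Generate a synthetic two-channel acquisition
#'
#' Forward model for one cell (see [fret_truth()] for the ratio field).
#' Inside the cell the donor channel is `donor_baseline` times its bleach
#' factor; the FRET channel is the ratio field times the donor signal times
#' the FRET-channel bleach factor.  The per-channel background offset is
#' added everywhere, then shot noise (Poisson, variance = mean) and Gaussian
#' read noise are sampled with per-frame RNG streams derived from the
#' truth's seed, and intensities are clamped at zero.  Re-running with the
#' same truth reproduces the stack bit for bit.
#'
#' @param truth a [fret_truth()].
#' @param n_frames number of frames (>= 2).
#' @param dim image size `c(H, W)` in pixels.
#' @param frame_interval_s frame interval, seconds.
#' @param flow_direction flow direction `(d_row, d_col)`; normalized.
#' @param corner_margin_px margin the cell must keep from every border so
#'   that corner background windows contain only background.
#' @param keep_clean if `TRUE`, attach the noise-free ratio field, cell mask
#'   and flow coordinate as `attr(, "clean")` for recovery oracles.
#' @return An `"acquisition_stack"` with the (geometry-completed) truth
#'   attached as `attr(, "truth")`.
#' @examples
#' tr <- fret_truth(photon_noise = FALSE, read_noise_sd = 0, seed = 7)
#' stk <- generate_stack(tr, n_frames = 8, dim = c(64, 64))
#' @export
generate_stack <- function(truth, n_frames, dim = c(128, 128),
                           frame_interval_s = 60,
                           flow_direction = c(0, 1),
                           corner_margin_px = 10,
                           keep_clean = FALSE) {
  stopifnot(inherits(truth, "fret_truth"), n_frames >= 2)
  meta <- acquisition_meta(flow_direction, truth$stimulus_onset_frame,
                           frame_interval_s)
  geo <- ellipse_geometry(truth, dim, meta$flow_direction, corner_margin_px)
  truth$cell_center <- geo$center
  truth$semi_axes <- geo$semi_axes
  E <- stim_envelope(truth, n_frames, frame_interval_s)
  G <- if (truth$gradient_mode == "stimulus") E else rep(1, n_frames)
  H <- dim[1]; W <- dim[2]
  donor <- array(0, c(H, W, n_frames))
  fret <- array(0, c(H, W, n_frames))
  clean_ratio <- if (keep_clean) array(NA_real_, c(H, W, n_frames)) else NULL
  m <- geo$mask
  for (f in seq_len(n_frames)) {
    ratio_f <- truth$ratio_baseline * (1 - truth$decay_amplitude * E[f]) *
      (1 + truth$gradient_slope * geo$u * G[f])
    if (any(ratio_f[m] <= 0)) stop("nonpositive ratio generated; check d and g")
    bl_d <- (1 - truth$bleach_rate["donor"])^(f - 1)
    bl_f <- (1 - truth$bleach_rate["fret"])^(f - 1)
    d_img <- matrix(0, H, W); f_img <- matrix(0, H, W)
    d_img[m] <- truth$donor_baseline * bl_d
    f_img[m] <- ratio_f[m] * truth$donor_baseline * bl_f
    d_img <- d_img + truth$background_offset["donor"]
    f_img <- f_img + truth$background_offset["fret"]
    if (truth$photon_noise || truth$read_noise_sd > 0) {
      set.seed((truth$seed + 104729L * f) %% 2147483629L)
      if (truth$photon_noise) {
        d_img[] <- rpois(length(d_img), d_img)
        f_img[] <- rpois(length(f_img), f_img)
      }
      if (truth$read_noise_sd > 0) {
        d_img <- d_img + rnorm(length(d_img), 0, truth$read_noise_sd)
        f_img <- f_img + rnorm(length(f_img), 0, truth$read_noise_sd)
      }
      d_img <- pmax(d_img, 0)
      f_img <- pmax(f_img, 0)
    }
    donor[, , f] <- d_img
    fret[, , f] <- f_img
    if (keep_clean) {
      page <- matrix(NA_real_, H, W)
      page[m] <- ratio_f[m]
      clean_ratio[, , f] <- page
    }
  }
  stack <- new_acquisition_stack(donor, fret, meta)
  attr(stack, "truth") <- truth
  if (keep_clean)
    attr(stack, "clean") <- list(mask = m, u = geo$u, ratio = clean_ratio,
                                 envelope = E)
  stack
}

#' Generate a cohort of replicate cells
#'
#' Draws `n_cells` per-cell ground truths around a condition's parameters —
#' decay amplitude and gradient slope jittered by `between_cell_sd`
#' (truncated to their valid ranges), geometry jittered in center, size and
#' orientation — and generates one acquisition per cell.  Per-cell seeds and
#' parameter draws derive deterministically from `master_seed`, so a cohort
#' is reproducible piecewise: cell `i` is the same stack no matter how many
#' cells are requested.
#'
#' @param truth condition-level [fret_truth()].
#' @param n_cells number of replicate cells (>= 2).
#' @param n_frames,dim,frame_interval_s,flow_direction,corner_margin_px
#'   passed to [generate_stack()].
#' @param between_cell_sd standard deviation of the per-cell draws of
#'   `decay_amplitude` and `gradient_slope` (0 = all cells share the
#'   condition's parameters, differing only in geometry and noise seed).
#' @param master_seed seed from which all per-cell seeds derive.
#' @return List of `"acquisition_stack"`s, each with its own truth attached.
#' @export
generate_cohort <- function(truth, n_cells, n_frames, dim = c(128, 128),
                            between_cell_sd = 0.03,
                            frame_interval_s = 60,
                            flow_direction = c(0, 1),
                            corner_margin_px = 10,
                            master_seed = truth$seed) {
  stopifnot(inherits(truth, "fret_truth"), n_cells >= 2)
  H <- dim[1]; W <- dim[2]
  lapply(seq_len(n_cells), function(i) {
    cell_seed <- (as.integer(master_seed) + 7919L * i) %% 2147483629L
    set.seed(cell_seed)
    tr <- truth
    tr$seed <- cell_seed
    if (between_cell_sd > 0) {
      tr$decay_amplitude <- min(max(rnorm(1, truth$decay_amplitude,
                                          between_cell_sd), 0), 0.95)
      tr$gradient_slope <- min(max(rnorm(1, truth$gradient_slope,
                                         between_cell_sd), -1.8), 1.8)
    }
    # geometry jitter: position, size, orientation (auto base keeps a 10%
    # reserve so the jitter cannot break the corner margin)
    tr$cell_center <- round(c((H + 1) / 2 + runif(1, -3, 3),
                              (W + 1) / 2 + runif(1, -3, 3)), 2)
    base_ax <- truth$semi_axes %||%
      (0.9 * c(0.80, 0.95) * (dim / 2 - corner_margin_px - 2))
    tr$semi_axes <- base_ax * runif(2, 0.9, 1.05)
    tr$orientation_deg <- runif(1, -10, 10)
    generate_stack(tr, n_frames, dim, frame_interval_s, flow_direction,
                   corner_margin_px)
  })
}

#' Write a ground-truth record as JSON
#'
#' @param truth a [fret_truth()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "fret_truth"))
  out <- unclass(truth)
  out$background_offset <- as.list(out$background_offset)
  out$bleach_rate <- as.list(out$bleach_rate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(fret_truth, raw[!vapply(raw, is.null, logical(1))])
}
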