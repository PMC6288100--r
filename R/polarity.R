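# Scalar projections of the valid pixels onto the flow axis, 0-based
# pixel coordinates (row-major, origin top-left).
flow_projection <- function(valid, flow_direction) {
  idx <- which(valid, arr.ind = TRUE)
  (idx[, 1] - 1) * flow_direction[1] + (idx[, 2] - 1) * flow_direction[2]
}

#' Divide a cell into equal-width bins along the flow axis
#'
#' Each valid pixel is projected onto the flow axis; the projection range
#' over the mask is split into `n_bins` equal-width intervals (half-open,
#' the downstream-most interval closed).  Bin 1 holds the largest
#' projections — the downstream extreme, where the flow exits the cell — and
#' bin `n_bins` the upstream extreme.  A bin's percentage is the summed
#' ratio value of its pixels as a share of the whole-cell sum, so the 50
#' percentages always total 100.
#'
#' Bin assignment works in the centered coordinate
#' `q = (p - mid) / half_range`, and the half-open boundary convention is
#' applied in a canonical axis orientation (axis sign chosen so the first
#' nonzero component of the direction is positive).  On integer pixel grids
#' pixels regularly fall exactly on bin edges whatever the flow angle; the
#' canonical convention assigns them identically for `d` and `-d`, so
#' flipping `flow_direction` reverses the profile bin-for-bin, exactly.
#'
#' @param ratio_map a [compute_ratio_map()] result.
#' @param flow_direction unit 2-vector `(d_row, d_col)`, e.g. from
#'   [acquisition_meta()].
#' @param n_bins number of bins (the standard analysis uses 50).
#' @param weight optional `H x W` matrix of per-pixel weights replacing the
#'   ratio values (used for the raw-intensity weighting mode).
#' @param proj_range optional fixed projection range `c(min, max)` (the
#'   fixed-edges mode); default recomputes the range from this frame's mask.
#' @return An object of class `"spatial_profile"`: list with `percentages`
#'   (length `n_bins`, summing to 100), `bin_edges` (`n_bins + 1` projections,
#'   downstream edge first), `n_pixels` per bin, `frame_index`, and
#'   `normalized_percentages` (`NULL` until [normalize_profiles()]).
#' @export
bin_along_flow <- function(ratio_map, flow_direction, n_bins = 50,
                           weight = NULL, proj_range = NULL) {
  stopifnot(inherits(ratio_map, "ratio_map"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2")
  flow_direction <- as.numeric(flow_direction)
  if (length(flow_direction) != 2L ||
      abs(sqrt(sum(flow_direction^2)) - 1) > 1e-9)
    stop("flow_direction must be a unit 2-vector")
  valid <- ratio_map$valid
  if (!any(valid)) stop("empty ratio map")
  w <- if (is.null(weight)) ratio_map$ratio[valid] else weight[valid]
  if (any(!is.finite(w))) stop("non-finite weights on valid pixels")
  # canonicalize the axis orientation so that d and -d run the identical
  # computation (bin indices remapped afterwards): flip reversal is then
  # exact by construction, boundary pixels included
  flipped <- flow_direction[1] < 0 ||
    (flow_direction[1] == 0 && flow_direction[2] < 0)
  d_can <- if (flipped) -flow_direction else flow_direction
  p <- flow_projection(valid, d_can)
  rng <- if (is.null(proj_range)) range(p) else {
    r <- as.numeric(proj_range)
    if (flipped) sort(-r) else r
  }
  mid <- (rng[1] + rng[2]) / 2
  half <- (rng[2] - rng[1]) / 2
  if (half <= n_bins * .Machine$double.eps * max(1, abs(mid)))
    stop("degenerate projection range: mask too thin along the flow axis")
  q <- (p - mid) / half                      # q in [-1, 1], +1 downstream
  # pixels on integer grids regularly land exactly on bin edges; snap
  # within 1e-9 of an edge so the assignment is stable against the last-ulp
  # differences of algebraically equivalent projection formulas
  k <- floor(n_bins * (1 + q) / 2 + 1e-9)    # 0-based from upstream
  k[k < 0] <- 0
  k[k > n_bins - 1] <- n_bins - 1
  bin <- n_bins - k                          # 1 = downstream (canonical axis)
  if (flipped) bin <- n_bins + 1L - bin
  sums <- numeric(n_bins)
  npx <- integer(n_bins)
  ord <- order(bin, w)  # value-sorted within bins: summation order canonical
  gs <- rowsum(w[ord], bin[ord])
  present <- as.integer(rownames(gs))
  sums[present] <- gs[, 1]
  npx[present] <- tabulate(bin, nbins = n_bins)[present]
  total <- sum(sums)
  if (total <= 0) stop("total ratio weight must be positive")
  edges <- mid + half * (1 - 2 * (0:n_bins) / n_bins)  # canonical axis
  if (flipped) edges <- -rev(edges)          # downstream edge first
  structure(list(percentages = 100 * sums / total,
                 bin_edges = edges,
                 n_pixels = npx,
                 frame_index = ratio_map$frame_index,
                 normalized_percentages = NULL),
            class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  n <- length(x$percentages)
  cat(sprintf("Spatial profile: %d bins (1 = downstream), %d px\n",
              n, sum(x$n_pixels)))
  cat(sprintf("  downstream 5-bin mean %.3f%%, upstream 5-bin mean %.3f%%\n",
              mean(x$percentages[1:5]), mean(x$percentages[(n - 4):n])))
  invisible(x)
}

#' Normalize per-bin traces by their pre-stimulus means
#'
#' Each bin's percentage trace is divided by its own mean over the
#' pre-stimulus frames, so every bin's normalized pre-stimulus mean is
#' exactly 1 and post-stimulus values read as fold change of that region.
#' Bins with zero pre-stimulus signal (e.g. empty bins of a concave mask)
#' are flagged invalid and carried as `NA`.
#'
#' @param profiles list of per-frame [bin_along_flow()] profiles covering
#'   frames `1..T` in order.
#' @param stimulus_onset_frame 1-based index of the first stimulated frame.
#' @return The list of profiles with `normalized_percentages` filled in; the
#'   indices of invalid bins are attached as `attr(, "invalid_bins")`.
#' @export
normalize_profiles <- function(profiles, stimulus_onset_frame) {
  onset <- as.integer(stimulus_onset_frame)
  T_ <- length(profiles)
  if (onset < 2L || onset > T_)
    stop("need at least one pre-stimulus frame")
  P <- vapply(profiles, function(p) p$percentages,
              numeric(length(profiles[[1]]$percentages)))
  pre_mean <- rowMeans(P[, seq_len(onset - 1L), drop = FALSE])
  invalid <- which(pre_mean <= 0)
  norm <- P / pre_mean
  if (length(invalid)) norm[invalid, ] <- NA_real_
  for (t in seq_len(T_)) profiles[[t]]$normalized_percentages <- norm[, t]
  attr(profiles, "invalid_bins") <- invalid
  profiles
}

#' Upstream and downstream summaries of a profile
#'
#' Averages the first `n_regions` bins (downstream) and the last `n_regions`
#' bins (upstream) of the normalized profile; averaging several edge regions
#' damps the discreteness of any single thin bin.  Invalid (`NA`) bins among
#' the five are dropped; if all are invalid an error is raised.
#'
#' @param profile a [bin_along_flow()] profile with normalized percentages
#'   (see [normalize_profiles()]); set `normalized = FALSE` to summarize the
#'   raw percentages instead.
#' @param n_regions bins averaged at each extreme (default 5).
#' @param normalized summarize normalized (default) or raw percentages.
#' @return Named numeric vector `c(down_mean, up_mean)`.
#' @export
updown_summary <- function(profile, n_regions = 5, normalized = TRUE) {
  stopifnot(inherits(profile, "spatial_profile"))
  vals <- if (normalized) profile$normalized_percentages else profile$percentages
  if (is.null(vals))
    stop("profile has no normalized percentages; run normalize_profiles() first")
  n <- length(vals)
  stopifnot(n_regions >= 1, 2 * n_regions <= n)
  down <- vals[seq_len(n_regions)]
  up <- vals[seq.int(n - n_regions + 1L, n)]
  if (all(is.na(down)) || all(is.na(up)))
    stop("all edge bins invalid; cannot summarize")
  c(down_mean = mean(down, na.rm = TRUE), up_mean = mean(up, na.rm = TRUE))
}

#' Polarity test across replicate cells
#'
#' Two-tailed two-sample t-test comparing the per-cell upstream summaries
#' with the per-cell downstream summaries at one time point (the reference
#' analysis uses 30 min after flow onset).  Cells, not pixels, are the
#' replication unit.  Polarity is called when `p < alpha`.
#'
#' @param up_values,down_values per-cell upstream / downstream summaries
#'   (length >= 2 each).
#' @param alpha significance level for the polarity call.
#' @param variant `"welch"` (unequal variances, default) or `"student"`
#'   (pooled variance).
#' @return An object of class `c("polarity_test", "htest")` with fields
#'   `statistic` (t, for up - down), `parameter` (df), `p.value`, `estimate`
#'   (`up_mean`, `down_mean`), `polar`, `alpha`, `n_cells`, `variant`.
#' @examples
#' polarity_test(c(1.00, 1.02, 0.98), c(2.00, 2.02, 1.98))
#' @export
polarity_test <- function(up_values, down_values, alpha = 0.05,
                          variant = c("welch", "student")) {
  variant <- match.arg(variant)
  up <- as.numeric(up_values); down <- as.numeric(down_values)
  if (length(up) < 2L || length(down) < 2L)
    stop("need at least 2 cells per group")
  if (anyNA(up) || anyNA(down)) stop("missing values in group summaries")
  if (sd(up) == 0 && sd(down) == 0) {
    # degenerate: both groups constant
    same <- isTRUE(all.equal(mean(up), mean(down)))
    out <- list(statistic = c(t = if (same) 0 else sign(mean(up) - mean(down)) * Inf),
                parameter = c(df = length(up) + length(down) - 2),
                p.value = if (same) 1 else 0,
                estimate = c(up_mean = mean(up), down_mean = mean(down)),
                method = "degenerate two-sample comparison (zero variance)",
                data.name = "up_values vs down_values")
  } else {
    tt <- t.test(up, down, alternative = "two.sided",
                 var.equal = (variant == "student"))
    out <- list(statistic = tt$statistic,
                parameter = tt$parameter,
                p.value = tt$p.value,
                estimate = c(up_mean = unname(tt$estimate[1]),
                             down_mean = unname(tt$estimate[2])),
                method = tt$method,
                data.name = "up_values vs down_values")
  }
  out$alpha <- alpha
  out$polar <- out$p.value < alpha
  out$variant <- variant
  out$n_cells <- c(up = length(up), down = length(down))
  class(out) <- c("polarity_test", "htest")
  out
}

#' @export
print.polarity_test <- function(x, ...) {
  y <- x
  class(y) <- "htest"
  print(y, ...)
  cat(sprintf("polarity: %s (alpha = %g, %s t-test, n = %d up / %d down cells)\n",
              if (x$polar) "PRESENT" else "absent", x$alpha, x$variant,
              x$n_cells["up"], x$n_cells["down"]))
  invisible(x)
}

#' Export polarity results as JSON
#'
#' @param x a [polarity_test()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_polarity_json <- function(x, path) {
  stopifnot(inherits(x, "polarity_test"))
  jsonlite::write_json(
    list(down_mean = unname(x$estimate["down_mean"]),
         up_mean = unname(x$estimate["up_mean"]),
         t = unname(x$statistic),
         df = unname(x$parameter),
         p = x$p.value,
         polar = x$polar,
         alpha = x$alpha,
         n_cells = unname(x$n_cells),
         variant = x$variant),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
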