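# Independent brute-force oracles: simple loops and quadrature, sharing no
# code path with the package implementations they check.

oracle_background <- function(image, w) {
  H <- nrow(image); W <- ncol(image)
  px <- c()
  for (i in seq_len(w)) for (j in seq_len(w)) {
    px <- c(px, image[i, j], image[i, W - w + j],
            image[H - w + i, j], image[H - w + i, W - w + j])
  }
  mean(px)
}

oracle_median_filter <- function(image, r) {
  H <- nrow(image); W <- ncol(image)
  out <- image
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax(i + (-r:r), 1), H)
    jj <- pmin(pmax(j + (-r:r), 1), W)
    out[i, j] <- median(image[ii, jj])
  }
  out
}

oracle_ratio <- function(fret, donor, mask, floor = 0) {
  out <- matrix(NA_real_, nrow(donor), ncol(donor))
  for (i in seq_len(nrow(donor))) for (j in seq_len(ncol(donor))) {
    if (mask[i, j] && donor[i, j] > 0 && donor[i, j] >= floor)
      out[i, j] <- fret[i, j] / donor[i, j]
  }
  out
}

# Per-pixel assignment loop; arithmetic deliberately phrased differently from
# the implementation (offset-from-minimum instead of centered coordinate).
# Applies the same documented boundary convention — intervals are half-open
# along the canonical axis orientation (sign chosen so the first nonzero
# component is positive), which on integer pixel grids regularly places
# pixels exactly on bin edges whatever the flow angle.
oracle_bin <- function(ratio, valid, flow, n = 50) {
  flip <- flow[1] < 0 || (flow[1] == 0 && flow[2] < 0)
  dc <- if (flip) -flow else flow
  idx <- which(valid, arr.ind = TRUE)
  p <- (idx[, 1] - 1) * dc[1] + (idx[, 2] - 1) * dc[2]
  w <- ratio[valid]
  lo <- min(p); hi <- max(p)
  sums <- numeric(n)
  for (k in seq_along(p)) {
    # same 1e-9 edge snap as the documented convention
    j <- floor(n * (p[k] - lo) / (hi - lo) + 1e-9)  # 0-based, canonical upstream
    if (j > n - 1) j <- n - 1
    if (j < 0) j <- 0
    i <- n - j                               # 1 = canonical downstream
    if (flip) i <- n + 1 - i
    sums[i] <- sums[i] + w[k]
  }
  100 * sums / sum(sums)
}

# two-sided p-value from numerical integration of the t density
oracle_t_pvalue <- function(t_stat, df) {
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
}

oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = oracle_t_pvalue(t_stat, df))
}

# hole filling by flood-filling the complement from the borders (4-connected)
oracle_fill_holes <- function(comp) {
  H <- nrow(comp); W <- ncol(comp)
  grow <- function(b) {
    b |
      rbind(b[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, b[-H, , drop = FALSE]) |
      cbind(b[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, b[, -W, drop = FALSE])
  }
  outside <- !comp & (row(comp) == 1 | row(comp) == H |
                        col(comp) == 1 | col(comp) == W)
  repeat {
    nxt <- grow(outside) & !comp
    if (identical(nxt, outside)) break
    outside <- nxt
  }
  comp | (!comp & !outside)
}
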