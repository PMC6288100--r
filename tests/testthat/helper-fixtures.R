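# Small fixtures built in code.

# random blob-free mask + positive ratio values on it
random_ratio_map <- function(H = 32, W = 32, n_px = 200, frame_index = 1L) {
  valid <- matrix(FALSE, H, W)
  idx <- unique(cbind(sample.int(H, n_px, replace = TRUE),
                      sample.int(W, n_px, replace = TRUE)))
  valid[idx] <- TRUE
  ratio <- matrix(NA_real_, H, W)
  ratio[valid] <- runif(sum(valid), 0.2, 3)
  structure(list(ratio = ratio, valid = valid,
                 frame_index = as.integer(frame_index), n_excluded = 0L),
            class = "ratio_map")
}

as_ratio_map <- function(ratio, valid, frame_index = 1L) {
  structure(list(ratio = ratio, valid = valid,
                 frame_index = as.integer(frame_index),
                 n_excluded = 0L),
            class = "ratio_map")
}

ellipse_mask <- function(H, W, ctr, ax) {
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
}

# rotate a matrix and a flow vector together by 90 degrees:
# (r, c) -> (c, H + 1 - r), d -> (d_col, -d_row)
rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]
rot90_flow <- function(d) c(d[2], -d[1])

write_uint16_tiff <- function(pages, path) {
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16, compression = "none")
  path
}
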