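test_that("ratio maps divide channel intensities and guard the donor floor", {
  msk <- matrix(TRUE, 6, 6)
  rm_ <- compute_ratio_map(matrix(30, 6, 6), matrix(20, 6, 6), msk)
  expect_true(all(rm_$ratio[rm_$valid] == 1.5))
  expect_identical(sum(rm_$valid), 36L)

  # a zero-donor pixel inside the mask is excluded, not infinite
  donor <- matrix(20, 6, 6); donor[3, 3] <- 0
  rm_ <- compute_ratio_map(matrix(30, 6, 6), donor, msk)
  expect_false(rm_$valid[3, 3])
  expect_identical(rm_$n_excluded, 1L)
  expect_true(all(is.finite(rm_$ratio[rm_$valid])))

  # elementwise oracle on random frames, with a floor
  set.seed(21)
  for (i in 1:10) {
    fret <- matrix(runif(256, 0, 50), 16, 16)
    donor <- matrix(runif(256, 0, 30), 16, 16)
    msk <- matrix(runif(256) < 0.7, 16, 16)
    rm_ <- compute_ratio_map(fret, donor, msk, donor_floor = 5)
    expect_identical(rm_$ratio, oracle_ratio(fret, donor, msk, 5))
  }
  expect_error(compute_ratio_map(fret, donor, msk, donor_floor = 1e5),
               "no valid pixels")
})

test_that("whole-cell series normalizes by the pre-stimulus baseline", {
  meta <- acquisition_meta(c(0, 1), 4)
  const_map <- function(v, f) {
    msk <- matrix(TRUE, 5, 5)
    as_ratio_map(matrix(v, 5, 5), msk, f)
  }
  maps <- c(lapply(1:3, function(f) const_map(1.5, f)), list(const_map(1.2, 4)))
  s <- whole_cell_series(maps, meta)
  expect_equal(s$normalized_ratio, c(1, 1, 1, 0.8))
  expect_equal(s$times_s, c(0, 60, 120, 180))

  # identical frames normalize to exactly 1
  maps <- lapply(1:4, function(f) const_map(1.37, f))
  s <- whole_cell_series(maps, meta)
  expect_true(all(s$normalized_ratio == 1))

  # pre-stimulus normalized mean is 1 to 1e-9 on random maps
  set.seed(22)
  maps <- lapply(1:6, function(f) random_ratio_map(16, 16, 150, f))
  s <- whole_cell_series(maps, acquisition_meta(c(0, 1), 4))
  expect_equal(mean(s$normalized_ratio[1:3]), 1, tolerance = 1e-9)

  # a frame without valid pixels is flagged NA with a warning
  empty <- as_ratio_map(matrix(NA_real_, 16, 16), matrix(FALSE, 16, 16), 5)
  expect_warning(s <- whole_cell_series(c(maps[1:4], list(empty), maps[6]),
                                        acquisition_meta(c(0, 1), 4)),
                 "without valid pixels")
  expect_true(is.na(s$mean_ratio[5]))
})

test_that("noise-free synthetic decay is recovered in closed form", {
  # tiny tau: envelope is exactly 1 from the first post-stimulus frame on
  tr <- fret_truth(decay_amplitude = 0.3, decay_tau_s = 1e-9,
                   gradient_slope = 0, photon_noise = FALSE,
                   read_noise_sd = 0, background_offset = 0,
                   stimulus_onset_frame = 3, seed = 5)
  stk <- generate_stack(tr, n_frames = 6, dim = c(64, 64), keep_clean = TRUE)
  cl <- attr(stk, "clean")
  maps <- lapply(1:6, function(f) {
    compute_ratio_map(stk$fret[, , f], stk$donor[, , f],
                      structure(list(mask = cl$mask, frame_index = f),
                                class = "cell_mask"))
  })
  s <- whole_cell_series(maps, stk$meta)
  # first post-onset frame still has envelope 0; plateau from the next frame
  expect_equal(s$normalized_ratio[4:6], rep(1 - 0.3, 3), tolerance = 1e-12)
  expect_equal(s$normalized_ratio[1:2], c(1, 1), tolerance = 1e-12)
})

test_that("ratio operations are scale-equivariant", {
  set.seed(23)
  fret <- matrix(runif(256, 10, 50), 16, 16)
  donor <- matrix(runif(256, 10, 30), 16, 16)
  msk <- matrix(TRUE, 16, 16)
  r1 <- compute_ratio_map(fret, donor, msk)
  rk <- compute_ratio_map(fret * 3, donor, msk)
  expect_equal(rk$ratio[msk], 3 * r1$ratio[msk], tolerance = 1e-12)
  rboth <- compute_ratio_map(fret * 3, donor * 3, msk)
  expect_equal(rboth$ratio[msk], r1$ratio[msk], tolerance = 1e-12)
})

test_that("spectral ratio interpolates the emission spectrum linearly", {
  sp <- emission_spectrum(seq(450, 530, 5), rep(100, 17))
  expect_identical(spectral_fret_ratio(sp), 1)

  wl <- c(450, 475, 500, 515, 530)
  sp <- emission_spectrum(wl, c(50, 200, 150, 100, 80))
  expect_identical(spectral_fret_ratio(sp), 2)

  # 5-nm grid missing the readout points: hand-computed linear interpolation
  wl <- seq(451, 531, 5)            # brackets 475 between 471 and 476, etc.
  inten <- 2 * wl - 800             # linear ramp
  sp <- emission_spectrum(wl, inten)
  expect_equal(spectral_fret_ratio(sp), (2 * 475 - 800) / (2 * 515 - 800),
               tolerance = 1e-12)

  # acceptor-band zero is an error; out-of-range readout is an error
  sp0 <- emission_spectrum(c(475, 515), c(10, 0))
  expect_error(spectral_fret_ratio(sp0), "zero")
  expect_error(spectral_fret_ratio(sp, donor_nm = 400), "within the sampled")
  expect_error(emission_spectrum(c(475, 470), c(1, 1)), "ascending")
})
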