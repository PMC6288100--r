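test_that("noise-free generator obeys its closed form", {
  # d = 0, g = 0, no noise, no offset: fret/donor is the baseline ratio
  # everywhere on the cell, every frame
  tr <- fret_truth(decay_amplitude = 0, gradient_slope = 0,
                   photon_noise = FALSE, read_noise_sd = 0,
                   background_offset = 0, stimulus_onset_frame = 3,
                   ratio_baseline = 1.8, seed = 1)
  stk <- generate_stack(tr, 5, dim = c(64, 64), keep_clean = TRUE)
  m <- attr(stk, "clean")$mask
  for (f in 1:5) {
    r <- stk$fret[, , f][m] / stk$donor[, , f][m]
    expect_equal(r, rep(1.8, sum(m)), tolerance = 1e-12)
    expect_true(all(stk$donor[, , f][!m] == 0))
  }

  # static gradient g = 0.4: downstream/upstream edge ratio = 1.2/0.8 = 1.5
  tr <- fret_truth(decay_amplitude = 0, gradient_slope = 0.4,
                   gradient_mode = "static", photon_noise = FALSE,
                   read_noise_sd = 0, background_offset = 0,
                   stimulus_onset_frame = 3, seed = 1)
  stk <- generate_stack(tr, 3, dim = c(64, 64), keep_clean = TRUE)
  cl <- attr(stk, "clean")
  u <- cl$u[cl$mask]
  ratio <- stk$fret[, , 1][cl$mask] / stk$donor[, , 1][cl$mask]
  expect_equal(ratio[which.max(u)] / ratio[which.min(u)], 1.5,
               tolerance = 1e-9)

  # stimulus-mode gradient is absent before onset and grows afterwards
  tr <- fret_truth(decay_amplitude = 0, gradient_slope = 0.4,
                   gradient_mode = "stimulus", photon_noise = FALSE,
                   read_noise_sd = 0, background_offset = 0,
                   stimulus_onset_frame = 3, seed = 1)
  stk <- generate_stack(tr, 6, dim = c(64, 64), keep_clean = TRUE)
  cl <- attr(stk, "clean")
  spread <- function(f) diff(range(cl$ratio[, , f][cl$mask]))
  expect_equal(spread(1), 0)
  expect_equal(spread(2), 0)
  expect_gt(spread(4), 0)
  expect_gt(spread(6), spread(4))

  expect_error(fret_truth(decay_amplitude = 1.2), "decay_amplitude")
  expect_error(fret_truth(gradient_slope = 2.5), "gradient_slope")
})

test_that("generation is deterministic given the seed", {
  tr <- fret_truth(seed = 99, stimulus_onset_frame = 3)
  a <- generate_stack(tr, 4, dim = c(64, 64))
  b <- generate_stack(tr, 4, dim = c(64, 64))
  expect_identical(a$donor, b$donor)
  expect_identical(a$fret, b$fret)
  tr2 <- fret_truth(seed = 100, stimulus_onset_frame = 3)
  c_ <- generate_stack(tr2, 4, dim = c(64, 64))
  expect_false(identical(a$donor, c_$donor))
})

test_that("corner windows of generated images hold only background", {
  # geometry margin keeps the cell away from the corners, so the corner
  # estimator is an unbiased background reader: 100-seed mean within 1%
  est <- vapply(1:100, function(s) {
    tr <- fret_truth(seed = s, stimulus_onset_frame = 2,
                     background_offset = 100)
    stk <- generate_stack(tr, 2, dim = c(48, 48), corner_margin_px = 8)
    estimate_background(stk$donor[, , 1], 8)$value
  }, numeric(1))
  expect_lt(abs(mean(est) - 100) / 100, 0.01)
})

test_that("cohorts are reproducible and draw around the condition", {
  tr <- fret_truth(decay_amplitude = 0.25, gradient_slope = 0.1,
                   stimulus_onset_frame = 2, semi_axes = c(10, 12), seed = 7)
  coh1 <- generate_cohort(tr, 4, n_frames = 2, dim = c(48, 48),
                          between_cell_sd = 0, corner_margin_px = 6)
  coh2 <- generate_cohort(tr, 4, n_frames = 2, dim = c(48, 48),
                          between_cell_sd = 0, corner_margin_px = 6)
  for (i in 1:4) expect_identical(coh1[[i]]$donor, coh2[[i]]$donor)

  # sd = 0: all cells share the condition's d and g, geometry/seed differ
  truths <- lapply(coh1, attr, "truth")
  expect_true(all(vapply(truths, `[[`, numeric(1), "decay_amplitude") == 0.25))
  expect_true(all(vapply(truths, `[[`, numeric(1), "gradient_slope") == 0.1))
  expect_gt(length(unique(vapply(truths, `[[`, numeric(1), "seed"))), 1)
  centers <- vapply(truths, function(t) t$cell_center[1], numeric(1))
  expect_gt(length(unique(centers)), 1)

  # law of large numbers: mean per-cell d over n = 1000 within 3 SE
  sd_d <- 0.04
  coh <- generate_cohort(tr, 1000, n_frames = 2, dim = c(40, 40),
                         between_cell_sd = sd_d, corner_margin_px = 4)
  ds <- vapply(coh, function(s) attr(s, "truth")$decay_amplitude, numeric(1))
  expect_lt(abs(mean(ds) - 0.25), 3 * sd_d / sqrt(1000))
})
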