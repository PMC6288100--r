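test_that("flow-axis binning: symmetry, monotonicity, conservation", {
  # uniform rectangle, flow parallel to a side: every bin gets 2%
  valid <- matrix(FALSE, 50, 120); valid[10:40, 11:110] <- TRUE
  ratio <- matrix(NA_real_, 50, 120); ratio[valid] <- 1
  prof <- bin_along_flow(as_ratio_map(ratio, valid), c(0, 1))
  expect_equal(prof$percentages, rep(2, 50), tolerance = 1e-9)
  expect_equal(sum(prof$percentages), 100, tolerance = 1e-9)
  expect_equal(prof$n_pixels, rep(31L * 2L, 50))

  # ratio linear in the projection, downstream (bin 1) highest:
  # strictly decreasing percentages
  cc <- matrix(rep(1:120, each = 50), 50, 120)
  ratio[valid] <- 1 + (cc[valid] - 11) / 99   # 1 upstream edge -> 2 downstream
  prof <- bin_along_flow(as_ratio_map(ratio, valid), c(0, 1))
  expect_true(all(diff(prof$percentages) < 0))

  expect_error(bin_along_flow(as_ratio_map(ratio, valid), c(0, 2)), "unit")
  thin <- matrix(FALSE, 50, 120); thin[, 60] <- TRUE
  r2 <- matrix(NA_real_, 50, 120); r2[thin] <- 1
  expect_error(bin_along_flow(as_ratio_map(r2, thin), c(0, 1)), "degenerate")
})

test_that("binning matches the brute-force assignment loop", {
  set.seed(31)
  for (i in 1:20) {
    rm_ <- random_ratio_map(32, 32, 300)
    ang <- runif(1, 0, 2 * pi)
    d <- c(sin(ang), cos(ang))
    prof <- bin_along_flow(rm_, d)
    expect_equal(prof$percentages, oracle_bin(rm_$ratio, rm_$valid, d),
                 tolerance = 1e-9)
  }
})

test_that("flipping the flow reverses the profile exactly; 90-degree joint rotation leaves it invariant", {
  set.seed(32)
  for (i in 1:10) {
    rm_ <- random_ratio_map(40, 60, 400)
    ang <- runif(1, 0, 2 * pi)
    d <- c(sin(ang), cos(ang))
    p_fwd <- bin_along_flow(rm_, d)$percentages
    p_rev <- bin_along_flow(rm_, -d)$percentages
    expect_identical(p_fwd, rev(p_rev))
  }

  rm_ <- random_ratio_map(40, 60, 400)
  d <- c(0, 1)
  base <- bin_along_flow(rm_, d)$percentages
  ratio <- rm_$ratio; valid <- rm_$valid
  for (k in 1:3) {
    ratio <- rot90_mat(ratio); valid <- rot90_mat(valid)
    d <- rot90_flow(d)
    rotated <- bin_along_flow(as_ratio_map(ratio, valid), d)$percentages
    expect_identical(rotated, base)
  }
})

test_that("per-bin normalization anchors the pre-stimulus mean at 1", {
  mk <- function(perc, f) structure(
    list(percentages = perc, bin_edges = 0:length(perc), n_pixels = rep(1L, length(perc)),
         frame_index = f, normalized_percentages = NULL),
    class = "spatial_profile")

  # time-constant profiles: everything normalizes to 1
  perc <- c(30, 30, 40)
  profs <- normalize_profiles(lapply(1:4, function(f) mk(perc, f)), 3)
  for (p in profs) expect_equal(p$normalized_percentages, c(1, 1, 1))

  # one bin doubling post-stimulus reaches 2, the others stay at 1
  profs <- list(mk(c(25, 25, 50), 1), mk(c(25, 25, 50), 2),
                mk(c(50, 25, 50), 3))
  out <- normalize_profiles(profs, 3)
  expect_equal(out[[3]]$normalized_percentages, c(2, 1, 1))
  expect_equal(out[[1]]$normalized_percentages, c(1, 1, 1))

  # a bin with zero pre-stimulus signal is flagged invalid
  profs <- lapply(1:4, function(f) mk(c(0, 60, 40), f))
  out <- normalize_profiles(profs, 3)
  expect_identical(attr(out, "invalid_bins"), 1L)
  expect_true(is.na(out[[1]]$normalized_percentages[1]))

  # random profiles: pre-stimulus mean of every valid bin's trace is 1
  set.seed(33)
  profs <- lapply(1:6, function(f) mk(runif(50, 0.5, 4), f))
  out <- normalize_profiles(profs, 4)
  N <- vapply(out, function(p) p$normalized_percentages, numeric(50))
  expect_equal(unname(rowMeans(N[, 1:3])), rep(1, 50), tolerance = 1e-9)
})

test_that("up/down summaries average the edge regions", {
  mk <- function(norm) structure(
    list(percentages = norm, bin_edges = 0:50, n_pixels = rep(1L, 50),
         frame_index = 1L, normalized_percentages = norm),
    class = "spatial_profile")
  expect_equal(updown_summary(mk(rep(1, 50))),
               c(down_mean = 1, up_mean = 1))
  v <- rep(2, 50); v[1:5] <- 1:5
  expect_equal(updown_summary(mk(v)), c(down_mean = 3, up_mean = 2))

  set.seed(34)
  v <- runif(50)
  expect_equal(updown_summary(mk(v)),
               c(down_mean = mean(v[1:5]), up_mean = mean(v[46:50])))

  # invalid bins among the five are dropped; all-invalid is an error
  v[c(1, 3)] <- NA
  expect_equal(updown_summary(mk(v))[["down_mean"]], mean(v[c(2, 4, 5)]))
  v[1:5] <- NA
  expect_error(updown_summary(mk(v)), "invalid")
  expect_error(updown_summary(structure(list(percentages = 1:50,
                                             normalized_percentages = NULL),
                                        class = "spatial_profile")),
               "normalize_profiles")
})

test_that("polarity test matches hand-computed Welch/Student statistics", {
  # identical groups: degenerate p = 1, no polarity
  res <- polarity_test(c(1, 1, 1), c(1, 1, 1))
  expect_identical(res$p.value, 1)
  expect_false(res$polar)

  up <- c(1.00, 1.02, 0.98); down <- c(2.00, 2.02, 1.98)
  res <- polarity_test(up, down)
  or <- oracle_welch(up, down)
  expect_equal(unname(res$statistic), or$t, tolerance = 1e-12)
  expect_equal(unname(res$parameter), or$df, tolerance = 1e-12)
  expect_equal(res$p.value, or$p, tolerance = 1e-10)
  expect_lt(res$p.value, 0.001)
  expect_true(res$polar)
  expect_equal(unname(res$estimate), c(1, 2), tolerance = 1e-12)

  # arbitrary inputs: p equals t-density quadrature to 1e-10, both variants
  set.seed(35)
  for (i in 1:10) {
    a <- rnorm(6, 1, 0.1); b <- rnorm(8, 1.05, 0.2)
    rw <- polarity_test(a, b, variant = "welch")
    expect_equal(rw$p.value,
                 oracle_t_pvalue(rw$statistic, rw$parameter), tolerance = 1e-10)
    rs <- polarity_test(a, b, variant = "student")
    sp2 <- ((6 - 1) * var(a) + (8 - 1) * var(b)) / 12
    t_s <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 8))
    expect_equal(unname(rs$statistic), t_s, tolerance = 1e-12)
    expect_identical(unname(rs$parameter), 12)
    expect_equal(rs$p.value, oracle_t_pvalue(t_s, 12), tolerance = 1e-10)
  }

  expect_error(polarity_test(1, c(1, 2)), "at least 2 cells")
  # zero variance, unequal means: certain difference
  res <- polarity_test(c(2, 2), c(1, 1))
  expect_identical(res$p.value, 0)
  expect_true(res$polar)
})
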