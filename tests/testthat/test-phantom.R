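test_that("static noiseless phantom yields bit-identical repeats, deterministically", {
  p <- tiny_protocol(n_alines = 24L, n_positions = 10L, n_depth = 64L)
  b <- default_layer_boundaries(64L)
  spec <- phantom_spec(b, default_layer_reflectivities(), seed = 11L)
  sim <- simulate_cluster(spec, p)
  d <- sim$cluster$data
  for (r in 2:p$n_repeats)
    expect_identical(d[, r, , ], d[, 1, , ])

  sim2 <- simulate_cluster(spec, p)
  expect_identical(sim2$cluster$data, d)

  spec2 <- phantom_spec(b, default_layer_reflectivities(), seed = 12L)
  expect_false(identical(simulate_cluster(spec2, p)$cluster$data, d))
})

test_that("decorrelation changes repeats only inside the vessel mask", {
  p <- tiny_protocol(n_alines = 24L, n_positions = 10L, n_depth = 64L)
  b <- default_layer_boundaries(64L)
  vm <- array(FALSE, c(10L, 64L, 24L))
  vm[4:5, 25:29, 8:12] <- TRUE
  spec <- phantom_spec(b, default_layer_reflectivities(), vessel_mask = vm,
                       flow_decorrelation = 0.8, noise_sigma = 0, seed = 5L)
  d <- simulate_cluster(spec, p)$cluster$data
  diff12 <- abs(d[, 2, , ] - d[, 1, , ])
  expect_true(all(diff12[vm] > 0))
  expect_true(all(diff12[!vm] == 0))
})

test_that("invalid phantom specs are rejected with located diagnostics", {
  p <- tiny_protocol(n_alines = 8L, n_positions = 4L, n_depth = 32L)
  crossing <- list(ILM = matrix(20, 4, 8), RPE = matrix(12, 4, 8))
  spec <- phantom_spec(crossing, c(0.1, 1, 0.5))
  expect_error(simulate_cluster(spec, p), "RPE.*ILM.*slow=1.*fast=1")

  vm <- array(FALSE, c(4L, 32L, 8L))
  vm[2, 5, 3] <- TRUE  # above the ILM at depth 10
  spec2 <- phantom_spec(list(ILM = matrix(10, 4, 8), RPE = matrix(20, 4, 8)),
                        c(0.1, 1, 0.5), vessel_mask = vm,
                        flow_decorrelation = 0.5)
  expect_error(simulate_cluster(spec2, p), "slow=2, depth=5, fast=3")

  expect_error(phantom_spec(list(ILM = 10), c(0.1, 1), flow_decorrelation = 1.2),
               "flow_decorrelation")
  expect_error(scan_protocol(n_repeats = 1L), "n_repeats")
  expect_error(scan_protocol(overlap_fraction = 0.5), "overlap_fraction")
})

test_that("speckle amplitudes in a homogeneous noisy layer are positive and unimodal", {
  p <- tiny_protocol(n_alines = 32L, n_positions = 16L, n_depth = 64L)
  spec <- phantom_spec(list(ILM = 20, RPE = 50), c(0.05, 1.0, 0.4),
                       noise_sigma = 0.1, seed = 21L)
  sim <- simulate_cluster(spec, p)
  amp <- Mod(sim$cluster$data[, 1, 25:45, ])  # inside the bright layer
  expect_true(all(amp > 0))
  h <- hist(amp, breaks = 8, plot = FALSE)$counts
  peaks <- sum(diff(sign(diff(h))) < 0)
  expect_lte(peaks, 1)
  expect_gt(stats::median(amp), 0.5)  # near the layer reflectivity
})

test_that("grid cubes share anatomy in overlap strips and follow the layout formula", {
  p <- tiny_protocol(n_alines = 40L, n_positions = 20L, n_depth = 64L,
                     grid_shape = c(1L, 2L))
  ph <- wide_field_phantom(p, preset = "normal", seed = 2L)
  sim <- simulate_grid(ph$spec_factory, p)
  expect_length(sim$cubes, 2L)
  stride_x <- round((1 - p$overlap_fraction) * p$n_alines)  # 36
  ov <- p$n_alines - stride_x                               # 4 columns
  t1 <- sim$cubes[[1]]$truth; t2 <- sim$cubes[[2]]$truth
  expect_identical(t1$vessel_mask[, , (stride_x + 1):p$n_alines],
                   t2$vessel_mask[, , seq_len(ov)])
  expect_equal(t1$boundaries$ILM[, (stride_x + 1):p$n_alines],
               t2$boundaries$ILM[, seq_len(ov)])

  # 3x3 origins: closed-form spacing equals brute-force accumulation
  p9 <- tiny_protocol(n_alines = 20L, n_positions = 20L, n_depth = 32L,
                      grid_shape = c(3L, 3L))
  lay <- montage_layout(c(3L, 3L), p9$cube_width_mm, 0.10)
  step <- (1 - 0.10) * p9$cube_width_mm
  acc <- 0
  for (i in 1:2) acc <- acc + step  # brute-force accumulation of origins
  expect_equal(max(lay$origins$x_mm), acc)
  expect_equal(lay$canvas_extent_mm[2], acc + p9$cube_width_mm)
  expect_equal(lay$canvas_extent_mm[2],
               p9$cube_width_mm * (3 - 2 * 0.10))  # 2.8 w span

  lay1 <- montage_layout(c(1L, 1L), 2.4, 0.10)
  expect_equal(unname(lay1$canvas_extent_mm), c(2.4, 2.4))
  expect_error(montage_layout(c(0L, 2L), 2.4, 0.1), "positive")
})
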