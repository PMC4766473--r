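test_that("montage extent follows the closed form and its monotonicities", {
  w <- 2.4
  expect_equal(montage_extent(1, w, 0.10), w)
  expect_equal(montage_extent(3, w, 0.10), w * 2.8)

  # strictly increasing in n and w, strictly decreasing in f
  ns <- 1:6
  expect_true(all(diff(montage_extent(ns, w, 0.1)) > 0))
  expect_gt(montage_extent(4, w + 0.5, 0.1), montage_extent(4, w, 0.1))
  expect_gt(montage_extent(4, w, 0.05), montage_extent(4, w, 0.25))
})

test_that("protocol timing reproduces the acquisition numbers", {
  p <- scan_protocol()  # 245 x 245 x 4 at 3.7 ms
  t <- protocol_timing(p)
  expect_equal(t$frame_rate_hz, 270)
  expect_equal(t$cube_time_s, 3.6)

  slow <- scan_protocol(inter_bscan_interval_ms = 1000)
  expect_equal(protocol_timing(slow)$frame_rate_hz, 1)
})

test_that("stitching two consistent tiles reproduces the source image", {
  set.seed(51)
  ny <- 60L; nxw <- 114L; nx <- 60L   # two 60-px tiles, 6-px overlap (10%)
  wide <- matrix(runif(ny * nxw), ny, nxw)
  wide <- smooth_flow(array(wide, c(ny, 1, nxw)))[, 1, ]  # correlated texture
  t1 <- wide[, 1:60]; t2 <- wide[, 55:114]
  lay <- montage_layout(c(1L, 2L), cube_width_mm = 1.2, overlap_fraction = 0.10,
                        snap_px = c(ny, nx))
  st <- stitch(list(t1, t2), lay)
  expect_equal(unname(st$shifts[2, ]), c(0, 0))
  expect_false(any(st$flagged))
  expect_equal(dim(st$composite), c(ny, nxw))
  expect_lt(max(abs(st$composite - wide)), 1e-6)
})

test_that("an injected tile offset is recovered exactly", {
  set.seed(52)
  ny <- 60L; nx <- 60L
  wide <- matrix(runif(ny * 120), ny, 120)
  wide <- smooth_flow(array(wide, c(ny, 1, 120)))[, 1, ]
  t1 <- wide[, 1:60]
  t2 <- wide[, (55 + 3):(114 + 3)]   # tile content sits 3 px right of nominal
  lay <- montage_layout(c(1L, 2L), 1.2, 0.10, snap_px = c(ny, nx))
  st <- stitch(list(t1, t2), lay, search_frac = 0.6)
  expect_equal(unname(st$shifts[2, ]), c(0, 3))
})

test_that("single-tile stitching is the identity", {
  set.seed(53)
  t1 <- matrix(runif(400), 20, 20)
  lay <- montage_layout(c(1L, 1L), 1.0, 0.10)
  st <- stitch(list(t1), lay)
  expect_equal(st$composite, t1)
})

test_that("feather weights sum to one wherever tiles cover the canvas", {
  ones <- matrix(1, 40, 40)
  lay <- montage_layout(c(2L, 2L), 1.0, 0.10, snap_px = c(40L, 40L))
  st <- stitch(list(ones, ones, ones, ones), lay, min_corr = 1.1)  # nominal placement
  expect_lt(max(abs(st$composite - 1)), 1e-12)
})

test_that("a weak correlation peak falls back to nominal placement with a flag", {
  set.seed(54)
  t1 <- matrix(runif(900), 30, 30)
  t2 <- matrix(runif(900), 30, 30)  # unrelated content
  lay <- montage_layout(c(1L, 2L), 1.0, 0.10, snap_px = c(30L, 30L))
  st <- stitch(list(t1, t2), lay, min_corr = 0.9)
  expect_true(st$flagged[2])
  expect_equal(unname(st$shifts[2, ]), c(0L, 0L))
})

test_that("stitched phantom grid reconstructs the wide-field vasculature", {
  p <- tiny_protocol(n_alines = 50L, n_positions = 50L, n_depth = 96L,
                     grid_shape = c(1L, 2L))
  ph <- wide_field_phantom(p, preset = "vessel-grid", seed = 5L)
  sim <- simulate_grid(ph$spec_factory, p)
  tiles <- lapply(sim$cubes, function(cb) {
    vols <- build_volumes(cb$cluster)
    model <- segment_layers(vols$structure)
    m <- slab_mask(model, "whole_retina", dim(vols$flow$data))
    max_project(smooth_flow(vols$flow), m)
  })
  st <- stitch(tiles, sim$layout)
  shadow <- ph$truth$vessel_shadow * 1
  sm_shadow <- smooth_flow(array(shadow, c(dim(shadow)[1], 1, dim(shadow)[2])))[, 1, ]
  expect_equal(dim(st$composite), dim(shadow))
  cor_truth <- cor(as.numeric(st$composite), as.numeric(sm_shadow))
  expect_gt(cor_truth, 0.9)
})
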