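make_speckle_bscan <- function(nz, nx, seed) {
  set.seed(seed)
  # aperiodic layered amplitude profile under fully developed speckle
  prof <- 0.2 + sin(seq(0, 2.6, length.out = nz))^2 +
    c(rep(0, nz %/% 3), rep(0.8, nz - nz %/% 3))
  matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)), nz, nx) * prof
}

test_that("registration recovers injected integer shifts exactly", {
  b0 <- make_speckle_bscan(40, 32, seed = 1)
  b1 <- b0[c(38:40, 1:37), ]            # content moved down by +3
  b1 <- b1[, c(3:32, 1:2)]              # and left by -2
  stack <- array(0i, c(2, 40, 32))
  stack[1, , ] <- b0; stack[2, , ] <- b1
  reg <- register_repeats(stack)
  expect_equal(unname(reg$shifts[2, ]), c(3, -2))
  # aligned data matches repeat 0 wherever valid
  al <- reg$aligned[2, , ]
  expect_equal(al[reg$valid[2, , ]], b0[reg$valid[2, , ]])
  expect_false(all(reg$valid[2, , ]))

  stack_id <- array(0i, c(3, 40, 32))
  for (r in 1:3) stack_id[r, , ] <- b0
  reg_id <- register_repeats(stack_id)
  expect_true(all(reg_id$shifts == 0))
  expect_false(any(reg_id$warning))
})

test_that("an all-zero B-scan yields zero shift and a warning flag", {
  stack <- array(0i, c(2, 16, 16))
  stack[1, , ] <- make_speckle_bscan(16, 16, seed = 2)
  reg <- register_repeats(stack)
  expect_true(reg$warning[2])
  expect_equal(unname(reg$shifts[2, ]), c(0, 0))
})

test_that("subpixel registration recovers fractional shifts within a quarter pixel", {
  b0 <- make_speckle_bscan(48, 48, seed = 3)
  for (s in list(c(1.5, 0), c(-0.7, 2.3), c(0.25, -1.75))) {
    b1 <- oracle_fourier_shift(b0, s[1], s[2])
    stack <- array(0i, c(2, 48, 48))
    stack[1, , ] <- b0; stack[2, , ] <- b1
    reg <- register_repeats(stack, subpixel = TRUE)
    expect_lt(abs(reg$shifts[2, 1] - s[1]), 0.25)
    expect_lt(abs(reg$shifts[2, 2] - s[2]), 0.25)
  }
})

test_that("complex differentiation matches hand and brute-force oracles", {
  # identical repeats: zero flow
  stack <- array(0i, c(4, 8, 8))
  for (r in 1:4) stack[r, , ] <- make_speckle_bscan(8, 8, seed = 4)
  expect_true(all(omag_differentiate(stack) == 0))

  # sign flip at one voxel: |(-1) - 1| = 2
  s2 <- array(1 + 0i, c(2, 4, 4))
  s2[2, 2, 3] <- -1 + 0i
  f <- omag_differentiate(s2)
  expect_equal(f[2, 3], 2)
  expect_equal(sum(f), 2)

  # random stacks equal a per-voxel loop computation to machine precision
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(2:4, 1)
    st <- array(complex(real = rnorm(n * 8 * 8), imaginary = rnorm(n * 8 * 8)),
                c(n, 8, 8))
    ref <- matrix(0, 8, 8)
    for (z in 1:8) for (x in 1:8) {
      acc <- 0
      for (i in 1:(n - 1)) acc <- acc + Mod(st[i + 1, z, x] - st[i, z, x])
      ref[z, x] <- acc / (n - 1)
    }
    expect_equal(omag_differentiate(st), ref, ignore_attr = TRUE,
                 tolerance = 1e-12)
    # reversing repeat order leaves the flow unchanged
    expect_equal(omag_differentiate(st[n:1, , , drop = FALSE]),
                 omag_differentiate(st), ignore_attr = TRUE)
  }
  expect_error(omag_differentiate(array(0i, c(1, 4, 4))), "2 repeats")
})

test_that("invalid voxels are excluded with renormalization", {
  st <- array(0i, c(3, 4, 4))
  st[1, , ] <- 1; st[2, , ] <- 1i; st[3, , ] <- -1
  valid <- array(TRUE, c(3, 4, 4))
  valid[3, 1, ] <- FALSE                 # second pair invalid on row 1
  f <- omag_differentiate(st, valid)
  expect_equal(f[1, 1], Mod(1i - 1))     # single-pair average
  expect_equal(f[2, 1], (Mod(1i - 1) + Mod(-1 - 1i)) / 2)
  valid[1:2, 2, ] <- FALSE               # no valid pair at all on row 2
  f2 <- omag_differentiate(st, valid)
  expect_equal(f2[2, 2], 0)
})

test_that("global phase offsets are removed without boosting static signal", {
  b0 <- make_speckle_bscan(24, 24, seed = 6)
  stack <- array(0i, c(3, 24, 24))
  stack[1, , ] <- b0
  stack[2, , ] <- b0 * exp(1i * 0.7)
  stack[3, , ] <- b0 * exp(-1i * 1.2)
  comp <- bulk_phase_compensate(stack)
  expect_true(all(omag_differentiate(comp$aligned) < 1e-12))
  expect_equal(comp$phase[2], 0.7, tolerance = 1e-10)

  # zero offset leaves the stack unchanged
  same <- array(0i, c(2, 24, 24))
  same[1, , ] <- b0; same[2, , ] <- b0
  expect_equal(bulk_phase_compensate(same)$aligned, same)

  # random per-repeat phases on a static phantom: compensation reduces flow
  set.seed(7)
  ph <- runif(3, -pi, pi); ph[1] <- 0
  noisy <- array(0i, c(3, 24, 24))
  for (r in 1:3) noisy[r, , ] <- b0 * exp(1i * ph[r]) +
    0.05 * matrix(complex(real = rnorm(576), imaginary = rnorm(576)), 24, 24)
  raw <- mean(omag_differentiate(noisy))
  fixed <- mean(omag_differentiate(bulk_phase_compensate(noisy)$aligned))
  expect_lt(fixed, raw)
})

test_that("volume build: static input gives zero flow and exact structure", {
  p <- tiny_protocol(n_alines = 24L, n_positions = 8L, n_depth = 64L)
  spec <- phantom_spec(default_layer_boundaries(64L),
                       default_layer_reflectivities(), seed = 9L)
  sim <- simulate_cluster(spec, p)
  vols <- build_volumes(sim$cluster)
  expect_true(all(vols$flow$data == 0))
  expect_equal(vols$structure$data, Mod(sim$cluster$data[, 1, , ]))
})

test_that("bulk motion is compensated: flow matches the motion-free run", {
  p <- tiny_protocol(n_alines = 32L, n_positions = 10L, n_depth = 64L)
  vp <- vessel_phantom_spec(p, noise_sigma = 0, seed = 13L)
  base <- build_volumes(simulate_cluster(vp$spec, p)$cluster)

  bm <- matrix(0, 4, 2); bm[2, ] <- c(2, 1)
  spec_m <- phantom_spec(vp$boundaries, default_layer_reflectivities(),
                         vessel_mask = vp$vessel_mask,
                         flow_decorrelation = 0.8, bulk_motion = bm,
                         noise_sigma = 0, seed = 13L)
  moved <- build_volumes(simulate_cluster(spec_m, p)$cluster)
  expect_equal(unname(moved$report$shifts[1, 2, ]), c(2, 1))
  tissue <- base$flow$data > 0
  rel <- abs(moved$flow$data[tissue] - base$flow$data[tissue]) /
    base$flow$data[tissue]
  expect_lt(stats::median(rel), 0.01)
})

test_that("mean in-vessel flow increases with the decorrelation rate", {
  p <- tiny_protocol(n_alines = 32L, n_positions = 12L, n_depth = 64L)
  means <- vapply(c(0.2, 0.5, 0.9), function(d) {
    vp <- vessel_phantom_spec(p, decorrelation = d, noise_sigma = 0.09,
                              seed = 17L)
    vols <- build_volumes(simulate_cluster(vp$spec, p)$cluster)
    mean(vols$flow$data[vp$vessel_mask])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
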