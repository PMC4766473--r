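# flat five-boundary phantom: step contrasts decrease with depth and each
# boundary carries an anatomical band prior below its predecessor
flat5_targets <- function() {
  data.frame(
    name = c("ILM", "B2", "B3", "B4", "B5"),
    polarity = c("up", "down", "down", "down", "down"),
    after = c("", "ILM", "B2", "B3", "B4"), before = "",
    near = c("", "after", "after", "after", "after"),
    band_um = c(NA, 300, 300, 300, 300), order = 1:5,
    stringsAsFactors = FALSE
  )
}

flat5_args <- function() list(grad_window = 3L, max_step = 1L,
                              presmooth = c(5L, 11L))

flat5_volume <- function(protocol, depths = c(40, 80, 120, 160, 200),
                         ilm_wave = 0, seed = 31L) {
  nz <- protocol$n_depth
  b <- as.list(depths)
  names(b) <- c("ILM", "B2", "B3", "B4", "B5")
  if (ilm_wave > 0) {
    ny <- protocol$n_positions; nx <- protocol$n_alines
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    b$ILM <- depths[1] + ilm_wave * sin(2 * pi * xx / nx)
  }
  spec <- phantom_spec(b, c(0.05, 1.6, 1.0, 0.6, 0.35, 0.2), seed = seed)
  sim <- simulate_cluster(spec, protocol)
  list(structure = build_volumes(sim$cluster)$structure, truth = b)
}

test_that("flat phantom boundaries are recovered within one pixel", {
  p <- tiny_protocol(n_alines = 64L, n_positions = 10L, n_depth = 256L)
  fv <- flat5_volume(p)
  model <- do.call(segment_layers, c(list(fv$structure, targets = flat5_targets()),
                                     flat5_args()))
  for (n in names(fv$truth))
    expect_lt(max(abs(model$boundaries[[n]] - fv$truth[[n]])), 1 + 1e-9,
              label = paste("boundary", n))
  expect_equal(nrow(model$failed), 0)
})

test_that("a sinusoidal ILM is tracked with RMSE below two pixels", {
  p <- tiny_protocol(n_alines = 48L, n_positions = 10L, n_depth = 256L)
  fv <- flat5_volume(p, ilm_wave = 10)
  model <- segment_layers(fv$structure, targets = flat5_targets(),
                          max_step = 3L, presmooth = c(1L, 3L),
                          grad_window = 3L)
  rmse <- sqrt(mean((model$boundaries$ILM - fv$truth$ILM)^2))
  expect_lt(rmse, 2)
})

test_that("seed points are hard constraints and make segmentation idempotent", {
  p <- tiny_protocol(n_alines = 24L, n_positions = 6L, n_depth = 256L)
  fv <- flat5_volume(p)
  seeds <- data.frame(boundary = "B5", slow = 3L, fast = 10L, depth = 205)
  model <- do.call(segment_layers, c(list(fv$structure, targets = flat5_targets(),
                                          seeds = seeds), flat5_args()))
  expect_equal(model$boundaries$B5[3, 10], 205)

  # re-running with seeds drawn from the model's own output reproduces it
  base <- do.call(segment_layers, c(list(fv$structure, targets = flat5_targets()),
                                    flat5_args()))
  own <- do.call(rbind, lapply(c(1L, 4L), function(y)
    data.frame(boundary = "ILM", slow = y, fast = c(5L, 20L),
               depth = base$boundaries$ILM[y, c(5L, 20L)])))
  redo <- do.call(segment_layers, c(list(fv$structure, targets = flat5_targets(),
                                         seeds = own), flat5_args()))
  for (n in names(base$boundaries))
    expect_equal(redo$boundaries[[n]], base$boundaries[[n]])
})

test_that("full boundary set is recovered on the noisy default phantom", {
  p <- tiny_protocol(n_alines = 48L, n_positions = 20L, n_depth = 96L)
  vp <- vessel_phantom_spec(p, noise_sigma = 0.09, seed = 3L)
  vols <- build_volumes(simulate_cluster(vp$spec, p)$cluster)
  model <- segment_layers(vols$structure)
  for (n in names(model$boundaries)) {
    expect_true(all(is.finite(model$boundaries[[n]])), label = n)
    expect_lt(mean(abs(model$boundaries[[n]] - vp$boundaries[[n]])), 1.5,
              label = paste("boundary", n))
  }
  # anatomical ordering holds everywhere
  nm <- names(model$boundaries)
  for (k in seq_along(nm)[-1])
    expect_true(all(model$boundaries[[nm[k]]] >= model$boundaries[[nm[k - 1]]]))
})

test_that("slab masks follow the half-open micron-offset rule", {
  ny <- 4L; nz <- 256L; nx <- 6L
  bnds <- lapply(default_layer_boundaries(256L) * 0 + c(40, 52, 64, 76, 88, 200, 240),
                 function(d) matrix(d, ny, nx))
  names(bnds) <- names(default_layer_boundaries(256L))
  model <- layer_model(bnds, axial_pitch_um = 3.0)

  cc <- slab_mask(model, "choriocapillaris", c(ny, nz, nx))
  z_in <- which(cc[1, , 1])
  expect_equal(z_in, 200:209)  # 30 um / 3 um = 10 rows from the RPE down

  # retina partition: five slabs tile ILM..RPE disjointly
  parts <- c("NFL", "SRL", "DRL", "ORL", "photoreceptors")
  masks <- lapply(parts, function(s) slab_mask(model, s, c(ny, nz, nx)))
  whole <- slab_mask(model, "whole_retina", c(ny, nz, nx))
  acc <- array(0L, c(ny, nz, nx))
  for (m in masks) acc <- acc + m
  expect_true(all(acc <= 1L))            # pairwise disjoint
  expect_identical(acc == 1L, whole)     # union equals ILM..RPE

  # zero-thickness slab triggers a named error
  degenerate <- slab_definition("rpe_line", "RPE", "RPE")
  expect_error(slab_mask(model, degenerate, c(ny, nz, nx)), "rpe_line")
  expect_error(slab_mask(model, "nonsense", c(ny, nz, nx)), "nonsense")

  # deep choroid falls back to a fixed band when the scleral boundary is absent
  model2 <- layer_model(bnds[1:6], axial_pitch_um = 3.0)
  dc <- slab_mask(model2, "deep_choroid", c(ny, 300L, nx))
  expect_equal(which(dc[1, , 1]), 210:(210 + round(200 / 3) - 1))
})
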