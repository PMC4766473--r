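# Shared fixtures: small protocols and phantoms, plus independent oracles
# kept deliberately naive (loops, direct formulas) so they do not share code
# paths with the implementation they check.

tiny_protocol <- function(n_alines = 48L, n_positions = 40L, n_repeats = 4L,
                          n_depth = 96L, grid_shape = c(1L, 1L),
                          overlap_fraction = 0.10) {
  # scale the axial pitch so reduced-depth phantoms keep the physical depth
  # range of the full 512-pixel protocol (3 um at 512)
  scan_protocol(n_alines = n_alines, n_positions = n_positions,
                n_repeats = n_repeats, n_depth = n_depth,
                axial_pitch_um = 3 * 512 / n_depth,
                grid_shape = grid_shape, overlap_fraction = overlap_fraction)
}

# phantom with the default anatomy plus one rectangular vessel in the SRL
vessel_phantom_spec <- function(protocol, decorrelation = 0.8,
                                noise_sigma = 0.09, bulk_motion = NULL,
                                seed = 3L) {
  ny <- protocol$n_positions; nz <- protocol$n_depth; nx <- protocol$n_alines
  b <- default_layer_boundaries(nz)
  vm <- array(FALSE, c(ny, nz, nx))
  z0 <- b[["NFL/GCL"]] + 1L; z1 <- b[["IPL/INL"]] - 1L
  vm[(ny %/% 4):(ny %/% 4 + 4L), z0:z1, (nx %/% 5):(4L * nx %/% 5)] <- TRUE
  list(
    spec = phantom_spec(b, default_layer_reflectivities(), vessel_mask = vm,
                        flow_decorrelation = decorrelation,
                        bulk_motion = bulk_motion,
                        noise_sigma = noise_sigma, seed = seed),
    vessel_mask = vm, boundaries = b
  )
}

# independent subpixel shifter: direct double loop over frequencies
oracle_fourier_shift <- function(m, dz, dx) {
  nz <- nrow(m); nx <- ncol(m)
  kz <- c(0:(ceiling(nz / 2) - 1), -(floor(nz / 2):1))
  kx <- c(0:(ceiling(nx / 2) - 1), -(floor(nx / 2):1))
  Fm <- stats::fft(m)
  for (i in seq_len(nz)) for (j in seq_len(nx))
    Fm[i, j] <- Fm[i, j] * exp(-2i * pi * (kz[i] * dz / nz + kx[j] * dx / nx))
  stats::fft(Fm, inverse = TRUE) / (nz * nx)
}

# Otsu threshold by exhaustive between-class variance search
oracle_otsu <- function(x, nbins = 256L) {
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); mut <- mu[nbins]
  sb <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
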