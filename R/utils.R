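# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# n draws from a circular complex Gaussian with E|c|^2 = 1.
rcnorm <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)

# Circular shift of a matrix: content moves down by dz rows, right by dx cols.
circshift2 <- function(m, dz, dx) {
  nz <- nrow(m); nx <- ncol(m)
  dz <- ((dz %% nz) + nz) %% nz
  dx <- ((dx %% nx) + nx) %% nx
  if (dz > 0) m <- m[c((nz - dz + 1):nz, seq_len(nz - dz)), , drop = FALSE]
  if (dx > 0) m <- m[, c((nx - dx + 1):nx, seq_len(nx - dx)), drop = FALSE]
  m
}

fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

# Subpixel (circular) translation via a Fourier phase ramp.
fourier_shift2 <- function(m, dz, dx) {
  nz <- nrow(m); nx <- ncol(m)
  ph <- exp(-2i * pi * outer(fft_freqs(nz) * dz / nz, fft_freqs(nx) * dx / nx, `+`))
  stats::fft(stats::fft(m) * ph, inverse = TRUE) / (nz * nx)
}

# Validity mask after shifting content by (dz, dx): rows/cols that wrapped
# around the frame carry no acquired data.
shift_valid_mask <- function(nz, nx, dz, dx) {
  v <- matrix(TRUE, nz, nx)
  cz <- min(ceiling(abs(dz)), nz)
  cx <- min(ceiling(abs(dx)), nx)
  if (cz > 0) {
    if (dz > 0) v[seq_len(cz), ] <- FALSE else v[(nz - cz + 1):nz, ] <- FALSE
  }
  if (cx > 0) {
    if (dx > 0) v[, seq_len(cx)] <- FALSE else v[, (nx - cx + 1):nx] <- FALSE
  }
  v
}

# Signed shift (dz, dx) at the peak of a circular cross-correlation surface.
# Ties (within a tiny numerical band) resolve to the smallest displacement
# magnitude, then lexicographically on (dz, dx).
peak_shift <- function(cc) {
  nz <- nrow(cc); nx <- ncol(cc)
  mx <- max(cc)
  tol <- 1e-9 * max(abs(mx), 1)
  idx <- which(cc >= mx - tol, arr.ind = TRUE)
  dz <- idx[, 1] - 1; dz <- ifelse(dz >= ceiling(nz / 2), dz - nz, dz)
  dx <- idx[, 2] - 1; dx <- ifelse(dx >= ceiling(nx / 2), dx - nx, dx)
  ord <- order(dz * dz + dx * dx, dz, dx)
  c(dz[ord[1]], dx[ord[1]])
}

# Refine an integer correlation peak by evaluating the cross-power spectrum G
# on an upsampled grid around s0 (matrix-multiply discrete Fourier transform).
upsampled_peak <- function(G, s0, upsample = 20L, halfwidth = 1.5) {
  nz <- nrow(G); nx <- ncol(G)
  sz <- s0[1] + seq(-halfwidth, halfwidth, by = 1 / upsample)
  sx <- s0[2] + seq(-halfwidth, halfwidth, by = 1 / upsample)
  kz <- fft_freqs(nz); kx <- fft_freqs(nx)
  Ez <- exp(2i * pi * outer(sz, kz) / nz)
  Ex <- exp(2i * pi * outer(kx, sx) / nx)
  cc <- Re(Ez %*% G %*% Ex)
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(sz[ij[1]], sx[ij[2]])
}

# Pearson correlation between two equal-size arrays, 0 for degenerate input.
ncc_score <- function(a, b) {
  a <- as.numeric(a) - mean(a); b <- as.numeric(b) - mean(b)
  d <- sqrt(sum(a^2) * sum(b^2))
  if (d == 0) return(0)
  sum(a * b) / d
}

# Broadcast a per-(slow, fast) matrix to a [slow, depth, fast] array.
expand_yx_to_yzx <- function(m, nz) {
  ny <- nrow(m); nx <- ncol(m)
  aperm(array(rep(m, times = nz), dim = c(ny, nx, nz)), c(1, 3, 2))
}

# Depth-index array matching a [slow, depth, fast] volume.
depth_index_array <- function(ny, nz, nx) {
  aperm(array(seq_len(nz), dim = c(nz, ny, nx)), c(2, 1, 3))
}
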