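#' Register repeated B-scans by cross-correlation
#'
#' Aligns each repeat to the first by the displacement maximizing the
#' normalized cross-correlation of the amplitude images (computed circularly
#' via FFT on mean-subtracted amplitudes; for full-frame circular shifts the
#' correlation norm is shift-invariant, so the argmax equals the normalized
#' one). Ties break toward the smallest displacement magnitude, then
#' lexicographically on `(dz, dx)`. With `subpixel = TRUE` the integer peak
#' is refined by upsampled evaluation of the cross-power spectrum.
#'
#' Voxels that leave the frame under the aligning shift are flagged invalid
#' rather than wrapped into the average; downstream operations exclude them.
#'
#' @param stack complex `[repeat, depth, fast]` array (one cluster).
#' @param subpixel refine shifts below one pixel.
#' @param upsample upsampling factor of the subpixel refinement (precision
#'   about `1/upsample` px).
#' @return list: `aligned` (complex stack), `valid` (logical stack, `FALSE`
#'   where a voxel has no acquired data after alignment), `shifts`
#'   (`[repeat, 2]` matrix of `(dz, dx)` in pixels), `warning` (logical per
#'   repeat; `TRUE` where correlation was undefined and a zero shift was
#'   returned).
#' @export
register_repeats <- function(stack, subpixel = FALSE, upsample = 20L) {
  d <- dim(stack)
  if (length(d) != 3L || d[1] < 2L)
    stop("stack must be [repeat, depth, fast] with at least 2 repeats", call. = FALSE)
  nrep <- d[1]; nz <- d[2]; nx <- d[3]
  if (nz * nx == 0L) stop("B-scans must be nonempty", call. = FALSE)
  if (!is.complex(stack)) stack <- stack + 0i

  aligned <- stack
  valid <- array(TRUE, dim = d)
  shifts <- matrix(0, nrep, 2, dimnames = list(NULL, c("dz", "dx")))
  warn <- logical(nrep)

  a0 <- Mod(matrix(stack[1, , ], nz, nx))
  deg0 <- all(a0 == a0[1])
  F0 <- if (deg0) NULL else Conj(stats::fft(a0 - mean(a0)))

  for (r in 2:nrep) {
    ar <- Mod(matrix(stack[r, , ], nz, nx))
    if (deg0 || all(ar == ar[1])) {
      warn[r] <- TRUE
      next
    }
    G <- stats::fft(ar - mean(ar)) * F0
    if (subpixel) {
      # low-pass the correlation (a circular Gaussian blur of both amplitude
      # images) to tame speckle interpolation artifacts in the refinement
      sig <- 1
      W <- outer(exp(-2 * pi^2 * sig^2 * (fft_freqs(nz) / nz)^2),
                 exp(-2 * pi^2 * sig^2 * (fft_freqs(nx) / nx)^2))
      G <- G * W
    }
    cc <- Re(stats::fft(G, inverse = TRUE)) / (nz * nx)
    s <- peak_shift(cc)
    if (subpixel) s <- upsampled_peak(G, s, upsample = upsample)
    shifts[r, ] <- s
    if (any(s != 0)) {
      b <- matrix(stack[r, , ], nz, nx)
      if (all(s == round(s))) {
        aligned[r, , ] <- circshift2(b, -as.integer(s[1]), -as.integer(s[2]))
      } else {
        aligned[r, , ] <- fourier_shift2(b, -s[1], -s[2])
      }
      valid[r, , ] <- shift_valid_mask(nz, nx, -s[1], -s[2])
    }
  }
  list(aligned = aligned, valid = valid, shifts = shifts, warning = warn)
}

#' OMAG flow contrast by complex differentiation
#'
#' The flow value at each voxel is the mean absolute difference of the
#' complex OCT signal between successive registered repeats,
#' `flow = 1/(N-1) * sum_i |C[i+1] - C[i]|`, which uses both amplitude and
#' phase: static tissue (identical complex values) yields exactly zero,
#' while decorrelating blood flow yields a positive value growing with the
#' decorrelation rate. Pairs containing an invalid (out-of-frame) voxel are
#' excluded and the average renormalized over the remaining pairs; voxels
#' with no valid pair are set to 0.
#'
#' @param aligned complex `[repeat, depth, fast]` stack, registered.
#' @param valid logical stack from [register_repeats()], or `NULL` (all valid).
#' @param amplitude_only use `||C[i+1]| - |C[i]||` (amplitude decorrelation
#'   only) instead of the complex difference.
#' @return non-negative `[depth, fast]` flow matrix; attribute
#'   `n_valid_pairs` holds the per-voxel pair count used.
#' @export
omag_differentiate <- function(aligned, valid = NULL, amplitude_only = FALSE) {
  d <- dim(aligned)
  if (length(d) != 3L || d[1] < 2L)
    stop("need a [repeat, depth, fast] stack with at least 2 repeats", call. = FALSE)
  nrep <- d[1]; nz <- d[2]; nx <- d[3]
  if (is.null(valid)) valid <- array(TRUE, dim = d)
  num <- matrix(0, nz, nx)
  cnt <- matrix(0L, nz, nx)
  for (i in seq_len(nrep - 1L)) {
    ci <- matrix(aligned[i, , ], nz, nx)
    cj <- matrix(aligned[i + 1L, , ], nz, nx)
    dd <- if (amplitude_only) abs(Mod(cj) - Mod(ci)) else Mod(cj - ci)
    pv <- matrix(valid[i, , ], nz, nx) & matrix(valid[i + 1L, , ], nz, nx)
    num <- num + dd * pv
    cnt <- cnt + pv
  }
  flow <- num / pmax(cnt, 1L)
  flow[cnt == 0L] <- 0
  attr(flow, "n_valid_pairs") <- cnt
  flow
}

#' Remove per-repeat global phase offsets
#'
#' Estimates, for each repeat, the amplitude-weighted mean phase difference
#' relative to the first repeat — `Arg(sum(C_r * Conj(C_1)))` over jointly
#' valid voxels — and multiplies the repeat by its conjugate phase. A purely
#' global phase drift on static tissue is removed exactly, so the complex
#' differentiation signal of static tissue is never increased.
#'
#' @param aligned complex `[repeat, depth, fast]` stack.
#' @param valid optional logical stack restricting the phase estimate.
#' @return list with `aligned` (compensated stack) and `phase` (the removed
#'   offset per repeat, radians).
#' @export
bulk_phase_compensate <- function(aligned, valid = NULL) {
  d <- dim(aligned)
  nrep <- d[1]; nz <- d[2]; nx <- d[3]
  if (is.null(valid)) valid <- array(TRUE, dim = d)
  phase <- numeric(nrep)
  c1 <- matrix(aligned[1, , ], nz, nx)
  v1 <- matrix(valid[1, , ], nz, nx)
  for (r in seq_len(nrep)[-1L]) {
    cr <- matrix(aligned[r, , ], nz, nx)
    pv <- v1 & matrix(valid[r, , ], nz, nx)
    s <- sum(cr[pv] * Conj(c1[pv]))
    if (Mod(s) > 0) {
      phase[r] <- Arg(s)
      aligned[r, , ] <- cr * exp(-1i * phase[r])
    }
  }
  list(aligned = aligned, phase = phase)
}

#' Build flow and structure volumes from a cluster scan
#'
#' Runs the per-position OMAG chain over a whole cube: register the repeats
#' at each slow-axis position, optionally remove global phase offsets, then
#' differentiate the complex signal. The structural volume is the mean
#' amplitude across registered repeats (invalid voxels excluded from the
#' mean).
#'
#' @param cluster a [cluster_volume()].
#' @param phase_compensation apply [bulk_phase_compensate()] before
#'   differentiation (off by default; the acquisition model compensates
#'   displacement, not phase).
#' @param subpixel subpixel registration (see [register_repeats()]).
#' @param amplitude_only amplitude-only differentiation.
#' @return list: `flow` ([flow_volume()]), `structure` ([structure_volume()])
#'   and `report` (per-position registration shifts `[slow, repeat, 2]` and
#'   a logical matrix of correlation warnings).
#' @export
build_volumes <- function(cluster, phase_compensation = FALSE,
                          subpixel = FALSE, amplitude_only = FALSE) {
  stopifnot(inherits(cluster, "cluster_volume"))
  d <- dim(cluster$data)
  ny <- d[1]; nrep <- d[2]; nz <- d[3]; nx <- d[4]
  flow <- array(0, dim = c(ny, nz, nx))
  struc <- array(0, dim = c(ny, nz, nx))
  shifts <- array(0, dim = c(ny, nrep, 2))
  warns <- matrix(FALSE, ny, nrep)
  for (y in seq_len(ny)) {
    stack <- array(cluster$data[y, , , ], dim = c(nrep, nz, nx))
    reg <- register_repeats(stack, subpixel = subpixel)
    if (phase_compensation)
      reg$aligned <- bulk_phase_compensate(reg$aligned, reg$valid)$aligned
    flow[y, , ] <- omag_differentiate(reg$aligned, reg$valid,
                                      amplitude_only = amplitude_only)
    asum <- matrix(0, nz, nx); acnt <- matrix(0L, nz, nx)
    for (r in seq_len(nrep)) {
      vr <- matrix(reg$valid[r, , ], nz, nx)
      asum <- asum + Mod(matrix(reg$aligned[r, , ], nz, nx)) * vr
      acnt <- acnt + vr
    }
    struc[y, , ] <- asum / pmax(acnt, 1L)
    shifts[y, , ] <- reg$shifts
    warns[y, ] <- reg$warning
  }
  list(
    flow = flow_volume(flow, cluster$protocol),
    structure = structure_volume(struc, cluster$protocol),
    report = list(shifts = shifts, warnings = warns)
  )
}
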