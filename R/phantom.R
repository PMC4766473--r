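#' Synthetic retina phantom specification
#'
#' Defines the ground truth a simulated cluster scan is rendered from:
#' layered anatomy (smooth boundary surfaces with a mean reflectivity per
#' layer), a vessel mask with a per-voxel flow decorrelation rate, residual
#' bulk motion between repeated B-scans, and additive complex noise.
#'
#' The speckle model gives every voxel a circular complex Gaussian draw
#' scaled by its layer reflectivity (so amplitudes are Rayleigh within a
#' homogeneous layer). Static voxels keep the same complex value across
#' repeats; a vessel voxel with decorrelation rate `d` is re-mixed each
#' inter-scan interval as `sqrt(1 - d) * previous + sqrt(d) * fresh`, which
#' makes the complex-difference flow signal grow monotonically with `d`
#' while preserving the amplitude statistics.
#'
#' @param layer_boundaries boundary depths in pixels, ordered top to bottom:
#'   either a named numeric vector of flat depths or a named list of
#'   `[slow, fast]` matrices. Names identify the anatomical interfaces (see
#'   [default_layer_boundaries()]). Boundaries must strictly increase with
#'   depth at every location.
#' @param layer_reflectivities mean amplitude per layer, length
#'   `length(layer_boundaries) + 1` (the first entry is the medium above the
#'   first boundary), all > 0.
#' @param vessel_mask logical `[slow, depth, fast]` array of flow voxels, or
#'   `NULL` for a static phantom. Vessel voxels must lie strictly below the
#'   first (ILM) boundary.
#' @param flow_decorrelation decorrelation per inter-scan interval in
#'   `[0, 1]`: a scalar applied to every vessel voxel, or an array matching
#'   `vessel_mask`.
#' @param bulk_motion residual displacement `(dz, dx)` in pixels per
#'   (position, repeat): `NULL` (none), a `[n_repeats, 2]` matrix applied at
#'   every position, or a `[n_positions, n_repeats, 2]` array.
#' @param noise_sigma scale of the additive complex Gaussian acquisition
#'   noise (same units as reflectivity).
#' @param seed integer RNG seed; identical spec + protocol + seed gives
#'   bit-identical volumes.
#' @return a `phantom_spec` object.
#' @seealso [simulate_cluster()], [simulate_grid()], [wide_field_phantom()]
#' @export
phantom_spec <- function(layer_boundaries, layer_reflectivities,
                         vessel_mask = NULL, flow_decorrelation = 0,
                         bulk_motion = NULL, noise_sigma = 0, seed = 1L) {
  if (is.numeric(layer_boundaries) && !is.list(layer_boundaries))
    layer_boundaries <- as.list(layer_boundaries)
  if (is.null(names(layer_boundaries)) || any(!nzchar(names(layer_boundaries))))
    stop("layer_boundaries must be named", call. = FALSE)
  if (length(layer_reflectivities) != length(layer_boundaries) + 1L)
    stop("need one reflectivity per layer: length(layer_boundaries) + 1", call. = FALSE)
  if (any(layer_reflectivities <= 0))
    stop("layer reflectivities must be > 0", call. = FALSE)
  if (any(flow_decorrelation < 0 | flow_decorrelation > 1))
    stop("flow_decorrelation must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(
    layer_boundaries = layer_boundaries,
    layer_reflectivities = as.numeric(layer_reflectivities),
    vessel_mask = vessel_mask,
    flow_decorrelation = flow_decorrelation,
    bulk_motion = bulk_motion,
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default retinal boundary depths for a phantom
#'
#' Seven interfaces placed at fixed fractions of the depth range, spanning a
#' plausible posterior-segment profile: ILM, NFL/GCL, IPL/INL, OPL/ONL, ELM,
#' RPE (bottom of the bright RPE band) and choroid/sclera.
#'
#' @param n_depth depth pixels of the target volume.
#' @return named numeric vector of boundary depths in pixels.
#' @export
default_layer_boundaries <- function(n_depth = 512L) {
  round(c(ILM = 0.20, `NFL/GCL` = 0.225, `IPL/INL` = 0.275, `OPL/ONL` = 0.33,
          ELM = 0.39, RPE = 0.43, `choroid/sclera` = 0.55) * n_depth)
}

#' Default layer reflectivities matching [default_layer_boundaries()]
#'
#' Eight zones, top to bottom: vitreous, NFL, SRL (GCL + IPL), DRL
#' (INL + OPL), ORL (ONL), photoreceptor/RPE complex, choroid, sclera.
#' The interface contrasts are ordered so each boundary is the most
#' prominent transition of its polarity within the band the segmentation
#' searches (see [boundary_targets()]).
#' @export
default_layer_reflectivities <- function() {
  c(vitreous = 0.05, NFL = 1.3, SRL = 0.9, DRL = 0.65, ORL = 0.35,
    RPE_complex = 1.40, choroid = 0.55, sclera = 0.95)
}

# Expand flat / matrix boundary input to [ny, nx] matrices and validate the
# strict top-to-bottom ordering, naming the first crossing encountered.
expand_boundaries <- function(bnds, ny, nx, n_depth) {
  out <- lapply(bnds, function(b) {
    if (is.matrix(b)) {
      if (!all(dim(b) == c(ny, nx)))
        stop(sprintf("boundary matrix must be %d x %d (slow x fast)", ny, nx), call. = FALSE)
      b
    } else {
      matrix(as.numeric(b), ny, nx)
    }
  })
  names(out) <- names(bnds)
  nm <- names(out)
  for (k in seq_along(out)) {
    if (any(out[[k]] < 1 | out[[k]] > n_depth))
      stop(sprintf("boundary '%s' leaves the depth range [1, %d]", nm[k], n_depth),
           call. = FALSE)
    if (k > 1L) {
      bad <- which(out[[k]] <= out[[k - 1L]], arr.ind = TRUE)
      if (nrow(bad) > 0)
        stop(sprintf(
          "boundary '%s' does not lie strictly below '%s' at (slow=%d, fast=%d)",
          nm[k], nm[k - 1L], bad[1, 1], bad[1, 2]), call. = FALSE)
    }
  }
  out
}

# Per-(position, repeat) motion table as an [ny, nrep, 2] array.
expand_bulk_motion <- function(bm, ny, nrep) {
  if (is.null(bm)) return(array(0, dim = c(ny, nrep, 2)))
  if (is.matrix(bm) && all(dim(bm) == c(nrep, 2L))) {
    out <- array(0, dim = c(ny, nrep, 2))
    for (r in seq_len(nrep)) {
      out[, r, 1] <- bm[r, 1]
      out[, r, 2] <- bm[r, 2]
    }
    return(out)
  }
  if (length(dim(bm)) == 3L && all(dim(bm) == c(ny, nrep, 2L))) return(bm)
  stop("bulk_motion must be NULL, an [n_repeats, 2] matrix, or an [n_positions, n_repeats, 2] array",
       call. = FALSE)
}

#' Simulate one complex OCT cluster scan from a phantom
#'
#' Renders the phantom into a complex volume `[slow, repeat, depth, fast]`:
#' a static speckle field per voxel, per-repeat re-mixing inside the vessel
#' mask at the specified decorrelation rate, bulk motion applied per
#' (position, repeat) B-scan, and additive complex Gaussian noise. Static
#' voxels therefore differ between repeats only through noise and motion.
#'
#' @param spec a [phantom_spec()].
#' @param protocol a [scan_protocol()]; supplies the volume dimensions.
#' @param subpixel_motion if `TRUE`, non-integer bulk motion is applied with
#'   a Fourier phase ramp; integer motion is a circular pixel shift.
#' @return list with `cluster` (a [cluster_volume()]) and `truth` (the
#'   expanded boundary matrices, vessel mask, per-voxel decorrelation, the
#'   2-D vessel shadow `any` projection, and the reflectivity volume).
#' @export
simulate_cluster <- function(spec, protocol, subpixel_motion = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  protocol <- validate_scan_protocol(protocol)
  ny <- protocol$n_positions; nrep <- protocol$n_repeats
  nz <- protocol$n_depth; nx <- protocol$n_alines

  bnds <- expand_boundaries(spec$layer_boundaries, ny, nx, nz)
  refl <- spec$layer_reflectivities
  zidx <- depth_index_array(ny, nz, nx)
  reflvol <- array(refl[1], dim = c(ny, nz, nx))
  for (k in seq_along(bnds)) {
    below <- zidx >= expand_yx_to_yzx(bnds[[k]], nz)
    reflvol[below] <- refl[k + 1L]
  }

  vmask <- spec$vessel_mask
  if (is.null(vmask)) vmask <- array(FALSE, dim = c(ny, nz, nx))
  if (!all(dim(vmask) == c(ny, nz, nx)))
    stop("vessel_mask must match [n_positions, n_depth, n_alines]", call. = FALSE)
  above <- vmask & (zidx <= expand_yx_to_yzx(bnds[[1L]], nz))
  if (any(above)) {
    w <- which(above, arr.ind = TRUE)
    stop(sprintf("vessel voxel at (slow=%d, depth=%d, fast=%d) is not strictly below the '%s' boundary",
                 w[1, 1], w[1, 2], w[1, 3], names(bnds)[1]), call. = FALSE)
  }
  dec <- spec$flow_decorrelation
  if (length(dec) == 1L) {
    decvol <- array(0, dim = c(ny, nz, nx))
    decvol[vmask] <- dec
  } else {
    if (!all(dim(dec) == c(ny, nz, nx)))
      stop("flow_decorrelation array must match vessel_mask dimensions", call. = FALSE)
    decvol <- dec * vmask
  }

  bm <- expand_bulk_motion(spec$bulk_motion, ny, nrep)
  fv <- which(vmask)

  data <- with_seed(spec$seed, {
    base <- reflvol * array(rcnorm(ny * nz * nx), dim = c(ny, nz, nx))
    reps <- vector("list", nrep)
    reps[[1L]] <- base
    for (r in seq_len(nrep)[-1L]) {
      cur <- reps[[r - 1L]]
      if (length(fv) > 0) {
        d <- decvol[fv]
        cur[fv] <- sqrt(1 - d) * cur[fv] + sqrt(d) * reflvol[fv] * rcnorm(length(fv))
      }
      reps[[r]] <- cur
    }
    out <- array(0i, dim = c(ny, nrep, nz, nx))
    for (r in seq_len(nrep)) {
      vol <- reps[[r]]
      for (y in seq_len(ny)) {
        b <- vol[y, , ]
        dz <- bm[y, r, 1]; dx <- bm[y, r, 2]
        if (dz != 0 || dx != 0) {
          b <- if (subpixel_motion && (dz != round(dz) || dx != round(dx)))
            fourier_shift2(b, dz, dx)
          else
            circshift2(b, as.integer(round(dz)), as.integer(round(dx)))
        }
        out[y, r, , ] <- b
      }
      if (spec$noise_sigma > 0)
        out[, r, , ] <- out[, r, , ] + spec$noise_sigma *
          array(rcnorm(ny * nz * nx), dim = c(ny, nz, nx))
    }
    out
  })

  list(
    cluster = cluster_volume(data, protocol, provenance = sprintf("phantom seed=%d", spec$seed)),
    truth = list(
      boundaries = bnds,
      vessel_mask = vmask,
      decorrelation = decvol,
      vessel_shadow = apply(vmask, c(1, 3), any),
      reflectivity = reflvol,
      bulk_motion = bm
    )
  )
}

#' Simulate a montage grid of cluster scans sharing one anatomy
#'
#' Lays out `protocol$grid_shape` cubes whose origins are spaced by the
#' non-overlapping cube fraction and renders each with `spec_factory`, so
#' overlap strips of adjacent cubes sample the same anatomy (boundaries and
#' vessels agree; speckle is drawn independently per cube, as it is for
#' independently acquired cubes).
#'
#' Cube origins are snapped to the lateral pixel grid
#' (`round((1 - f) * n)` pixels per step) so the shared anatomy is sampled
#' on a common wide-field raster.
#'
#' @param spec_factory `function(row, col, y0_px, x0_px)` returning the
#'   [phantom_spec()] for the cube at grid position (row, col) whose origin
#'   sits at global pixel `(y0_px, x0_px)` (0-based offsets).
#' @param protocol a [scan_protocol()] with `grid_shape` set.
#' @param subpixel_motion passed to [simulate_cluster()].
#' @return list with `cubes` (row-major list of [simulate_cluster()] results),
#'   `layout` (a [montage_layout()] with pixel-snapped origins) and
#'   `origins_px` (0-based global pixel offsets per cube).
#' @export
simulate_grid <- function(spec_factory, protocol, subpixel_motion = FALSE) {
  protocol <- validate_scan_protocol(protocol)
  rows <- protocol$grid_shape[1]; cols <- protocol$grid_shape[2]
  if (rows < 1L || cols < 1L) stop("grid_shape must have positive rows and cols", call. = FALSE)
  f <- protocol$overlap_fraction
  stride_y <- max(1L, as.integer(round((1 - f) * protocol$n_positions)))
  stride_x <- max(1L, as.integer(round((1 - f) * protocol$n_alines)))
  layout <- montage_layout(c(rows, cols), protocol$cube_width_mm, f,
                           snap_px = c(protocol$n_positions, protocol$n_alines))
  cubes <- vector("list", rows * cols)
  origins_px <- matrix(0L, rows * cols, 2,
                       dimnames = list(NULL, c("y_px", "x_px")))
  i <- 0L
  for (r in seq_len(rows)) {
    for (cl in seq_len(cols)) {
      i <- i + 1L
      y0 <- (r - 1L) * stride_y
      x0 <- (cl - 1L) * stride_x
      origins_px[i, ] <- c(y0, x0)
      cubes[[i]] <- simulate_cluster(spec_factory(r, cl, y0, x0), protocol,
                                     subpixel_motion = subpixel_motion)
    }
  }
  list(cubes = cubes, layout = layout, origins_px = origins_px)
}

#' Wide-field phantom presets for montage simulation
#'
#' Builds a global anatomy over the whole montage raster — gently curved
#' layer boundaries plus a network of tube vessels in the superficial (SRL)
#' and deep (DRL) retinal slabs — and returns a cube factory for
#' [simulate_grid()] together with the wide-field ground truth.
#'
#' Presets set the nuisance conditions: `"normal"` has no bulk motion and
#' 5 % noise; `"vessel-grid"` adds +/-1 px inter-repeat motion and 10 %
#' noise (relative to the SRL reflectivity); `"motion-stress"` uses +/-3 px
#' motion. Vessel decorrelation defaults to 0.8 per inter-scan interval.
#'
#' @param protocol a [scan_protocol()].
#' @param preset one of `"normal"`, `"vessel-grid"`, `"motion-stress"`.
#' @param seed integer master seed; per-cube seeds are derived from it.
#' @param decorrelation vessel decorrelation rate in `[0, 1]`.
#' @param n_vessels_per_band vessels drawn across each retinal band.
#' @return list with `spec_factory`, `truth` (global vessel mask/shadow and
#'   boundary surfaces on the wide-field raster) and `canvas_px`.
#' @export
wide_field_phantom <- function(protocol, preset = c("vessel-grid", "normal", "motion-stress"),
                               seed = 1L, decorrelation = 0.8,
                               n_vessels_per_band = 4L) {
  preset <- match.arg(preset)
  protocol <- validate_scan_protocol(protocol)
  rows <- protocol$grid_shape[1]; cols <- protocol$grid_shape[2]
  f <- protocol$overlap_fraction
  ny <- protocol$n_positions; nx <- protocol$n_alines; nz <- protocol$n_depth
  stride_y <- max(1L, as.integer(round((1 - f) * ny)))
  stride_x <- max(1L, as.integer(round((1 - f) * nx)))
  gy <- stride_y * (rows - 1L) + ny
  gx <- stride_x * (cols - 1L) + nx

  base <- default_layer_boundaries(nz)
  refl <- default_layer_reflectivities()
  # gentle global curvature so segmentation sees non-flat but smooth surfaces
  yy <- matrix(seq_len(gy), gy, gx)
  xx <- matrix(seq_len(gx), gy, gx, byrow = TRUE)
  tilt <- 0.02 * nz * sin(2 * pi * xx / gx) * 0.5 +
    0.01 * nz * cos(2 * pi * yy / gy) * 0.5
  gb <- lapply(base, function(b) pmin(pmax(b + tilt, 2), nz - 1))
  names(gb) <- names(base)

  # tube vessels in global coordinates, within the SRL and DRL bands
  vmask <- array(FALSE, dim = c(gy, nz, gx))
  rad <- 2
  vessels <- with_seed(seed, {
    bands <- list(
      SRL = c("NFL/GCL", "IPL/INL"),
      DRL = c("IPL/INL", "OPL/ONL")
    )
    v <- list()
    for (b in names(bands)) {
      for (k in seq_len(n_vessels_per_band)) {
        horiz <- (k %% 2L == 0L)
        v[[length(v) + 1L]] <- list(
          band = b, horiz = horiz,
          offset = stats::runif(1, 0.15, 0.85),
          amp = stats::runif(1, 0.02, 0.06),
          phase = stats::runif(1, 0, 2 * pi)
        )
      }
    }
    v
  })
  for (v in vessels) {
    bt <- if (v$band == "SRL") gb[["NFL/GCL"]] else gb[["IPL/INL"]]
    bb <- if (v$band == "SRL") gb[["IPL/INL"]] else gb[["OPL/ONL"]]
    if (v$horiz) {
      for (x in seq_len(gx)) {
        yc <- round(gy * (v$offset + v$amp * sin(2 * pi * x / gx + v$phase)))
        yc <- min(max(yc, rad + 1L), gy - rad)
        zc <- round((bt[yc, x] + bb[yc, x]) / 2)
        ys <- (yc - rad):(yc + rad)
        zs <- max(2L, zc - rad):min(nz, zc + rad)
        sel <- outer((ys - yc)^2, (zs - zc)^2, `+`) <= rad^2
        for (i in seq_along(ys)) vmask[ys[i], zs[sel[i, ]], x] <- TRUE
      }
    } else {
      for (y in seq_len(gy)) {
        xc <- round(gx * (v$offset + v$amp * sin(2 * pi * y / gy + v$phase)))
        xc <- min(max(xc, rad + 1L), gx - rad)
        zc <- round((bt[y, xc] + bb[y, xc]) / 2)
        xs <- (xc - rad):(xc + rad)
        zs <- max(2L, zc - rad):min(nz, zc + rad)
        sel <- outer((xs - xc)^2, (zs - zc)^2, `+`) <= rad^2
        for (i in seq_along(xs)) vmask[y, zs[sel[i, ]], xs[i]] <- TRUE
      }
    }
  }
  # keep vessels strictly below the ILM
  zidx <- depth_index_array(gy, nz, gx)
  vmask <- vmask & (zidx > expand_yx_to_yzx(gb[["ILM"]], nz))

  tissue_amp <- refl[["SRL"]]
  noise <- switch(preset, normal = 0.05, `vessel-grid` = 0.10,
                  `motion-stress` = 0.10) * tissue_amp
  motion_mag <- switch(preset, normal = 0L, `vessel-grid` = 1L, `motion-stress` = 3L)

  spec_factory <- function(row, col, y0_px, x0_px) {
    ys <- (y0_px + 1L):(y0_px + ny)
    xs <- (x0_px + 1L):(x0_px + nx)
    cube_seed <- (seed + 7919L * row + 104729L * col) %% .Machine$integer.max
    bm <- NULL
    if (motion_mag > 0L) {
      bm <- with_seed(cube_seed + 1L, {
        m <- matrix(0, protocol$n_repeats, 2)
        m[-1L, ] <- sample(seq(-motion_mag, motion_mag),
                           2L * (protocol$n_repeats - 1L), replace = TRUE)
        m
      })
    }
    phantom_spec(
      layer_boundaries = lapply(gb, function(b) b[ys, xs, drop = FALSE]),
      layer_reflectivities = refl,
      vessel_mask = vmask[ys, , xs, drop = FALSE],
      flow_decorrelation = decorrelation,
      bulk_motion = bm,
      noise_sigma = noise,
      seed = cube_seed
    )
  }

  list(
    spec_factory = spec_factory,
    truth = list(
      boundaries = gb,
      vessel_mask = vmask,
      vessel_shadow = apply(vmask, c(1, 3), any)
    ),
    canvas_px = c(gy, gx)
  )
}
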