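#' Boundary targets for layer segmentation
#'
#' The default set of seven retinal/choroidal interfaces, top to bottom,
#' with the gradient polarity the tracker looks for: `"up"` marks a
#' dark-to-bright transition with increasing depth (ILM, ELM,
#' choroid/sclera), `"down"` a bright-to-dark one.
#'
#' Boundaries are not found in anatomical order but in prominence order
#' (`order` column), each restricted to the depth band between the
#' already-found `after` and `before` boundaries (`""` meaning the volume
#' limit), optionally tightened to within `band_um` of the `near` anchor.
#' The bright RPE complex's lower edge is by far the strongest
#' bright-to-dark transition, so it anchors the search; the ELM is the
#' strongest dark-to-bright transition within a bounded distance above it,
#' the ILM the strongest one higher up, and the inner boundaries are
#' recovered by subdividing the bands these anchors delimit. The bounded
#' anatomical distances keep a weak boundary from being captured by a
#' stronger same-polarity gradient elsewhere in the scan.
#'
#' @return data.frame with columns `name`, `polarity`, `after`, `before`,
#'   `near` (`"after"`, `"before"` or `""`), `band_um`, `order`.
#' @export
boundary_targets <- function() {
  data.frame(
    name = c("ILM", "NFL/GCL", "IPL/INL", "OPL/ONL", "ELM", "RPE", "choroid/sclera"),
    polarity = c("up", "down", "down", "down", "up", "down", "up"),
    after = c("", "ILM", "NFL/GCL", "NFL/GCL", "", "", "RPE"),
    before = c("ELM", "ELM", "OPL/ONL", "ELM", "RPE", "", ""),
    near = c("", "after", "", "before", "before", "", ""),
    band_um = c(NA, 90, NA, 150, 150, NA, NA),
    order = c(3L, 5L, 7L, 6L, 2L, 1L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Layer model: named boundary surfaces over the en face grid
#'
#' @param boundaries named list of numeric `[slow, fast]` depth matrices, in
#'   anatomical (top to bottom) order; depths may be fractional pixels.
#' @param axial_pitch_um depth pixel pitch, um.
#' @param failed data.frame of `(boundary, slow)` pairs where no feasible
#'   path was found.
#' @return a `layer_model` object.
#' @export
layer_model <- function(boundaries, axial_pitch_um,
                        failed = data.frame(boundary = character(), slow = integer())) {
  stopifnot(is.list(boundaries), !is.null(names(boundaries)), axial_pitch_um > 0)
  nm <- names(boundaries)
  for (k in seq_along(boundaries)[-1L]) {
    bad <- boundaries[[k]] < boundaries[[k - 1L]]
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)
      stop(sprintf("boundary '%s' rises above '%s' at (slow=%d, fast=%d)",
                   nm[k], nm[k - 1L], w[1, 1], w[1, 2]), call. = FALSE)
    }
  }
  structure(list(boundaries = boundaries, axial_pitch_um = axial_pitch_um,
                 failed = failed), class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("<layer_model> %d boundaries on a %d x %d grid (axial pitch %.2f um)\n",
              length(x$boundaries), nrow(x$boundaries[[1]]),
              ncol(x$boundaries[[1]]), x$axial_pitch_um))
  cat("  ", paste(names(x$boundaries), collapse = ", "), "\n")
  if (nrow(x$failed)) cat(sprintf("  %d failed boundary/B-scan pairs\n", nrow(x$failed)))
  invisible(x)
}

# Minimum-cost depth path across one B-scan. cost: [depth, fast]; the path
# moves at most max_step depth pixels per column. Returns integer depths per
# column, or NULL when no finite-cost path exists.
dp_min_path <- function(cost, max_step = 2L) {
  nz <- nrow(cost); nx <- ncol(cost)
  offs <- seq.int(-max_step, max_step)
  D <- cost
  P <- matrix(0L, nz, nx)
  for (x in seq_len(nx)[-1L]) {
    prev <- D[, x - 1L]
    best <- rep(Inf, nz)
    barg <- rep(0L, nz)
    for (o in offs) {
      # predecessor depth z + o for current depth z
      src <- seq_len(nz) + o
      val <- rep(Inf, nz)
      ok <- src >= 1L & src <= nz
      val[ok] <- prev[src[ok]]
      upd <- val < best
      best[upd] <- val[upd]
      barg[upd] <- o
    }
    D[, x] <- cost[, x] + best
    P[, x] <- barg
  }
  if (!any(is.finite(D[, nx]))) return(NULL)
  path <- integer(nx)
  path[nx] <- which.min(D[, nx])
  for (x in rev(seq_len(nx - 1L)))
    path[x] <- path[x + 1L] + P[path[x + 1L], x + 1L]
  if (any(path < 1L | path > nz)) return(NULL)
  path
}

# Boxcar average of width w along dimension d, shrinking at the edges.
boxcar_dim <- function(a, d, w) {
  w <- as.integer(w)
  if (w <= 1L || dim(a)[d] == 1L) return(a)
  p <- seq_along(dim(a)); p[c(1, d)] <- p[c(d, 1)]
  b <- aperm(a, p)
  dm <- dim(b); n <- dm[1]
  dim(b) <- c(n, prod(dm[-1]))
  h <- (w - 1L) %/% 2L
  cs <- apply(b, 2, cumsum)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  top <- cs[hi, , drop = FALSE]
  bot <- rbind(0, cs)[lo, , drop = FALSE]
  out <- (top - bot) / (hi - lo + 1L)
  dim(out) <- dm
  aperm(out, p)
}

# Running median then mean along the slow axis (columns of a [slow, fast]
# matrix), with shrinking windows at the ends; the median pass rejects
# isolated per-B-scan excursions before the mean smooths the surface.
smooth_slow <- function(m, window) {
  if (window <= 1L) return(m)
  ny <- nrow(m)
  h <- (as.integer(window) - 1L) %/% 2L
  med <- m
  for (y in seq_len(ny)) {
    lo <- max(1L, y - h); hi <- min(ny, y + h)
    med[y, ] <- apply(m[lo:hi, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }
  out <- med
  for (y in seq_len(ny)) {
    lo <- max(1L, y - h); hi <- min(ny, y + h)
    out[y, ] <- colMeans(med[lo:hi, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Segment retinal boundaries from a structural volume
#'
#' Tracks each target boundary per B-scan as the minimum-cost depth path
#' through an axial-gradient cost image (negative gradient cost for
#' dark-to-bright interfaces, positive for bright-to-dark), found by dynamic
#' programming with a bounded per-column depth step. The volume is first
#' smoothed laterally and along the slow axis to suppress speckle before
#' the gradient is taken.
#'
#' Boundaries are found in the prominence order their target table
#' specifies, each restricted to lie at least `min_sep` pixels inside the
#' band delimited by its already-found `after`/`before` boundaries (see
#' [boundary_targets()]); when the table carries no band columns, targets
#' are found top to bottom, each below the previous. Surfaces are then
#' smoothed along the slow axis and clamped to anatomical order. Sparse
#' manual seed points act as hard constraints: the path is forced through
#' them, and seeded values are re-imposed after smoothing.
#'
#' When no feasible ordered path exists for a boundary on a B-scan, that
#' boundary is set to `NA` there and flagged in the returned model's
#' `failed` table.
#'
#' @param structure a [structure_volume()] or `[slow, depth, fast]` array.
#' @param targets data.frame of boundary `name` and `polarity` in anatomical
#'   order, optionally with `after`/`before`/`order` band columns; default
#'   [boundary_targets()].
#' @param seeds optional data.frame with columns `boundary`, `slow`, `fast`,
#'   `depth` of manual hint points.
#' @param axial_pitch_um depth pixel pitch recorded in the model (taken from
#'   the volume's protocol when available).
#' @param max_step maximum depth change per fast-axis column, px.
#' @param min_sep minimum separation between consecutive boundaries, px.
#' @param smooth_window moving-average window along the slow axis, frames.
#' @param presmooth integer `(slow, fast)` boxcar widths applied to the
#'   volume before the gradient; `c(1, 1)` disables.
#' @param grad_window axial half-window of the step detector: the cost at
#'   depth z compares the mean over `[z, z+grad_window-1]` with the mean
#'   over `[z-grad_window, z-1]`, which localizes a reflectivity step under
#'   speckle better than a single-pixel difference.
#' @return a [layer_model()].
#' @export
segment_layers <- function(structure, targets = boundary_targets(), seeds = NULL,
                           axial_pitch_um = NULL, max_step = 2L, min_sep = 2L,
                           smooth_window = 5L, presmooth = c(3L, 7L),
                           grad_window = 2L) {
  if (inherits(structure, "structure_volume")) {
    if (is.null(axial_pitch_um)) axial_pitch_um <- structure$protocol$axial_pitch_um
    vol <- structure$data
  } else {
    vol <- structure
  }
  if (is.null(axial_pitch_um)) axial_pitch_um <- 3.0
  d <- dim(vol)
  if (length(d) != 3L || any(d == 0L))
    stop("structure must be a nonempty [slow, depth, fast] volume", call. = FALSE)
  ny <- d[1]; nz <- d[2]; nx <- d[3]
  stopifnot(all(c("name", "polarity") %in% names(targets)))
  if (!all(c("after", "before", "order") %in% names(targets))) {
    targets$after <- c("", targets$name[-nrow(targets)])
    targets$before <- ""
    targets$order <- seq_len(nrow(targets))
  }
  if (is.null(targets$near)) targets$near <- ""
  if (is.null(targets$band_um)) targets$band_um <- NA_real_
  BIG <- 1e9

  vol <- boxcar_dim(boxcar_dim(vol, 1, presmooth[1]), 3, presmooth[2])

  res <- lapply(targets$name, function(n) matrix(NA_real_, ny, nx))
  names(res) <- targets$name
  failed <- list()
  find_order <- order(targets$order)

  h <- max(1L, as.integer(grad_window))
  for (y in seq_len(ny)) {
    img <- matrix(vol[y, , ], nz, nx)
    # step detector: mean of the h rows from z down minus the h rows above
    cs <- rbind(0, apply(img, 2, cumsum))
    g <- matrix(0, nz, nx)
    zz <- (h + 1L):(nz - h + 1L)
    g[zz, ] <- (cs[zz + h, , drop = FALSE] - cs[zz, , drop = FALSE]) / h -
      (cs[zz, , drop = FALSE] - cs[zz - h, , drop = FALSE]) / h
    found <- list()  # per-boundary depths on this B-scan
    for (k in find_order) {
      bname <- targets$name[k]
      cost <- if (targets$polarity[k] == "up") -g else g
      # band constraint vs already-found boundaries
      floor_depth <- rep(0, nx)
      ceil_depth <- rep(nz + 1, nx)
      aft <- targets$after[k]; bef <- targets$before[k]
      bad_band <- FALSE
      if (nzchar(aft)) {
        if (is.null(found[[aft]])) bad_band <- TRUE else floor_depth <- found[[aft]]
      }
      if (nzchar(bef)) {
        if (is.null(found[[bef]])) bad_band <- TRUE else ceil_depth <- found[[bef]]
      }
      if (bad_band) {
        failed[[length(failed) + 1L]] <- data.frame(boundary = bname, slow = y)
        next
      }
      if (nzchar(targets$near[k]) && !is.na(targets$band_um[k])) {
        band_px <- round(targets$band_um[k] / axial_pitch_um)
        if (targets$near[k] == "after") {
          ceil_depth <- pmin(ceil_depth, floor_depth + band_px)
        } else {
          floor_depth <- pmax(floor_depth, ceil_depth - band_px)
        }
      }
      for (x in seq_len(nx)) {
        lo <- floor(floor_depth[x] + min_sep)
        if (lo >= 1) cost[seq_len(min(nz, lo)), x] <- Inf
        hi <- ceiling(ceil_depth[x] - min_sep)
        if (hi <= nz) cost[max(1L, hi):nz, x] <- Inf
      }
      # seed constraints: force the path through given depths
      if (!is.null(seeds)) {
        sk <- seeds[seeds$boundary == bname & seeds$slow == y, , drop = FALSE]
        for (i in seq_len(nrow(sk))) {
          x <- sk$fast[i]
          cost[, x] <- BIG
          cost[max(1L, min(nz, round(sk$depth[i]))), x] <- -BIG
        }
      }
      path <- dp_min_path(cost, max_step = max_step)
      if (is.null(path)) {
        failed[[length(failed) + 1L]] <- data.frame(boundary = bname, slow = y)
      } else {
        res[[bname]][y, ] <- path
        found[[bname]] <- path
      }
    }
  }

  res <- lapply(res, smooth_slow, window = smooth_window)
  if (!is.null(seeds)) {
    for (i in seq_len(nrow(seeds)))
      res[[seeds$boundary[i]]][seeds$slow[i], seeds$fast[i]] <- seeds$depth[i]
  }
  # smoothing (or seeds) may graze the ordering; clamp to keep it monotone
  for (k in seq_along(res)[-1L]) {
    lower <- res[[k]] < res[[k - 1L]]
    lower[is.na(lower)] <- FALSE
    res[[k]][lower] <- res[[k - 1L]][lower]
  }
  layer_model(res, axial_pitch_um,
              failed = if (length(failed)) do.call(rbind, failed)
                       else data.frame(boundary = character(), slow = integer()))
}

#' Anatomical slab definition
#'
#' A slab is the depth band between two (possibly offset) boundary surfaces.
#' Offsets are given in um and converted with `round(offset / pitch)`. When
#' the bottom boundary is absent from a model, `fallback_um` below the top
#' surface is used (the deep-choroid rule for data lacking a
#' choroid/sclera boundary).
#'
#' @param name slab name.
#' @param top_boundary,bottom_boundary boundary names in the layer model.
#' @param top_offset_um,bottom_offset_um offsets in um added to each surface.
#' @param fallback_um slab thickness below the top surface when the bottom
#'   boundary is missing; `NA` to disallow.
#' @return a `slab_definition` object.
#' @export
slab_definition <- function(name, top_boundary, bottom_boundary,
                            top_offset_um = 0, bottom_offset_um = 0,
                            fallback_um = NA_real_) {
  structure(list(name = name, top_boundary = top_boundary,
                 bottom_boundary = bottom_boundary,
                 top_offset_um = top_offset_um,
                 bottom_offset_um = bottom_offset_um,
                 fallback_um = fallback_um),
            class = "slab_definition")
}

#' Standard slabs of the wide-field angiography protocol
#'
#' NFL (ILM to NFL/GCL), SRL (ganglion cell + inner plexiform), DRL (inner
#' nuclear + outer plexiform), ORL (outer nuclear to ELM), photoreceptors
#' (ELM to RPE), whole retina (ILM to RPE), choriocapillaris (30 um slab
#' beneath the RPE) and deep choroid (choriocapillaris bottom to the
#' choroid/sclera interface, defaulting to a 200 um band where that
#' boundary is unavailable).
#'
#' @return named list of [slab_definition()]s.
#' @export
standard_slabs <- function() {
  list(
    NFL = slab_definition("NFL", "ILM", "NFL/GCL"),
    SRL = slab_definition("SRL", "NFL/GCL", "IPL/INL"),
    DRL = slab_definition("DRL", "IPL/INL", "OPL/ONL"),
    ORL = slab_definition("ORL", "OPL/ONL", "ELM"),
    photoreceptors = slab_definition("photoreceptors", "ELM", "RPE"),
    whole_retina = slab_definition("whole_retina", "ILM", "RPE"),
    choriocapillaris = slab_definition("choriocapillaris", "RPE", "RPE",
                                       bottom_offset_um = 30),
    deep_choroid = slab_definition("deep_choroid", "RPE", "choroid/sclera",
                                   top_offset_um = 30, fallback_um = 200)
  )
}

#' Voxel mask of an anatomical slab
#'
#' A voxel `(slow, z, fast)` belongs to the slab iff
#' `top_depth <= z < bottom_depth` (half-open in depth), where each surface
#' is its boundary depth plus `round(offset_um / axial_pitch_um)` pixels.
#'
#' @param model a [layer_model()].
#' @param slab a [slab_definition()] or the name of a [standard_slabs()] entry.
#' @param vol_dim integer `(slow, depth, fast)` dimensions of the target
#'   volume.
#' @return logical `[slow, depth, fast]` array.
#' @export
slab_mask <- function(model, slab, vol_dim) {
  stopifnot(inherits(model, "layer_model"), length(vol_dim) == 3L)
  if (is.character(slab)) {
    slabs <- standard_slabs()
    if (!slab %in% names(slabs)) stop(sprintf("unknown slab '%s'", slab), call. = FALSE)
    slab <- slabs[[slab]]
  }
  pitch <- model$axial_pitch_um
  if (!slab$top_boundary %in% names(model$boundaries))
    stop(sprintf("slab '%s': boundary '%s' missing from model", slab$name,
                 slab$top_boundary), call. = FALSE)
  top <- model$boundaries[[slab$top_boundary]] + round(slab$top_offset_um / pitch)
  if (slab$bottom_boundary %in% names(model$boundaries)) {
    bottom <- model$boundaries[[slab$bottom_boundary]] +
      round(slab$bottom_offset_um / pitch)
  } else if (!is.na(slab$fallback_um)) {
    bottom <- top + round(slab$fallback_um / pitch)
  } else {
    stop(sprintf("slab '%s': boundary '%s' missing from model", slab$name,
                 slab$bottom_boundary), call. = FALSE)
  }
  if (!all(dim(top) == vol_dim[c(1, 3)]))
    stop("layer model grid does not match the volume's (slow, fast) shape", call. = FALSE)
  if (all(bottom <= top, na.rm = TRUE))
    stop(sprintf("slab '%s' has zero thickness everywhere", slab$name), call. = FALSE)
  nz <- vol_dim[2]
  zidx <- depth_index_array(vol_dim[1], nz, vol_dim[3])
  topv <- expand_yx_to_yzx(top, nz)
  botv <- expand_yx_to_yzx(bottom, nz)
  m <- zidx >= topv & zidx < botv
  m[is.na(m)] <- FALSE
  if (!any(m))
    stop(sprintf("slab '%s' is empty everywhere in this volume", slab$name), call. = FALSE)
  m
}
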