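#' Physical extent of a row of overlapping cubes
#'
#' `n` cubes of width `w` with fractional overlap `f` span
#' `w * (n - (n - 1) * f)`: each cube past the first adds only its
#' non-overlapping fraction. With the cube width calibrated so that a
#' 3-cube row spans 6.8 mm at 10 % overlap, a 4-cube row spans 9.0 mm, a
#' 5-cube row 11.2 mm and a 6-cube row 13.4 mm (to one decimal place).
#'
#' @param n_cubes number of cubes along the axis (vectorized).
#' @param cube_width_mm cube width, mm.
#' @param overlap_fraction fractional overlap in `[0, 0.5)`.
#' @return extent in mm.
#' @examples
#' w <- 6.8 / (3 - 2 * 0.10)       # calibrate from the 3-cube row
#' round(montage_extent(6, w, 0.10), 1)
#' @export
montage_extent <- function(n_cubes, cube_width_mm, overlap_fraction) {
  stopifnot(all(n_cubes >= 1), cube_width_mm > 0,
            overlap_fraction >= 0, overlap_fraction < 0.5)
  cube_width_mm * (n_cubes - (n_cubes - 1) * overlap_fraction)
}

#' Montage layout: cube origins and canvas extent
#'
#' Cube origins along each axis are spaced by the non-overlapping cube
#' fraction `(1 - f) * w`; the canvas extent follows [montage_extent()].
#' With `snap_px` set (cube size in pixels per axis), origin steps are
#' rounded to whole pixels so a shared anatomy can be sampled on one
#' wide-field raster; the canvas extent then matches the snapped origins.
#'
#' @param grid_shape integer `(rows, cols)`.
#' @param cube_width_mm cube width, mm (square cubes).
#' @param overlap_fraction fractional overlap in `[0, 0.5)`.
#' @param snap_px optional integer `(n_positions, n_alines)` to snap origin
#'   steps to the pixel grid.
#' @return a `montage_layout`: `grid_shape`, `cube_width_mm`,
#'   `overlap_fraction`, `origins` (data.frame `row`, `col`, `y_mm`,
#'   `x_mm`), `canvas_extent_mm` `(height, width)`.
#' @export
montage_layout <- function(grid_shape, cube_width_mm, overlap_fraction,
                           snap_px = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers", call. = FALSE)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (is.null(snap_px)) {
    step_y <- step_x <- (1 - overlap_fraction) * cube_width_mm
    extent <- c(montage_extent(rows, cube_width_mm, overlap_fraction),
                montage_extent(cols, cube_width_mm, overlap_fraction))
  } else {
    step_y <- max(1L, round((1 - overlap_fraction) * snap_px[1])) *
      cube_width_mm / snap_px[1]
    step_x <- max(1L, round((1 - overlap_fraction) * snap_px[2])) *
      cube_width_mm / snap_px[2]
    extent <- c((rows - 1L) * step_y + cube_width_mm,
                (cols - 1L) * step_x + cube_width_mm)
  }
  origins <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  origins$y_mm <- (origins$row - 1L) * step_y
  origins$x_mm <- (origins$col - 1L) * step_x
  structure(list(grid_shape = grid_shape, cube_width_mm = cube_width_mm,
                 overlap_fraction = overlap_fraction,
                 origins = origins, canvas_extent_mm = extent),
            class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat(sprintf("<montage_layout> %d x %d cubes of %.3f mm, overlap %.0f%%, FOV %.1f x %.1f mm\n",
              x$grid_shape[1], x$grid_shape[2], x$cube_width_mm,
              100 * x$overlap_fraction, x$canvas_extent_mm[1], x$canvas_extent_mm[2]))
  invisible(x)
}

#' Stitch en face tiles into a wide-field composite
#'
#' Places each tile at its nominal grid position (layout origins converted
#' to pixels), refines the placement by the integer shift maximizing the
#' normalized cross-correlation against the already-assembled canvas within
#' a search window of +/- `search_frac` of the overlap width, and blends
#' overlaps by linear feathering (per-tile weights ramp linearly over the
#' overlap band and are renormalized to sum to 1 at every covered pixel).
#' A correlation peak below `min_corr` falls back to nominal placement and
#' flags the seam.
#'
#' @param tiles row-major list of [enface_image()]s or matrices, one per
#'   layout origin.
#' @param layout a [montage_layout()].
#' @param search_frac search window as a fraction of the overlap width.
#' @param min_corr correlation threshold below which a seam falls back to
#'   its nominal placement.
#' @return list: `composite` (matrix), `shifts` (`[tile, 2]` refined minus
#'   nominal placement, px), `scores` (seam correlation per tile, `NA` for
#'   the first), `flagged` (logical per tile), `origins_px` (0-based
#'   refined placements), `layout`.
#' @export
stitch <- function(tiles, layout, search_frac = 0.2, min_corr = 0.3) {
  stopifnot(inherits(layout, "montage_layout"))
  mats <- lapply(tiles, function(t) if (inherits(t, "enface_image")) t$data else t)
  ntile <- length(mats)
  if (ntile != nrow(layout$origins))
    stop("number of tiles does not match the layout", call. = FALSE)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all tiles must share one pixel grid", call. = FALSE)
  ny <- dims[1, 1]; nx <- dims[2, 1]

  # nominal placement in pixels from the physical origins
  py <- layout$cube_width_mm / ny
  px <- layout$cube_width_mm / nx
  oy <- round(layout$origins$y_mm / py)
  ox <- round(layout$origins$x_mm / px)
  ov_y <- max(1L, ny - if (layout$grid_shape[1] > 1L) min(diff(sort(unique(oy)))) else ny)
  ov_x <- max(1L, nx - if (layout$grid_shape[2] > 1L) min(diff(sort(unique(ox)))) else nx)
  win_y <- max(1L, round(search_frac * ov_y))
  win_x <- max(1L, round(search_frac * ov_x))

  cy <- max(oy) + ny + win_y; cx <- max(ox) + nx + win_x
  num <- matrix(0, cy, cx); den <- matrix(0, cy, cx)

  ramp <- function(n, cap) pmin(pmin(seq_len(n), n + 1L - seq_len(n)), cap) / cap
  wmat <- outer(ramp(ny, ov_y), ramp(nx, ov_x), pmin)

  shifts <- matrix(0L, ntile, 2, dimnames = list(NULL, c("dy", "dx")))
  scores <- rep(NA_real_, ntile)
  flagged <- logical(ntile)
  origins_px <- matrix(0L, ntile, 2, dimnames = list(NULL, c("y_px", "x_px")))

  place <- function(tile, y0, x0) {
    rows <- (y0 + 1L):(y0 + ny); cols <- (x0 + 1L):(x0 + nx)
    num[rows, cols] <<- num[rows, cols] + wmat * tile
    den[rows, cols] <<- den[rows, cols] + wmat
  }

  for (i in seq_len(ntile)) {
    y0 <- oy[i]; x0 <- ox[i]
    if (i > 1L && ntile > 1L) {
      comp <- num / pmax(den, .Machine$double.eps)
      covered <- den > 0
      best <- -Inf; bs <- c(0L, 0L)
      for (dy in seq.int(-win_y, win_y)) {
        for (dx in seq.int(-win_x, win_x)) {
          ty <- y0 + dy; tx <- x0 + dx
          if (ty < 0L || tx < 0L || ty + ny > cy || tx + nx > cx) next
          rows <- (ty + 1L):(ty + ny); cols <- (tx + 1L):(tx + nx)
          ok <- covered[rows, cols]
          if (sum(ok) < 16L) next
          sc <- ncc_score(mats[[i]][ok], comp[rows, cols][ok])
          better <- sc > best + 1e-12 ||
            (abs(sc - best) <= 1e-12 &&
               (sum(c(dy, dx)^2) < sum(bs^2) ||
                  (sum(c(dy, dx)^2) == sum(bs^2) &&
                     (dy < bs[1] || (dy == bs[1] && dx < bs[2])))))
          if (better) { best <- sc; bs <- c(dy, dx) }
        }
      }
      scores[i] <- if (is.finite(best)) best else NA_real_
      if (is.finite(best) && best >= min_corr) {
        shifts[i, ] <- bs
        y0 <- y0 + bs[1]; x0 <- x0 + bs[2]
      } else {
        flagged[i] <- TRUE
      }
    }
    origins_px[i, ] <- c(y0, x0)
    place(mats[[i]], y0, x0)
  }

  composite <- num / pmax(den, .Machine$double.eps)
  composite[den == 0] <- 0
  # trim uncovered guard margins
  keep_r <- which(rowSums(den) > 0)
  keep_c <- which(colSums(den) > 0)
  composite <- composite[min(keep_r):max(keep_r), min(keep_c):max(keep_c), drop = FALSE]

  list(composite = composite, shifts = shifts, scores = scores,
       flagged = flagged, origins_px = origins_px, layout = layout)
}
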