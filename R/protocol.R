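#' Acquisition protocol for an OMAG cluster scan
#'
#' Describes the geometry and timing of a repeated B-scan ("cluster") OCT
#' acquisition: each slow-axis position is visited `n_repeats` times, each
#' B-scan holds `n_alines` depth profiles of `n_depth` pixels, and successive
#' B-scans are separated by `inter_bscan_interval_ms`. For montage imaging the
#' probe revisits a `grid_shape` grid of cube positions whose adjacent cubes
#' overlap by `overlap_fraction` of the cube width.
#'
#' Defaults follow the clinical protocol the package models: 245 A-lines x
#' 245 slow-axis positions x 4 repeats at a 3.7 ms inter-B-scan interval,
#' square cubes with 10 % overlap. The axial pixel pitch defaults to 3 um so
#' that a 30 um choriocapillaris slab is exactly 10 depth pixels; the lateral
#' pitch defaults to `cube_width_mm * 1000 / n_alines`. The default cube
#' width, 6.8 / 2.8 mm, is calibrated so a 3-cube montage row with 10 %
#' overlap spans 6.8 mm.
#'
#' Coordinate convention used throughout the package: arrays are indexed
#' `[slow, depth, fast]` (1-based), depth increases downward into tissue,
#' fast axis is x, slow axis is y. Physical positions are in mm, pixel
#' pitches in um.
#'
#' @param n_alines A-lines per B-scan (fast axis).
#' @param n_positions B-scan positions along the slow axis.
#' @param n_repeats repeated B-scans per cluster; at least 2.
#' @param n_depth depth pixels per A-line.
#' @param inter_bscan_interval_ms time between successive B-scans, ms.
#' @param axial_pitch_um depth pixel pitch, um.
#' @param lateral_pitch_um fast-axis pixel pitch, um; default derived from
#'   `cube_width_mm`.
#' @param cube_width_mm physical width of one scan cube, mm.
#' @param overlap_fraction fractional overlap of adjacent montage cubes,
#'   in `[0, 0.5)`.
#' @param grid_shape integer `(rows, cols)` of the montage grid.
#' @return A `scan_protocol` object (a validated named list).
#' @examples
#' p <- scan_protocol()
#' protocol_timing(p)
#' @export
scan_protocol <- function(n_alines = 245L, n_positions = 245L, n_repeats = 4L,
                          n_depth = 512L, inter_bscan_interval_ms = 3.7,
                          axial_pitch_um = 3.0, lateral_pitch_um = NULL,
                          cube_width_mm = 6.8 / 2.8, overlap_fraction = 0.10,
                          grid_shape = c(1L, 1L)) {
  if (is.null(lateral_pitch_um))
    lateral_pitch_um <- cube_width_mm * 1000 / n_alines
  p <- list(
    n_alines = as.integer(n_alines), n_positions = as.integer(n_positions),
    n_repeats = as.integer(n_repeats), n_depth = as.integer(n_depth),
    inter_bscan_interval_ms = as.numeric(inter_bscan_interval_ms),
    axial_pitch_um = as.numeric(axial_pitch_um),
    lateral_pitch_um = as.numeric(lateral_pitch_um),
    cube_width_mm = as.numeric(cube_width_mm),
    overlap_fraction = as.numeric(overlap_fraction),
    grid_shape = as.integer(grid_shape)
  )
  class(p) <- "scan_protocol"
  validate_scan_protocol(p)
}

validate_scan_protocol <- function(p) {
  stopifnot(inherits(p, "scan_protocol"))
  if (p$n_repeats < 2L) stop("n_repeats must be >= 2", call. = FALSE)
  if (p$overlap_fraction < 0 || p$overlap_fraction >= 0.5)
    stop("overlap_fraction must lie in [0, 0.5)", call. = FALSE)
  if (p$axial_pitch_um <= 0 || p$lateral_pitch_um <= 0)
    stop("pixel pitches must be > 0", call. = FALSE)
  if (p$inter_bscan_interval_ms <= 0)
    stop("inter_bscan_interval_ms must be > 0", call. = FALSE)
  if (any(c(p$n_alines, p$n_positions, p$n_depth) < 1L))
    stop("n_alines, n_positions and n_depth must be >= 1", call. = FALSE)
  if (length(p$grid_shape) != 2L || any(p$grid_shape < 1L))
    stop("grid_shape must be two positive integers", call. = FALSE)
  p
}

#' @export
print.scan_protocol <- function(x, ...) {
  t <- protocol_timing(x)
  cat(sprintf(
    "<scan_protocol> %d A-lines x %d positions x %d repeats x %d depth px\n",
    x$n_alines, x$n_positions, x$n_repeats, x$n_depth))
  cat(sprintf("  interval %.2f ms (%d fps), cube %.1f s, width %.3f mm, overlap %.0f%%, grid %dx%d\n",
              x$inter_bscan_interval_ms, t$frame_rate_hz, t$cube_time_s,
              x$cube_width_mm, 100 * x$overlap_fraction,
              x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' B-scan frame rate and per-cube acquisition time
#'
#' The frame rate is `1000 / interval_ms` rounded to the nearest integer Hz;
#' the cube time is `n_positions * n_repeats * interval_ms / 1000` seconds,
#' reported to one decimal place. With the default protocol (3.7 ms interval,
#' 245 positions x 4 repeats) this gives 270 Hz and 3.6 s.
#'
#' @param protocol a [scan_protocol()].
#' @return list with `frame_rate_hz` and `cube_time_s`.
#' @export
protocol_timing <- function(protocol) {
  protocol <- validate_scan_protocol(protocol)
  list(
    frame_rate_hz = round(1000 / protocol$inter_bscan_interval_ms),
    cube_time_s = round(protocol$n_positions * protocol$n_repeats *
                          protocol$inter_bscan_interval_ms / 1000, 1)
  )
}
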