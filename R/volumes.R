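#' Complex OCT cluster volume
#'
#' Container for the raw complex OCT signal of one scan cube, indexed
#' `[slow, repeat, depth, fast]`. The repeat axis holds the repeated B-scans
#' acquired at each slow-axis position (the "cluster"), which flow extraction
#' differentiates.
#'
#' @param data complex 4-D array `[slow][repeat][depth][fast]`.
#' @param protocol the [scan_protocol()] the volume was acquired under.
#' @param provenance free-text description of origin.
#' @return a `cluster_volume` object.
#' @export
cluster_volume <- function(data, protocol, provenance = "") {
  protocol <- validate_scan_protocol(protocol)
  d <- dim(data)
  if (length(d) != 4L)
    stop("cluster data must be a 4-D [slow, repeat, depth, fast] array", call. = FALSE)
  if (!is.complex(data)) data <- data + 0i
  if (d[2] != protocol$n_repeats)
    stop(sprintf("repeat axis (%d) does not match protocol n_repeats (%d)",
                 d[2], protocol$n_repeats), call. = FALSE)
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("cluster data must be finite", call. = FALSE)
  structure(list(data = data, protocol = protocol, provenance = provenance),
            class = "cluster_volume")
}

#' @export
print.cluster_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cluster_volume> %d positions x %d repeats x %d depth x %d A-lines\n",
              d[1], d[2], d[3], d[4]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

new_scalar_volume <- function(data, protocol, class, what) {
  if (length(dim(data)) != 3L)
    stop(sprintf("%s data must be a 3-D [slow, depth, fast] array", what), call. = FALSE)
  if (any(data < 0) || !all(is.finite(data)))
    stop(sprintf("%s values must be finite and >= 0", what), call. = FALSE)
  structure(list(data = data, protocol = protocol), class = class)
}

#' Flow-contrast volume
#'
#' Per-voxel OMAG flow contrast (mean absolute successive complex difference
#' across registered repeats), indexed `[slow, depth, fast]`. Values are
#' non-negative and zero wherever all repeats agree exactly.
#'
#' @param data non-negative 3-D array.
#' @param protocol the originating [scan_protocol()].
#' @export
flow_volume <- function(data, protocol) {
  new_scalar_volume(data, validate_scan_protocol(protocol), "flow_volume", "flow")
}

#' Structural (mean-amplitude) volume
#'
#' Per-voxel mean OCT amplitude across registered repeats, indexed
#' `[slow, depth, fast]`; the cross-sectional structural image the layer
#' segmentation operates on.
#'
#' @inheritParams flow_volume
#' @export
structure_volume <- function(data, protocol) {
  new_scalar_volume(data, validate_scan_protocol(protocol), "structure_volume", "structure")
}

#' @export
print.flow_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flow_volume> %d x %d x %d (slow x depth x fast), max %.4g\n",
              d[1], d[2], d[3], max(x$data)))
  invisible(x)
}

#' @export
print.structure_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<structure_volume> %d x %d x %d (slow x depth x fast), mean %.4g\n",
              d[1], d[2], d[3], mean(x$data)))
  invisible(x)
}

# Accept either a volume object or a bare [slow, depth, fast] array.
as_volume_array <- function(x) {
  if (inherits(x, c("flow_volume", "structure_volume"))) x$data else x
}
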