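#' Smooth a flow volume with a 3 x 3 x 3 Gaussian kernel
#'
#' Separable Gaussian over (slow, depth, fast), truncated to a 3-tap support
#' per axis and renormalized to unit sum, so constants are preserved and
#' total mass is conserved. Boundaries are handled by edge replication.
#' The default sigma of 0.8 px fills the 3-pixel support without spilling
#' significant weight outside it.
#'
#' @param flow a [flow_volume()] or `[slow, depth, fast]` array.
#' @param sigma Gaussian sigma per axis, px.
#' @return same type as the input, smoothed; non-negativity is preserved.
#' @export
smooth_flow <- function(flow, sigma = 0.8) {
  vol <- as_volume_array(flow)
  if (length(dim(vol)) != 3L || any(dim(vol) == 0L))
    stop("flow must be a nonempty 3-D volume", call. = FALSE)
  w1 <- exp(-1 / (2 * sigma^2))
  s <- 1 + 2 * w1
  w0 <- 1 / s; w1 <- w1 / s
  for (d in 1:3) vol <- blur_dim(vol, d, w0, w1)
  if (inherits(flow, "flow_volume")) flow_volume(pmax(vol, 0), flow$protocol) else pmax(vol, 0)
}

# 3-tap [w1, w0, w1] convolution along dimension d with edge replication.
blur_dim <- function(a, d, w0, w1) {
  if (dim(a)[d] == 1L) return(a)  # weights renormalize to the single sample
  p <- seq_along(dim(a)); p[c(1, d)] <- p[c(d, 1)]
  b <- aperm(a, p)
  dm <- dim(b); n <- dm[1]
  dim(b) <- c(n, prod(dm[-1]))
  out <- w0 * b + w1 * (b[c(1L, seq_len(n - 1L)), , drop = FALSE] +
                          b[c(seq_len(n - 1L) + 1L, n), , drop = FALSE])
  dim(out) <- dm
  aperm(out, p)
}

#' En face image
#'
#' A 2-D `[slow, fast]` projection of a volume within one slab, with the
#' slab name, a flag map of columns whose slab mask was empty, and a record
#' of any display normalization applied (`NULL` until display scaling).
#'
#' @param data non-negative `[slow, fast]` matrix.
#' @param slab slab name.
#' @param empty logical `[slow, fast]` matrix marking empty-mask columns.
#' @param normalization record of display scaling, or `NULL`.
#' @export
enface_image <- function(data, slab = "", empty = NULL, normalization = NULL) {
  stopifnot(is.matrix(data))
  if (any(data < 0)) stop("en face values must be >= 0", call. = FALSE)
  if (is.null(empty)) empty <- matrix(FALSE, nrow(data), ncol(data))
  structure(list(data = data, slab = slab, empty = empty,
                 normalization = normalization), class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d (slow x fast), slab '%s', max %.4g\n",
              nrow(x$data), ncol(x$data), x$slab, max(x$data)))
  invisible(x)
}

#' Maximum amplitude projection within a slab
#'
#' For each en face pixel, takes the maximum of the volume over the masked
#' depths at that (slow, fast) location. Columns whose mask is empty are set
#' to 0 and flagged in the result's `empty` map.
#'
#' @param flow a [flow_volume()], [structure_volume()] or 3-D array.
#' @param mask logical slab mask matching the volume (see [slab_mask()]).
#' @param slab slab name recorded on the image.
#' @return an [enface_image()].
#' @export
max_project <- function(flow, mask, slab = "") {
  vol <- as_volume_array(flow)
  if (!all(dim(mask) == dim(vol)))
    stop("mask shape does not match the volume", call. = FALSE)
  if (!any(mask)) stop("slab mask is empty: nothing to project", call. = FALSE)
  tmp <- ifelse(mask, vol, -Inf)
  img <- apply(tmp, c(1, 3), max)
  empty <- !is.finite(img)
  img[empty] <- 0
  enface_image(img, slab = slab, empty = empty)
}

#' Mean projection within a slab
#'
#' Companion to [max_project()] for structural en face views: the mean of
#' the masked depths per pixel.
#'
#' @inheritParams max_project
#' @return an [enface_image()].
#' @export
mean_project <- function(flow, mask, slab = "") {
  vol <- as_volume_array(flow)
  if (!all(dim(mask) == dim(vol)))
    stop("mask shape does not match the volume", call. = FALSE)
  if (!any(mask)) stop("slab mask is empty: nothing to project", call. = FALSE)
  num <- apply(vol * mask, c(1, 3), sum)
  cnt <- apply(mask, c(1, 3), sum)
  img <- num / pmax(cnt, 1L)
  empty <- cnt == 0L
  img[empty] <- 0
  enface_image(img, slab = slab, empty = empty)
}

#' Depth-coded RGB composite of three slab angiograms
#'
#' Maps the superficial, deep and outer retinal en face images to the red,
#' green and blue channels, each normalized to `[0, 1]` by its own high
#' percentile (display scaling only; the inputs are not modified).
#' Co-located superficial and deep flow therefore renders yellow.
#'
#' @param srl,drl,orl [enface_image()]s (or matrices) of equal shape.
#' @param percentile normalization percentile per channel, in (0, 1].
#' @return numeric `[slow, fast, 3]` RGB array in `[0, 1]`.
#' @export
color_composite <- function(srl, drl, orl, percentile = 0.99) {
  chans <- lapply(list(srl, drl, orl), function(x)
    if (inherits(x, "enface_image")) x$data else x)
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("the three en face images must have identical shapes", call. = FALSE)
  norm1 <- function(m) {
    q <- stats::quantile(m, percentile, names = FALSE)
    if (q <= 0) return(m * 0)
    pmin(m / q, 1)
  }
  out <- array(0, dim = c(dims[[1]], 3L))
  for (i in 1:3) out[, , i] <- norm1(chans[[i]])
  out
}
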