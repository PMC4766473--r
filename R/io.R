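#' Write a cluster volume to a self-describing container
#'
#' The container is a directory holding `real.tif` and `imag.tif`
#' (32-bit float multi-page TIFFs, one page per (position, repeat) B-scan,
#' position-major) plus `meta.yaml` with the full acquisition protocol, the
#' array dimensions, the value scaling and provenance. Complex values are
#' stored as `(v / scale_max + 1) / 2` so both components fit the TIFF
#' `[0, 1]` float range; `scale_max` is recorded in the metadata, making the
#' round-trip exact to 32-bit float precision.
#'
#' @param cluster a [cluster_volume()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_cluster <- function(cluster, path) {
  stopifnot(inherits(cluster, "cluster_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cluster$data)
  scale_max <- max(abs(Re(cluster$data)), abs(Im(cluster$data)), 1e-12)
  enc <- function(v) (v / scale_max + 1) / 2
  pages_re <- vector("list", d[1] * d[2])
  pages_im <- vector("list", d[1] * d[2])
  i <- 0L
  for (y in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      i <- i + 1L
      b <- matrix(cluster$data[y, r, , ], d[3], d[4])
      pages_re[[i]] <- enc(Re(b))
      pages_im[[i]] <- enc(Im(b))
    }
  }
  tiff::writeTIFF(pages_re, file.path(path, "real.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(pages_im, file.path(path, "imag.tif"), bits.per.sample = 32L)
  meta <- c(
    list(format = "omag-cluster-v1",
         dims = as.integer(d),
         scale_max = scale_max,
         provenance = cluster$provenance),
    unclass(cluster$protocol)
  )
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

required_cluster_meta <- function() {
  c("dims", "scale_max", "n_alines", "n_positions", "n_repeats", "n_depth",
    "inter_bscan_interval_ms", "axial_pitch_um", "lateral_pitch_um",
    "cube_width_mm", "overlap_fraction", "grid_shape")
}

#' Read a cluster volume container
#'
#' Reads a directory written by [write_cluster()]. Any missing metadata
#' attribute is reported by name.
#'
#' @param path container directory.
#' @return a [cluster_volume()].
#' @export
read_cluster <- function(path) {
  mf <- file.path(path, "meta.yaml")
  if (!file.exists(mf)) stop(sprintf("no meta.yaml under '%s'", path), call. = FALSE)
  meta <- yaml::read_yaml(mf)
  missing <- setdiff(required_cluster_meta(), names(meta))
  if (length(missing))
    stop(sprintf("cluster metadata lacks attribute(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  protocol <- scan_protocol(
    n_alines = meta$n_alines, n_positions = meta$n_positions,
    n_repeats = meta$n_repeats, n_depth = meta$n_depth,
    inter_bscan_interval_ms = meta$inter_bscan_interval_ms,
    axial_pitch_um = meta$axial_pitch_um,
    lateral_pitch_um = meta$lateral_pitch_um,
    cube_width_mm = meta$cube_width_mm,
    overlap_fraction = meta$overlap_fraction,
    grid_shape = meta$grid_shape
  )
  read_cluster_pair(file.path(path, "real.tif"), file.path(path, "imag.tif"),
                    protocol, scale_max = meta$scale_max,
                    provenance = meta$provenance %||% "")
}

#' Read a legacy real/imaginary TIFF pair
#'
#' Reads the two-file layout (one multi-page float TIFF per complex
#' component, pages ordered position-major over (position, repeat), values
#' stored as `(v / scale_max + 1) / 2`) given the acquisition protocol
#' explicitly, for inputs that carry no metadata sidecar.
#'
#' @param real_path,imag_path multi-page TIFF paths.
#' @param protocol a [scan_protocol()] describing the acquisition.
#' @param scale_max amplitude scale of the stored values.
#' @param provenance free text recorded on the volume.
#' @return a [cluster_volume()].
#' @export
read_cluster_pair <- function(real_path, imag_path, protocol, scale_max = 1,
                              provenance = "") {
  protocol <- validate_scan_protocol(protocol)
  dec <- function(p) (2 * p - 1) * scale_max
  re <- tiff::readTIFF(real_path, all = TRUE)
  im <- tiff::readTIFF(imag_path, all = TRUE)
  ny <- protocol$n_positions; nrep <- protocol$n_repeats
  nz <- protocol$n_depth; nx <- protocol$n_alines
  if (length(re) != ny * nrep || length(im) != ny * nrep)
    stop(sprintf("expected %d pages per component, found %d/%d",
                 ny * nrep, length(re), length(im)), call. = FALSE)
  data <- array(0i, dim = c(ny, nrep, nz, nx))
  i <- 0L
  for (y in seq_len(ny)) {
    for (r in seq_len(nrep)) {
      i <- i + 1L
      data[y, r, , ] <- complex(real = dec(re[[i]]), imaginary = dec(im[[i]]))
    }
  }
  cluster_volume(data, protocol, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an en face image as quantitative TIFF and display PNG
#'
#' The 16-bit grayscale TIFF stores `data / scale_max`, with `scale_max`
#' recorded in a JSON sidecar (quantitative values are recoverable); the
#' 8-bit PNG applies the display percentile normalization.
#'
#' @param image an [enface_image()].
#' @param tif_path,png_path output paths (`NULL` to skip either).
#' @param percentile display-normalization percentile for the PNG.
#' @return invisibly, the sidecar metadata list.
#' @export
write_enface <- function(image, tif_path = NULL, png_path = NULL,
                         percentile = 0.99) {
  stopifnot(inherits(image, "enface_image"))
  scale_max <- max(image$data, 1e-12)
  meta <- list(slab = image$slab, scale_max = scale_max,
               percentile = percentile)
  if (!is.null(tif_path)) {
    tiff::writeTIFF(image$data / scale_max, tif_path, bits.per.sample = 16L)
    jsonlite::write_json(meta, paste0(tif_path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(png_path)) {
    q <- stats::quantile(image$data, percentile, names = FALSE)
    disp <- if (q > 0) pmin(image$data / q, 1) else image$data * 0
    png::writePNG(disp, png_path)
  }
  invisible(meta)
}

#' Write a logical mask as an 8-bit multi-page TIFF
#'
#' Pages run over the slow axis; each page is the `[depth, fast]` mask of
#' one B-scan.
#'
#' @param mask logical `[slow, depth, fast]` array.
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask)
  pages <- lapply(seq_len(d[1]), function(y) matrix(as.numeric(mask[y, , ]), d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
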