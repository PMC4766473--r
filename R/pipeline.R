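#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end wide-field angiography pipeline:
#' the acquisition protocol, the phantom preset (when simulating), flow
#' extraction options, segmentation options, the slab list, en face options,
#' montage options, the RNG seed and the output directory. The object
#' round-trips losslessly through its YAML serialization
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param protocol a [scan_protocol()].
#' @param preset phantom preset for simulated input (see
#'   [wide_field_phantom()]).
#' @param flow list: `phase_compensation`, `subpixel`, `amplitude_only`.
#' @param segmentation list: `max_step`, `min_sep`, `smooth_window`.
#' @param slabs character vector of [standard_slabs()] names to project.
#' @param enface list: `sigma`, `percentile`.
#' @param montage list: `search_frac`, `min_corr`.
#' @param seed integer seed driving all simulation randomness.
#' @param out_dir output directory.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(protocol = scan_protocol(),
                            preset = "vessel-grid",
                            flow = list(phase_compensation = FALSE,
                                        subpixel = FALSE,
                                        amplitude_only = FALSE),
                            segmentation = list(max_step = 2L, min_sep = 2L,
                                                smooth_window = 5L),
                            slabs = c("SRL", "DRL", "ORL"),
                            enface = list(sigma = 0.8, percentile = 0.99),
                            montage = list(search_frac = 0.2, min_corr = 0.3),
                            seed = 1L, out_dir = "omag-out") {
  cfg <- list(
    protocol = validate_scan_protocol(protocol),
    preset = preset,
    flow = list(
      phase_compensation = isTRUE(flow$phase_compensation),
      subpixel = isTRUE(flow$subpixel),
      amplitude_only = isTRUE(flow$amplitude_only)
    ),
    segmentation = list(
      max_step = as.integer(segmentation$max_step %||% 2L),
      min_sep = as.integer(segmentation$min_sep %||% 2L),
      smooth_window = as.integer(segmentation$smooth_window %||% 5L)
    ),
    slabs = as.character(slabs),
    enface = list(sigma = as.numeric(enface$sigma %||% 0.8),
                  percentile = as.numeric(enface$percentile %||% 0.99)),
    montage = list(search_frac = as.numeric(montage$search_frac %||% 0.2),
                   min_corr = as.numeric(montage$min_corr %||% 0.3)),
    seed = as.integer(seed),
    out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$protocol <- unclass(x$protocol)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    protocol = do.call(scan_protocol, x$protocol),
    preset = x$preset, flow = x$flow, segmentation = x$segmentation,
    slabs = x$slabs, enface = x$enface, montage = x$montage,
    seed = x$seed, out_dir = x$out_dir
  )
}

#' Run the wide-field angiography pipeline end to end
#'
#' Simulates (or accepts) a montage grid of cluster scans, then per cube:
#' registers and differentiates the repeats into flow and structure volumes,
#' segments the retinal boundaries, builds the configured slab masks,
#' Gaussian-smooths the flow volume and maximum-projects each slab, and
#' renders the SRL/DRL/ORL color composite. Per-slab en face tiles are then
#' stitched into the wide-field composite. All images are written under
#' `config$out_dir` (quantitative 16-bit TIFF plus display PNG) together
#' with a machine-readable JSON report carrying per-cube registration
#' shifts, seam scores, the field of view, timings and provenance
#' (config hash, seed, package version). Identical config and seed give
#' identical image outputs.
#'
#' @param config a [pipeline_config()].
#' @param cubes optional row-major list of [simulate_cluster()]-style
#'   results (`list(cluster=, truth=)` or bare [cluster_volume()]s); when
#'   `NULL` the phantom preset is simulated.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, cubes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  protocol <- config$protocol
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "stitched"), showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  if (is.null(cubes)) {
    ph <- wide_field_phantom(protocol, preset = config$preset, seed = config$seed)
    sim <- simulate_grid(ph$spec_factory, protocol)
    cubes <- sim$cubes
    layout <- sim$layout
  } else {
    cubes <- lapply(cubes, function(cb)
      if (inherits(cb, "cluster_volume")) list(cluster = cb, truth = NULL) else cb)
    layout <- montage_layout(protocol$grid_shape, protocol$cube_width_mm,
                             protocol$overlap_fraction,
                             snap_px = c(protocol$n_positions, protocol$n_alines))
  }

  slabs <- standard_slabs()[config$slabs]
  tiles <- stats::setNames(vector("list", length(slabs)), names(slabs))
  for (s in names(slabs)) tiles[[s]] <- vector("list", length(cubes))
  cube_reports <- vector("list", length(cubes))

  for (i in seq_along(cubes)) {
    rc <- layout$origins[i, c("row", "col")]
    tag <- sprintf("cube_r%dc%d", rc$row, rc$col)
    cdir <- file.path(out, tag)
    dir.create(cdir, showWarnings = FALSE)
    rec <- list(cube = tag, status = "ok")
    t_cube <- proc.time()[["elapsed"]]
    res <- tryCatch({
      vols <- build_volumes(cubes[[i]]$cluster,
                            phase_compensation = config$flow$phase_compensation,
                            subpixel = config$flow$subpixel,
                            amplitude_only = config$flow$amplitude_only)
      model <- segment_layers(vols$structure,
                              max_step = config$segmentation$max_step,
                              min_sep = config$segmentation$min_sep,
                              smooth_window = config$segmentation$smooth_window)
      sm <- smooth_flow(vols$flow, sigma = config$enface$sigma)
      efs <- list()
      for (s in names(slabs)) {
        m <- slab_mask(model, slabs[[s]], dim(vols$flow$data))
        ef <- max_project(sm, m, slab = s)
        efs[[s]] <- ef
        write_enface(ef,
                     tif_path = file.path(cdir, paste0("enface_", s, ".tif")),
                     png_path = file.path(cdir, paste0("enface_", s, ".png")),
                     percentile = config$enface$percentile)
      }
      if (all(c("SRL", "DRL", "ORL") %in% names(efs))) {
        rgb <- color_composite(efs$SRL, efs$DRL, efs$ORL,
                               percentile = config$enface$percentile)
        png::writePNG(rgb, file.path(cdir, "composite_rgb.png"))
      }
      rec$registration_shifts <- list(
        max_abs = max(abs(vols$report$shifts)),
        n_warnings = sum(vols$report$warnings)
      )
      rec$segmentation_failed <- nrow(model$failed)
      list(efs = efs)
    }, error = function(e) {
      rec$status <<- "error"
      rec$message <<- conditionMessage(e)
      NULL
    })
    rec$elapsed_s <- round(proc.time()[["elapsed"]] - t_cube, 3)
    cube_reports[[i]] <- rec
    if (!is.null(res)) for (s in names(slabs)) tiles[[s]][[i]] <- res$efs[[s]]
  }

  seam <- list()
  for (s in names(slabs)) {
    ok <- !vapply(tiles[[s]], is.null, logical(1))
    if (!all(ok)) { seam[[s]] <- list(status = "skipped: missing tiles"); next }
    st <- stitch(tiles[[s]], layout,
                 search_frac = config$montage$search_frac,
                 min_corr = config$montage$min_corr)
    comp <- enface_image(st$composite, slab = s)
    write_enface(comp,
                 tif_path = file.path(out, "stitched", paste0(s, ".tif")),
                 png_path = file.path(out, "stitched", paste0(s, ".png")),
                 percentile = config$enface$percentile)
    seam[[s]] <- list(scores = unname(st$scores),
                      flagged = unname(st$flagged),
                      shifts = st$shifts)
  }

  fov <- layout$canvas_extent_mm
  report <- list(
    provenance = list(
      package = "omagr",
      version = as.character(utils::packageVersion("omagr")),
      seed = config$seed,
      config_md5 = cfg_hash
    ),
    fov = sprintf("%.1f × %.1f mm", fov[1], fov[2]),
    grid = paste(protocol$grid_shape, collapse = "x"),
    cubes = cube_reports,
    seams = seam,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
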