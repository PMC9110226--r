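#' Write the artifacts of a pipeline run
#'
#' Lays out a run directory: \code{report.json} (config echo, metrics, region
#' reports, restoration diagnostics and the normalization ranges used by the
#' image exports), one multi-page TIFF per arm with the reconstructed frames,
#' and per-map pseudocolor PNGs rendered with a fixed colormap over fixed,
#' recorded value ranges so renders are reproducible across runs.
#'
#' @param report A \code{ctp_run_report} from [run_pipeline()].
#' @param out_dir Directory to create/fill.
#' @return \code{out_dir}, invisibly.
#' @export
write_run_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)

  # fixed per-map display ranges taken from the reference arm
  ref <- report$arm_outputs$clean_reference$maps
  ranges <- lapply(ref, function(m) {
    v <- m[is.finite(m)]
    c(min(v), max(v))
  })

  for (arm in names(report$arm_outputs)) {
    out <- report$arm_outputs[[arm]]
    if (!is.null(out$frames))
      write_stack_tiff(out$frames, file.path(out_dir,
                                             paste0("frames_", arm, ".tif")))
    for (m in names(out$maps)) {
      write_map_png(out$maps[[m]], ranges[[m]],
                    file.path(maps_dir, sprintf("%s_%s.png", arm, m)))
    }
  }

  body <- list(
    version = report$version,
    seed = report$seed,
    arms = report$arms,
    config = config_echo(report$config),
    restoration = report$restoration,
    metrics = report$metrics,
    region_reports = report$region_reports,
    map_display_ranges = ranges,
    colormap = "viridis"
  )
  jsonlite::write_json(body, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(out_dir)
}

# serializable echo of a run_config
config_echo <- function(cfg) {
  list(
    grid_size = cfg$grid_size, frame_count = cfg$frame_count,
    frame_interval_s = cfg$frame_interval_s, n_views = cfg$n_views,
    fov_mm = cfg$fov_mm, mu_per_unit = cfg$mu_per_unit,
    n_baseline = cfg$n_baseline, seed = cfg$seed, arms = cfg$arms,
    noise = unclass(cfg$noise),
    restoration = unclass(cfg$restoration),
    recon = unclass(cfg$recon),
    regions = lapply(cfg$regions, unclass),
    kinetics = lapply(cfg$kinetics, unclass)
  )
}

#' Write an image stack as a multi-page TIFF
#'
#' Each frame is normalized by the stack's global range to [0, 1]; the range
#' is returned (and recorded in the run report when called from
#' [write_run_artifacts()]).
#'
#' @param stack A [dynamic_image()] or 3-D array.
#' @param path Output file.
#' @return Numeric length-2 normalization range, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  a <- unclass(stack)
  lo <- min(a); hi <- max(a)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(a)[3]), function(f) (a[, , f] - lo) / scale)
  tiff::writeTIFF(pages, path)
  invisible(c(lo, hi))
}

#' Render a parameter map to a pseudocolor PNG
#'
#' Values are clamped to \code{range}, mapped through a fixed 256-level
#' viridis colormap, and written as RGB; non-finite pixels render black.
#'
#' @param map Numeric matrix.
#' @param range Length-2 display range (fixed by the caller so renders are
#'   comparable between runs).
#' @param path Output file.
#' @export
write_map_png <- function(map, range, path) {
  pal <- t(grDevices::col2rgb(hcl.colors(256, "viridis"))) / 255
  v <- (map - range[1]) / max(range[2] - range[1], .Machine$double.eps)
  v[!is.finite(v)] <- NA
  idx <- pmin(pmax(floor(v * 255) + 1L, 1L), 256L)
  rgb <- array(0, dim = c(nrow(map), ncol(map), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(map), ncol(map))
    plane[ok] <- pal[idx[ok], ch]
    rgb[, , ch] <- plane
  }
  png::writePNG(rgb, path)
  invisible(path)
}
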