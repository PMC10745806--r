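# End-to-end pipeline: configuration, single-axon analysis, and batch runs
# over image + trace pairs with per-group profiles, metrics and comparisons.

#' Pipeline configuration
#'
#' Houses every numeric constant of the analysis. Defaults are the reference
#' values of the workflow: 25 um straightened width, strict 0.5 um minimum
#' collateral length, 5 um excised shaft band, 4-pixel transverse bins,
#' 70 um dorsal extent, FDR at q = 0.05.
#'
#' @param width_um Straightened band width (um).
#' @param min_collateral_um Minimum collateral length (um, strict).
#' @param band_um Excised shaft band width (um).
#' @param bin_px Transverse bin width in pixels.
#' @param dorsal_extent_um Dorsal region length (um).
#' @param q FDR level for profile comparisons.
#' @param fdr_method `"bky"` or `"bh"`.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param fixed_value Intensity threshold when `threshold = "fixed"`.
#' @param pixel_size_x,pixel_size_y Optional pixel-size overrides (um/px).
#' @param trace_units Units of CSV trace coordinates (`"px"` or `"um"`).
#' @param seed Integer seed for any stochastic step.
#' @return Object of class `axo_config`.
#' @export
pipeline_config <- function(width_um = 25, min_collateral_um = 0.5,
                            band_um = 5, bin_px = 4L, dorsal_extent_um = 70,
                            q = 0.05, fdr_method = "bky",
                            threshold = "otsu", fixed_value = NULL,
                            pixel_size_x = NULL, pixel_size_y = NULL,
                            trace_units = "px", seed = 1L) {
  for (v in list(width_um, min_collateral_um, band_um, bin_px,
                 dorsal_extent_um))
    if (!is.numeric(v) || v <= 0) stop("physical parameters must be > 0")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  structure(
    list(width_um = width_um, min_collateral_um = min_collateral_um,
         band_um = band_um, bin_px = as.integer(bin_px),
         dorsal_extent_um = dorsal_extent_um, q = q,
         fdr_method = match.arg(fdr_method, c("bky", "bh")),
         threshold = match.arg(threshold, c("otsu", "fixed")),
         fixed_value = fixed_value,
         pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
         trace_units = match.arg(trace_units, c("px", "um")),
         seed = as.integer(seed)),
    class = "axo_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of `key = value`; `#` starts a comment; unknown keys are an error.
#' Values override [pipeline_config()] defaults.
#'
#' @param path Path to the config file.
#' @return An `axo_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(pipeline_config)
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- if (key %in% c("fdr_method", "threshold", "trace_units"))
                     val else as.numeric(val)
  }
  do.call(pipeline_config, args)
}

#' Analyze one axon image along its trace
#'
#' Runs straighten -> threshold/skeletonize/filter -> shaft-band excision ->
#' density binning -> branching summary for a single image + trace pair.
#'
#' @param image A [planar_image()] (e.g. a maximum intensity projection).
#' @param trace A 2D [axon_trace()].
#' @param config An [pipeline_config()].
#' @return List: `str` (straightened image), `mask` (band-excised collateral
#'   mask), `grid` (`axo_density`), `intensity_grid` (densities from the
#'   straightened intensities), `branching` (`axo_branching`).
#' @export
analyze_axon <- function(image, trace, config = pipeline_config()) {
  str_img <- straighten_image(image, trace, config$width_um)
  mask <- make_mask(str_img, config$min_collateral_um, config$threshold,
                    config$fixed_value)
  mask <- remove_shaft_band(mask, config$band_um)
  str_banded <- remove_shaft_band(str_img, config$band_um)
  list(str = str_img,
       mask = mask,
       grid = density_grid(mask, config$bin_px),
       intensity_grid = density_grid(str_banded, config$bin_px),
       branching = branching_summary(mask, config$dorsal_extent_um))
}

#' Batch-process image + trace pairs into per-group results
#'
#' @param inputs Data frame with columns `image` (TIFF paths), `trace`
#'   (trace paths) and `group` (labels); or a list of already-loaded
#'   `list(image =, trace =, group =)` entries.
#' @param config An [pipeline_config()].
#' @param out_dir Output directory, created if needed. Per-axon STR/MASK
#'   TIFFs, per-group transverse/longitudinal profile TSVs, a metrics table,
#'   a comparison table for the first two groups, and a JSON run manifest
#'   are written.
#' @return Invisibly, a list with the per-axon results, per-group profiles,
#'   the metrics data frame and (for two groups) the profile comparisons.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir) {
  entries <- load_inputs(inputs, config)
  if (!length(entries)) stop("empty input list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- vector("list", length(entries))
  metrics <- NULL
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    res <- analyze_axon(e$image, e$trace, config)
    tag <- sprintf("axon_%03d", i)
    write_image(res$str, file.path(out_dir, paste0(tag, "_STR.tif")),
                bits = 32L)
    write_image(res$mask, file.path(out_dir, paste0(tag, "_MASK.tif")))
    b <- res$branching
    metrics <- rbind(metrics, data.frame(
      id = tag, group = e$group,
      axon_length_um = b$axon_length_um,
      total_branching = b$total_branching,
      dorsal_branching = b$dorsal_branching,
      ventral_branching = b$ventral_branching,
      n_components = b$n_components))
    results[[i]] <- c(res, list(group = e$group))
  }
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  groups <- unique(metrics$group)
  profs <- list()
  for (g in groups) {
    grids <- lapply(results[metrics$group == g], `[[`, "grid")
    profs[[g]] <- list(transverse = transverse_profile(grids),
                       longitudinal = longitudinal_profile(grids))
    write_profiles_tsv(profs[[g]]$transverse,
                       file.path(out_dir, paste0(g, "_transverse.tsv")))
    write_profiles_tsv(profs[[g]]$longitudinal,
                       file.path(out_dir, paste0(g, "_longitudinal.tsv")))
  }

  comparisons <- NULL
  if (length(groups) >= 2L) {
    g1 <- groups[1]; g2 <- groups[2]
    comparisons <- list(
      transverse = compare_profiles(profs[[g1]]$transverse,
                                    profs[[g2]]$transverse,
                                    config$q, config$fdr_method),
      longitudinal = compare_profiles(profs[[g1]]$longitudinal,
                                      profs[[g2]]$longitudinal,
                                      config$q, config$fdr_method))
    for (ax in names(comparisons))
      utils::write.table(comparisons[[ax]],
                         file.path(out_dir, paste0("compare_", ax, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("axoquant")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    n_inputs = length(entries),
    groups = as.list(table(metrics$group)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, profiles = profs, metrics = metrics,
                 comparisons = comparisons))
}

load_inputs <- function(inputs, config) {
  if (is.data.frame(inputs)) {
    stopifnot(all(c("image", "trace", "group") %in% names(inputs)))
    return(lapply(seq_len(nrow(inputs)), function(i) {
      img <- read_image(inputs$image[i], config$pixel_size_x,
                        config$pixel_size_y)
      if (!file.exists(inputs$trace[i]))
        stop("missing trace for ", inputs$image[i])
      tr <- read_trace(inputs$trace[i], img$pixel_size_x, img$pixel_size_y,
                       units = config$trace_units)
      list(image = img, trace = tr, group = inputs$group[i])
    }))
  }
  lapply(inputs, function(e) {
    stopifnot(all(c("image", "trace", "group") %in% names(e)))
    e
  })
}
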