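#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter with the workflow's standard defaults:
#' 8-neighbour conductance graph, ten Jenks current categories with the
#' two lowest dropped for the corridor, three levels within a 10 km
#' type-I buffer for pinch points. A configuration can also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param preset Synthetic-scene preset, `"channel"` or `"mosaic"`;
#'   ignored when a `scene` is supplied to [run_pipeline()].
#' @param seed Master seed for scene generation, point sampling, and the
#'   validation null.
#' @param nrows,ncols,cell_size Scene grid geometry.
#' @param neighborhood 4 or 8.
#' @param corridor_k,drop_classes Jenks classes for corridor extraction
#'   and the number of lowest (negligible-current) classes dropped.
#' @param pinch_k Jenks levels within the buffer.
#' @param buffer_radius_m Type-I buffer radius, metres.
#' @param n_warning_points Observation points sampled from the current
#'   map.
#' @param tolerance_cells Validation match tolerance, cells.
#' @param n_null Monte-Carlo draws for the validation null.
#' @param cap Optional factor-value cap (see [resistance_surface()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("channel", "mosaic"), seed = 1,
                            nrows = 100, ncols = 100, cell_size = 200,
                            neighborhood = 8, corridor_k = 10,
                            drop_classes = 2, pinch_k = 3,
                            buffer_radius_m = 10000,
                            n_warning_points = 200, tolerance_cells = 2,
                            n_null = 1000, cap = Inf, out_dir = NULL) {
  cfg <- list(preset = match.arg(preset), seed = seed, nrows = nrows,
              ncols = ncols, cell_size = cell_size,
              neighborhood = neighborhood, corridor_k = corridor_k,
              drop_classes = drop_classes, pinch_k = pinch_k,
              buffer_radius_m = buffer_radius_m,
              n_warning_points = n_warning_points,
              tolerance_cells = tolerance_cells, n_null = n_null,
              cap = cap, out_dir = out_dir)
  stopifnot(cfg$neighborhood %in% c(4, 8), cfg$corridor_k >= 2,
            cfg$drop_classes >= 0, cfg$drop_classes < cfg$corridor_k,
            cfg$pinch_k >= 2, cfg$buffer_radius_m >= 0, cfg$n_null >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file of configuration fields (unknown fields are an
#'   error).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full connectivity pipeline
#'
#' Executes the stages in order — patches, resistance surface, circuit
#' network, corridors, pinch points, validation — on a synthetic scene
#' (or one supplied by the caller) and returns a structured run report.
#' With `out_dir` set, every intermediate raster is written as an ESRI
#' ASCII grid, vector products as GeoJSON, tables as CSV, and the report
#' (with the resolved configuration and package version, for provenance)
#' as JSON. Reruns with the same configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param scene Optional `synthetic_scene`; by default one is generated
#'   from the preset and seed in `config`.
#' @return A `pipeline_report` list: `config`, `patch_table`, `reff`,
#'   `corridor` (threshold, group count, composition), `pinch` (area,
#'   composition), `validation`, and the intermediate objects under
#'   `layers`.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scene)) {
    scene <- switch(config$preset,
      channel = channel_scene(config$nrows, config$ncols, config$cell_size,
                              seed = config$seed),
      mosaic = mosaic_scene(config$nrows, config$ncols, config$cell_size,
                            seed = config$seed))
  }
  labels <- rasterize_patches(scene$patches, scene$spec)
  rs <- resistance_surface(scene$dem, scene$landuse, cap = config$cap)
  graph <- build_graph(rs$resistance, labels,
                       neighborhood = config$neighborhood)
  acc <- accumulate_current(graph)
  corridor <- extract_corridors(acc$current, labels, k = config$corridor_k,
                                drop_classes = config$drop_classes)
  buffer <- buffer_patches(labels, scene$patches,
                           radius_m = config$buffer_radius_m, types = "I")
  pinch <- extract_pinch_points(acc$current, buffer, labels,
                                k = config$pinch_k,
                                landuse = scene$landuse)
  points <- generate_warning_points(acc$current, config$n_warning_points,
                                    seed = config$seed + 1L)
  validation <- if (sum(as.matrix(pinch$mask)) > 0) {
    validate_points(pinch, points, tolerance_cells = config$tolerance_cells,
                    n_null = config$n_null, seed = config$seed + 2L)
  } else NULL
  report <- structure(list(
    config = config,
    package_version = as.character(utils::packageVersion("ecocircuit")),
    patch_table = patch_areas(labels, scene$patches),
    reff = acc$reff,
    n_pairs = acc$n_pairs,
    unreachable = acc$unreachable,
    kcl_max = acc$kcl_max,
    corridor = list(threshold = corridor$threshold_used,
                    n_groups = corridor$n_groups,
                    cells = sum(as.matrix(corridor$mask)),
                    composition = zonal_composition(corridor, scene$landuse)),
    pinch = list(area_km2 = pinch$total_area_km2,
                 cells = sum(as.matrix(pinch$mask)),
                 composition = pinch$composition),
    validation = validation,
    layers = list(scene = scene, labels = labels, resistance = rs$resistance,
                  current = acc$current, corridor = corridor,
                  buffer = buffer, pinch = pinch, points = points)),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_outputs(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  patches: %d (%.4g km2)\n", nrow(x$patch_table),
              sum(x$patch_table$area_km2)))
  finite <- x$reff[upper.tri(x$reff)]
  cat(sprintf("  R_eff over %d pair(s): %s\n", x$n_pairs,
              paste(signif(finite, 5), collapse = ", ")))
  cat(sprintf("  corridor: %d cells in %d group(s), threshold %.4g\n",
              x$corridor$cells, x$corridor$n_groups, x$corridor$threshold))
  cat(sprintf("  pinch points: %d cells, %.4g km2\n", x$pinch$cells,
              x$pinch$area_km2))
  if (!is.null(x$validation))
    cat(sprintf("  validation: fraction %.3f vs null q95 %.3f (p = %.4g)\n",
                x$validation$fraction, x$validation$null_q95,
                x$validation$p_value))
  invisible(x)
}

# Write every pipeline product under `dir` in plain-text formats.
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ly <- report$layers
  write_asc(ly$scene$dem, file.path(dir, "dem.asc"))
  write_asc(ly$scene$landuse, file.path(dir, "landuse.asc"))
  write_asc(ly$labels, file.path(dir, "patches.asc"))
  write_asc(ly$resistance, file.path(dir, "resistance.asc"))
  write_asc(ly$current, file.path(dir, "current.asc"))
  g <- ly$scene$spec
  write_asc(eco_raster(as.matrix(ly$corridor$mask) * 1, g),
            file.path(dir, "corridors.asc"))
  write_asc(eco_raster(as.matrix(ly$pinch$mask) * 1, g),
            file.path(dir, "pinch.asc"))
  write_patches_geojson(ly$scene$patches, g, file.path(dir, "patches.geojson"))
  write_points_geojson(ly$points, file.path(dir, "warning_points.geojson"))
  utils::write.csv(report$patch_table, file.path(dir, "patch_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$reff), file.path(dir, "reff.csv"))
  utils::write.csv(report$corridor$composition,
                   file.path(dir, "corridor_composition.csv"),
                   row.names = FALSE)
  if (!is.null(report$pinch$composition))
    utils::write.csv(report$pinch$composition,
                     file.path(dir, "pinch_composition.csv"),
                     row.names = FALSE)
  summary <- report[c("package_version", "n_pairs", "kcl_max", "corridor",
                      "pinch", "validation")]
  summary$config <- unclass(report$config)
  summary$reff <- as.data.frame(report$reff)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
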