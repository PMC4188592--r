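#' Run configuration for the command-line workflow
#'
#' A plain named list validated on construction; normally loaded from a
#' JSON config file by the `vmekde` command-line script.  All randomness in
#' a run flows from the single `seed`.
#'
#' @param input CSV path of survey records (not needed for `simulate`).
#' @param taxon taxon label to analyse (optional).
#' @param column_map named list/vector mapping package field names to CSV
#'   columns (optional).
#' @param crs_note declared planar CRS of the coordinates.
#' @param ladder ascending harmonization thresholds (kg).
#' @param alpha KS significance level.
#' @param search_radius,cell_size KDE overrides (m); defaults from the data
#'   extent when `NULL`.
#' @param scaling `"peak"` or `"density"`.
#' @param level_ratio geometric ratio of the threshold grid.
#' @param levels explicit decreasing threshold grid (overrides
#'   `level_ratio`).
#' @param criteria named list of [selection_criteria()] overrides.
#' @param scene named list of [scene_spec()] overrides (for `simulate`).
#' @param seed integer root seed.
#' @return Object of class `vme_config`.
#' @export
run_config <- function(input = NULL, taxon = NULL, column_map = NULL,
                       crs_note = "unspecified planar CRS",
                       ladder = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 10),
                       alpha = 0.05, search_radius = NULL, cell_size = NULL,
                       scaling = "peak", level_ratio = 2, levels = NULL,
                       criteria = list(), scene = list(), seed = 1L) {
  structure(list(input = input, taxon = taxon, column_map = column_map,
                 crs_note = crs_note, ladder = ladder, alpha = alpha,
                 search_radius = search_radius, cell_size = cell_size,
                 scaling = scaling, level_ratio = level_ratio,
                 levels = levels, criteria = criteria, scene = scene,
                 seed = as.integer(seed)),
            class = "vme_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with any subset of [run_config()]'s fields.
#' @return A `vme_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

.provenance <- function(config, out_dir) {
  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed,
         package = as.character(packageVersion("vmekde")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

.load_records <- function(config) {
  if (is.null(config$input)) stop("config error: no input path given")
  cm <- config$column_map
  if (!is.null(cm)) cm <- unlist(cm)
  read_survey_records(config$input, column_map = cm, crs_note = config$crs_note)
}

#' Simulate a synthetic scene to disk
#'
#' Writes `records.csv`, `truth.geojson` and `provenance.json` to
#' `out_dir`.
#'
#' @param config a [run_config()]; `config$scene` entries override
#'   [scene_spec()] defaults, `config$seed` seeds the scene.
#' @param out_dir output directory (created if needed).
#' @return The `vme_scene`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc_args <- config$scene
  sc_args$seed <- config$seed
  if (!is.null(sc_args$window)) sc_args$window <- do.call(extent, as.list(sc_args$window))
  spec <- do.call(scene_spec, sc_args)
  scene <- generate_scene(spec)
  write_scene(scene, file.path(out_dir, "records.csv"),
              file.path(out_dir, "truth.geojson"))
  .provenance(config, out_dir)
  invisible(scene)
}

#' Harmonize surveys and write the KS ladder
#'
#' Writes `harmonization.csv` (ladder rows) and `harmonization.json`
#' (thresholds + decision note) to `out_dir`.
#'
#' @inheritParams cmd_simulate
#' @return The `vme_harmonization`, invisibly.
#' @export
cmd_harmonize <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- .load_records(config)
  h <- harmonize_surveys(rec, taxon = config$taxon, thresholds = config$ladder,
                         alpha = config$alpha)
  write_harmonization_csv(h, file.path(out_dir, "harmonization.csv"))
  jsonlite::write_json(h[c("taxon", "duration_threshold", "gear_threshold",
                           "combinable_threshold", "decision_note")],
                       file.path(out_dir, "harmonization.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .provenance(config, out_dir)
  invisible(h)
}

.surface_from_config <- function(config, rec) {
  ext <- data_extent(rec[rec$biomass > 0, ])
  cfg <- default_config(ext, scaling = config$scaling)
  if (!is.null(config$search_radius) || !is.null(config$cell_size))
    cfg <- kde_config(ext,
                      search_radius = config$search_radius %||% cfg$search_radius,
                      cell_size = config$cell_size %||% cfg$cell_size,
                      scaling = config$scaling)
  kde(rec, cfg)
}

#' Compute and export the kernel density surface
#'
#' Writes `surface.asc` (ESRI ASCII grid) and `provenance.json`.
#'
#' @inheritParams cmd_simulate
#' @return The `vme_surface`, invisibly.
#' @export
cmd_kde <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  surf <- .surface_from_config(config, .load_records(config))
  write_surface_asc(surf, file.path(out_dir, "surface.asc"))
  .provenance(config, out_dir)
  invisible(surf)
}

#' Build and export the threshold-area curve
#'
#' Writes `curve.csv` and `provenance.json`.
#'
#' @inheritParams cmd_simulate
#' @return The `vme_curve`, invisibly.
#' @export
cmd_curve <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- .load_records(config)
  surf <- .surface_from_config(config, rec)
  levels <- config$levels %||% threshold_levels(surf, ratio = config$level_ratio)
  curve <- build_curve(surf, levels = levels)
  write_curve_csv(curve, file.path(out_dir, "curve.csv"))
  .provenance(config, out_dir)
  invisible(curve)
}

#' Full workflow: harmonize, KDE, curve, select, export
#'
#' Runs the complete analysis on a record file and writes every artifact:
#' `harmonization.csv`/`.json` (when several gears/durations are present),
#' `surface.asc`, `curve.csv`, `polygons.geojson` (at the selected
#' threshold), `selection.json`, `narrative.log` and `provenance.json`.
#'
#' @inheritParams cmd_simulate
#' @return List with the intermediate objects, invisibly.
#' @export
cmd_select <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- .load_records(config)

  h <- NULL
  cut <- 0
  multi <- ("gear" %in% names(rec) && length(unique(rec$gear)) > 1) ||
           ("duration" %in% names(rec) && length(unique(rec$duration)) > 1)
  if (multi) {
    h <- harmonize_surveys(rec, taxon = config$taxon,
                           thresholds = config$ladder, alpha = config$alpha)
    write_harmonization_csv(h, file.path(out_dir, "harmonization.csv"))
    if (is.na(h$combinable_threshold))
      stop("surveys not combinable: ", h$decision_note)
    cut <- h$combinable_threshold
  }
  used <- rec[rec$biomass > 0 & (cut == 0 | rec$biomass >= cut), ]

  surf <- .surface_from_config(config, used)
  write_surface_asc(surf, file.path(out_dir, "surface.asc"))
  levels <- config$levels %||% threshold_levels(surf, ratio = config$level_ratio)
  curve <- build_curve(surf, levels = levels)
  write_curve_csv(curve, file.path(out_dir, "curve.csv"))
  crit <- do.call(selection_criteria, config$criteria)
  sel <- select_threshold(curve, crit)

  enc <- NULL
  if (!is.na(sel$selected_threshold)) {
    polys <- polygonize(surf, sel$selected_threshold)
    write_polygons_geojson(polys, file.path(out_dir, "polygons.geojson"),
                           crs_note = config$crs_note)
    enc <- summarize_enclosure(surf, polys, rec)
  }
  jsonlite::write_json(
    list(selected_threshold = sel$selected_threshold,
         curve_flags = sel$curve_flags, enclosure = enc),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  writeLines(sel$narrative, file.path(out_dir, "narrative.log"))
  .provenance(config, out_dir)
  invisible(list(harmonization = h, surface = surf, curve = curve,
                 selection = sel, enclosure = enc))
}

#' Simulate a scene and run the full workflow on it
#'
#' Convenience end-to-end driver (`run-all`): [cmd_simulate()] then
#' [cmd_select()] on the simulated records.
#'
#' @inheritParams cmd_simulate
#' @return List as from [cmd_select()], plus the `scene`, invisibly.
#' @export
cmd_run_all <- function(config, out_dir) {
  scene <- cmd_simulate(config, out_dir)
  config$input <- file.path(out_dir, "records.csv")
  out <- cmd_select(config, out_dir)
  out$scene <- scene
  invisible(out)
}
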