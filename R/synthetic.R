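#' Specification of a synthetic trawl-survey scene
#'
#' Describes a landscape of dense biomass aggregations over a diffuse
#' low-biomass background, sampled by point trawl sets.  Aggregations
#' follow a Thomas cluster process -- Poisson parents, each with a
#' Poisson number of offspring displaced by an isotropic Gaussian -- the
#' simplest stationary cluster process with a tunable aggregation scale.
#' Catch weights are lognormal, reproducing the strong right skew of real
#' trawl catch-weight distributions (many small catches, few very large
#' ones), with separate parameters for cluster and background records.  A
#' zero-inflation probability turns records into null (zero-catch) sets.
#'
#' Defaults emulate a sponge-ground-like landscape at the scale of a
#' continental-margin survey footprint: a 300 x 360 km window (so the
#' default kernel search radius is 10 km), ~8 aggregations of ~40 sets
#' with catches around 50 kg, ~250 diffuse background sets with catches
#' around 0.5 kg, and 30% null sets.
#'
#' @param window a [extent()] (planar meters).
#' @param parent_intensity expected aggregation parents per m^2.
#' @param offspring_mean expected trawl sets per aggregation.
#' @param cluster_sd Gaussian displacement scale of offspring around the
#'   parent (m).
#' @param background_intensity expected background sets per m^2.
#' @param biomass_cluster `c(meanlog, sdlog)` of cluster catch weights (kg).
#' @param biomass_background `c(meanlog, sdlog)` of background catch
#'   weights (kg).
#' @param zero_inflation probability any set catches nothing.
#' @param seed integer seed; the scene is fully reproducible from it.
#' @return Object of class `vme_scene_spec`.
#' @export
scene_spec <- function(window = extent(0, 0, 300e3, 360e3),
                       parent_intensity = 8 / (300e3 * 360e3),
                       offspring_mean = 40,
                       cluster_sd = 8e3,
                       background_intensity = 250 / (300e3 * 360e3),
                       biomass_cluster = c(meanlog = log(50), sdlog = 1),
                       biomass_background = c(meanlog = log(0.5), sdlog = 0.6),
                       zero_inflation = 0.3,
                       seed = 1L) {
  stopifnot(inherits(window, "vme_extent"),
            parent_intensity >= 0, background_intensity >= 0,
            offspring_mean >= 0, cluster_sd > 0,
            zero_inflation >= 0, zero_inflation <= 1)
  structure(list(window = window, parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean, cluster_sd = cluster_sd,
                 background_intensity = background_intensity,
                 biomass_cluster = biomass_cluster,
                 biomass_background = biomass_background,
                 zero_inflation = zero_inflation, seed = as.integer(seed)),
            class = "vme_scene_spec")
}

#' Generate a synthetic trawl-survey scene
#'
#' Draws the Thomas-process point pattern and lognormal catch weights
#' described by a [scene_spec()].  Parents are simulated on the window
#' extended by `4 * cluster_sd` so cluster edges are unbiased at the window
#' boundary; offspring falling outside the window are discarded.  Ground
#' truth is retained: each record is labelled cluster or background, and
#' the truth regions are disks of radius `2 * cluster_sd` (about 86% of
#' offspring mass) around each parent.
#'
#' @param spec a [scene_spec()].
#' @param n_parents optionally force the number of parents (e.g. exactly 1
#'   cluster) instead of drawing it Poisson.
#' @return Object of class `vme_scene`: list with `records` (a
#'   `vme_records` data frame with `truth` labels as an extra column),
#'   `parents` (data frame of parent centers), `truth_radius`, and `spec`.
#' @export
generate_scene <- function(spec, n_parents = NULL) {
  w <- spec$window
  area <- w$width * w$height
  expected <- area * (spec$parent_intensity * spec$offspring_mean +
                      spec$background_intensity)
  if (expected < 3) stop("expected total points below 3; enlarge the scene")
  set.seed(spec$seed)

  pad <- 4 * spec$cluster_sd
  area_pad <- (w$width + 2 * pad) * (w$height + 2 * pad)
  n_par <- if (is.null(n_parents)) rpois(1, spec$parent_intensity * area_pad)
           else as.integer(n_parents)
  px <- runif(n_par, w$xmin - pad, w$xmax + pad)
  py <- runif(n_par, w$ymin - pad, w$ymax + pad)

  cx <- cy <- numeric(0)
  if (n_par > 0) {
    n_off <- rpois(n_par, spec$offspring_mean)
    cx <- rep(px, n_off) + rnorm(sum(n_off), 0, spec$cluster_sd)
    cy <- rep(py, n_off) + rnorm(sum(n_off), 0, spec$cluster_sd)
    keep <- cx >= w$xmin & cx <= w$xmax & cy >= w$ymin & cy <= w$ymax
    cx <- cx[keep]; cy <- cy[keep]
  }
  n_bg <- rpois(1, spec$background_intensity * area)
  bx <- runif(n_bg, w$xmin, w$xmax)
  by <- runif(n_bg, w$ymin, w$ymax)

  x <- c(cx, bx); y <- c(cy, by)
  truth <- c(rep("cluster", length(cx)), rep("background", length(bx)))
  n <- length(x)
  biomass <- numeric(n)
  is_cl <- truth == "cluster"
  biomass[is_cl] <- rlnorm(sum(is_cl), spec$biomass_cluster[["meanlog"]],
                           spec$biomass_cluster[["sdlog"]])
  biomass[!is_cl] <- rlnorm(sum(!is_cl), spec$biomass_background[["meanlog"]],
                            spec$biomass_background[["sdlog"]])
  biomass[runif(n) < spec$zero_inflation] <- 0

  rec <- data.frame(x = x, y = y, biomass = biomass,
                    survey_id = "synthetic", gear = "synthetic",
                    duration = 30, speed = 3, taxon = "synthetic",
                    truth = truth, stringsAsFactors = FALSE)
  records <- as_survey_records(rec[, setdiff(names(rec), "truth")],
                               crs_note = "synthetic planar meters")
  records$truth <- truth
  structure(list(records = records,
                 parents = data.frame(x = px, y = py),
                 truth_radius = 2 * spec$cluster_sd,
                 spec = spec),
            class = "vme_scene")
}

#' @export
print.vme_scene <- function(x, ...) {
  cat(sprintf("<vme_scene> %d records (%d cluster, %d background, %d null sets), %d parents\n",
              nrow(x$records), sum(x$records$truth == "cluster"),
              sum(x$records$truth == "background"),
              sum(x$records$biomass == 0), nrow(x$parents)))
  invisible(x)
}

#' Ground-truth cluster/background boundary level of a scene spec
#'
#' The surface level that separates the aggregation biomass regime from the
#' diffuse background regime.  Under peak kernel scaling an isolated set's
#' surface peak equals its catch weight, so the typical background record
#' enters the mapped superlevel sets at the background catch-weight scale:
#' the boundary is the background lognormal median, `exp(meanlog)`.
#'
#' @param spec a [scene_spec()].
#' @return The boundary level (kg-equivalent surface units, peak scaling).
#' @export
truth_boundary_level <- function(spec) {
  exp(spec$biomass_background[["meanlog"]])
}

#' Split a scene into synthetic surveys with a gear catch effect
#'
#' Partitions the scene spatially into two survey strata (west/east of the
#' window midline, emulating surveys with largely non-overlapping
#' coverage), assigns one gear label per stratum, and multiplies catches
#' *below* `cutoff_kg` for the affected gears, inducing a
#' KS-detectable distributional difference confined to small catches --
#' the situation the harmonization ladder is designed to detect: above the
#' cutoff the surveys remain combinable.
#'
#' @param scene a `vme_scene`.
#' @param gear_effects named numeric vector: catch multiplier per gear
#'   (applied below the cutoff).  Names become the gear labels; the first
#'   gear takes the western stratum.  Multiplier 1 means no effect.
#' @param cutoff_kg catch weight below which the multipliers act.
#' @return A `vme_records` data frame with reassigned `survey_id`/`gear`.
#' @export
make_multisurvey <- function(scene, gear_effects = c(A = 1, B = 0.5),
                             cutoff_kg = 0.2) {
  if (length(gear_effects) < 2) stop("need at least 2 gear labels")
  rec <- scene$records
  w <- scene$spec$window
  gears <- names(gear_effects)
  strata <- cut(rec$x, breaks = seq(w$xmin, w$xmax, length.out = length(gears) + 1),
                labels = gears, include.lowest = TRUE)
  rec$gear <- as.character(strata)
  rec$survey_id <- paste0("survey_", rec$gear)
  eff <- gear_effects[rec$gear]
  low <- rec$biomass > 0 & rec$biomass < cutoff_kg
  rec$biomass[low] <- rec$biomass[low] * eff[low]
  rec
}

#' Export a scene as CSV records plus ground-truth GeoJSON
#'
#' @param scene a `vme_scene`.
#' @param records_path CSV path for the records (survey_io dialect).
#' @param truth_path optional GeoJSON path for the truth-region disks
#'   (approximated as 64-gon polygons).
#' @return `records_path`, invisibly.
#' @export
write_scene <- function(scene, records_path, truth_path = NULL) {
  write_survey_records(scene$records[, setdiff(names(scene$records), "truth")],
                       records_path)
  if (!is.null(truth_path)) {
    th <- seq(0, 2 * pi, length.out = 65)
    feats <- lapply(seq_len(nrow(scene$parents)), function(i) {
      ring <- lapply(th, function(a)
        c(scene$parents$x[i] + scene$truth_radius * cos(a),
          scene$parents$y[i] + scene$truth_radius * sin(a)))
      list(type = "Feature",
           properties = list(parent = i, radius_m = scene$truth_radius),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(records_path)
}
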