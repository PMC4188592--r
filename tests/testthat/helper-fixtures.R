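# Shared fixtures: small record collections, surfaces and hand-built curves.

records_df <- function(x, y, biomass, ...) {
  as_survey_records(data.frame(x = x, y = y, biomass = biomass, ...))
}

# single-kernel surface on a unit-km window; fine grid for contour accuracy
point_surface <- function(w = 1, h = 200, cell = h / 50, scaling = "peak",
                          x = 505, y = 505) {
  e <- extent(0, 0, 1000, 1000)
  kde(records_df(x, y, w), kde_config(e, h, cell, scaling))
}

# random multi-point scene on a small grid (for oracle cross-checks)
random_surface <- function(seed, n = 10, side = 1000, h = 180, cell = 25,
                           scaling = "peak") {
  set.seed(seed)
  rec <- records_df(runif(n, 200, side - 200), runif(n, 200, side - 200),
                    rlnorm(n, 0, 1))
  kde(rec, kde_config(extent(0, 0, side, side), h, cell, scaling))
}

# hand-built threshold-area curve (areas in km^2); merges is a list indexed
# by step, each a list of merge events as produced by build_curve
fake_curve <- function(levels, areas, n_new = rep(10L, length(levels)),
                       merges = vector("list", length(levels)),
                       mean_new = NULL) {
  k <- length(levels)
  stopifnot(length(areas) == k)
  if (is.null(mean_new))
    mean_new <- c(levels[1], (levels[-k] + levels[-1]) / 2)
  steps <- lapply(seq_len(k), function(i) list(
    threshold = levels[i], total_area_km2 = areas[i], cell_area_km2 = areas[i],
    n_polygons = 1L, n_points_enclosed = sum(n_new[seq_len(i)]),
    n_new_points = n_new[i], n_new_points_in_new_areas = n_new[i],
    merges = merges[[i]] %||% list(), new_polygon_count = 0L,
    mean_new_area_value = mean_new[i]))
  summary <- data.frame(
    threshold = levels, n_polygons = 1L, total_area_km2 = areas,
    cell_area_km2 = areas, n_points_enclosed = cumsum(n_new),
    n_new_points = n_new, n_new_points_in_new_areas = n_new,
    n_merges = vapply(steps, function(s) length(s$merges), integer(1)),
    new_polygon_count = 0L, mean_new_area_value = mean_new)
  summary$area_ratio <- c(NA, ifelse(areas[-k] > 0, areas[-1] / areas[-k], NA))
  structure(list(steps = steps, summary = summary,
                 area_ratios = summary$area_ratio, levels = levels),
            class = "vme_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sample KS statistic: sup of |ECDF_a - ECDF_b| over all
# observed values (the ECDFs only change there)
ks_D_brute <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(vapply(g, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# moment skewness
skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# grid-index distance between a selected level and the truth level on a
# geometric grid
grid_step_distance <- function(levels, selected, truth) {
  if (is.na(selected)) return(Inf)
  abs(which.min(abs(log(levels) - log(selected))) -
      which.min(abs(log(levels) - log(truth))))
}
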