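#' Polygonize a density surface at one threshold level
#'
#' Traces the closed contours of the superlevel set `{value >= level}` by
#' marching squares with linear interpolation on the cell-center grid
#' (`grDevices::contourLines`), classifies rings as outer boundaries or
#' holes by even-odd nesting, and reports the enclosed area in km^2 (holes
#' subtracted).  A level above the surface maximum yields an empty polygon
#' set with zero area -- not an error.
#'
#' Surfaces produced by [kde()] are identically zero on the outermost grid
#' ring (the extent is grown by the search radius), so every contour at a
#' positive level closes inside the raster.  Rings passing through the
#' outermost data cells are flagged `edge_contact`.
#'
#' @param surface a `vme_surface`.
#' @param level contour level, > 0, in surface-value units.
#' @return Object of class `vme_polygons`: list with `level`, `rings` (each
#'   a list `x`, `y`, `hole`, `area_m2`, `edge_contact`), `n_polygons`
#'   (outer rings), `total_area_km2` (vector contour area) and
#'   `cell_area_km2` (cell-count area: cells >= level times cell area).
#' @export
polygonize <- function(surface, level) {
  if (!is.finite(level) || level <= 0) stop("contour level must be positive")
  v <- surface$values
  nr <- nrow(v)
  cl <- contourLines(x = surface$xc, y = rev(surface$yc),
                     z = t(v[nr:1, , drop = FALSE]), levels = level)
  rings <- lapply(cl, function(r) {
    x <- r$x; y <- r$y
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) { # defensive closure
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    list(x = x, y = y)
  })
  depth <- ring_depths(rings)
  xr <- range(surface$xc); yr <- range(surface$yc)
  area <- 0
  for (i in seq_along(rings)) {
    a <- ring_area(rings[[i]]$x, rings[[i]]$y)
    rings[[i]]$hole <- depth[i] %% 2L == 1L
    rings[[i]]$area_m2 <- a
    rings[[i]]$edge_contact <-
      any(rings[[i]]$x <= xr[1] | rings[[i]]$x >= xr[2] |
          rings[[i]]$y <= yr[1] | rings[[i]]$y >= yr[2])
    area <- area + if (rings[[i]]$hole) -a else a
  }
  structure(list(level = level, rings = rings,
                 n_polygons = sum(depth %% 2L == 0L),
                 total_area_km2 = area / 1e6,
                 cell_area_km2 = sum(v >= level) * surface$cell^2 / 1e6),
            class = "vme_polygons")
}

#' @export
print.vme_polygons <- function(x, ...) {
  cat(sprintf("<vme_polygons> level %.4g: %d polygon(s), %d hole(s), %.4g km^2\n",
              x$level, x$n_polygons, sum(vapply(x$rings, `[[`, TRUE, "hole")),
              x$total_area_km2))
  invisible(x)
}

#' Build the threshold-area curve of a density surface
#'
#' Polygonizes the surface at each of a strictly decreasing sequence of
#' biomass thresholds and tracks, per step: total enclosed area, the number
#' of records enclosed, the new point observations supporting the step
#' (records whose catch weight falls between this threshold and the previous
#' higher one -- the counts annotated on threshold-area histograms), how
#' many of those fall in areas outside the previous step's polygons, polygon
#' merge events (a region whose interior joins two or more previous
#' polygons) and newly created polygons with no predecessor.
#'
#' Merge topology is computed on the raster superlevel sets (4-connected
#' components), which the vector contours trace; enclosure of individual
#' records is read from the bilinear interpolant that defines those
#' contours, so point accounting and polygon geometry are mutually
#' consistent.
#'
#' @param surface a `vme_surface`.
#' @param records records to account against the polygons; defaults to the
#'   positive-biomass points the surface was built from.
#' @param levels strictly decreasing vector of positive thresholds.
#' @return Object of class `vme_curve`: list with `steps` (list of
#'   per-threshold accounting, see Details), `summary` (one data-frame row
#'   per step), `area_ratios` (area of each step divided by the previous
#'   step's), `levels`, and the `surface`.
#' @export
build_curve <- function(surface, records = NULL, levels) {
  if (length(levels) < 1) stop("need at least one level")
  if (is.unsorted(rev(levels), strictly = TRUE))
    stop("levels must be strictly decreasing")
  if (any(levels <= 0)) stop("levels must be positive")
  pts <- if (is.null(records)) surface$points else {
    df <- as.data.frame(records)
    df[is.finite(df$biomass) & df$biomass > 0, c("x", "y", "biomass")]
  }
  pt_val <- surface_value_at(surface, pts$x, pts$y)
  pt_cell <- cell_of_point(surface, pts$x, pts$y)

  steps <- vector("list", length(levels))
  lab_prev <- NULL
  n_prev_comp <- 0L
  prev_counts <- integer(0)
  prev_level <- Inf
  cell_km2 <- surface$cell^2 / 1e6

  for (k in seq_along(levels)) {
    lev <- levels[k]
    poly <- polygonize(surface, lev)
    mask <- surface$values >= lev
    lab <- label_components(mask)
    counts <- tabulate(lab, nbins = max(lab))

    # predecessor bookkeeping: which previous components feed each current one
    if (!is.null(lab_prev) && n_prev_comp > 0L && max(lab) > 0L) {
      sel <- lab_prev > 0L
      prs <- unique(cbind(cur = lab[sel], prev = lab_prev[sel]))
      npred <- tabulate(prs[, "cur"], nbins = max(lab))
    } else {
      prs <- cbind(cur = integer(0), prev = integer(0))
      npred <- rep(0L, max(lab, 0L))
    }

    comp_of_pt <- lab[pt_cell]
    new_band <- pt_val >= lev & pt_val < prev_level        # spatially newly mapped
    wt_band <- pts$biomass >= lev & pts$biomass < prev_level
    n_new <- sum(wt_band)
    in_prev <- if (is.finite(prev_level)) pt_val >= prev_level else rep(FALSE, nrow(pts))
    n_new_in_new <- sum(wt_band & !in_prev)

    merge_comps <- which(npred >= 2L)
    merges <- lapply(merge_comps, function(m) {
      preds <- prs[prs[, "cur"] == m, "prev"]
      growth <- (counts[m] - sum(prev_counts[preds])) * cell_km2
      support <- sum(comp_of_pt == m & !in_prev & pt_val >= lev)
      list(component = m, predecessors = preds,
           growth_km2 = growth, support_points = support)
    })

    steps[[k]] <- list(
      threshold = lev,
      polygons = poly,
      total_area_km2 = poly$total_area_km2,
      cell_area_km2 = poly$cell_area_km2,
      n_polygons = poly$n_polygons,
      n_components = max(lab, 0L),
      n_points_enclosed = sum(pt_val >= lev),
      n_new_points = n_new,
      n_new_points_in_new_areas = n_new_in_new,
      merges = merges,
      new_polygon_count = if (is.null(lab_prev)) max(lab, 0L) else sum(npred == 0L),
      mean_new_area_value =
        if (is.null(lab_prev)) mean(surface$values[mask])
        else if (any(mask & lab_prev == 0L)) mean(surface$values[mask & lab_prev == 0L])
        else NA_real_
    )
    lab_prev <- lab
    n_prev_comp <- max(lab, 0L)
    prev_counts <- counts
    prev_level <- lev
  }

  summary <- do.call(rbind, lapply(steps, function(s) data.frame(
    threshold = s$threshold, n_polygons = s$n_polygons,
    total_area_km2 = s$total_area_km2, cell_area_km2 = s$cell_area_km2,
    n_points_enclosed = s$n_points_enclosed, n_new_points = s$n_new_points,
    n_new_points_in_new_areas = s$n_new_points_in_new_areas,
    n_merges = length(s$merges), new_polygon_count = s$new_polygon_count,
    mean_new_area_value = s$mean_new_area_value)))
  a <- summary$total_area_km2
  ratios <- c(NA_real_, ifelse(a[-length(a)] > 0, a[-1] / a[-length(a)], NA_real_))
  summary$area_ratio <- ratios
  structure(list(steps = steps, summary = summary, area_ratios = ratios,
                 levels = levels, surface = surface, records = pts),
            class = "vme_curve")
}

#' @export
print.vme_curve <- function(x, ...) {
  cat(sprintf("<vme_curve> %d thresholds from %.4g down to %.4g\n",
              length(x$levels), max(x$levels), min(x$levels)))
  print(x$summary[, c("threshold", "n_polygons", "total_area_km2",
                      "n_new_points", "n_new_points_in_new_areas",
                      "n_merges", "area_ratio")], row.names = FALSE)
  invisible(x)
}

#' Geometric threshold grid over a surface's positive range
#'
#' Descending levels `max(surface) / ratio^k`, stopping above `floor`.  A
#' coarse geometric grid (default halving) spans the orders of magnitude
#' between dense aggregation cores and diffuse background catches.
#'
#' @param surface a `vme_surface`.
#' @param ratio successive-level ratio (> 1, default 2).
#' @param floor lowest level retained; defaults to the smallest positive
#'   catch weight among the surface's input points, capped below by 1e-6 of
#'   the maximum.
#' @return Decreasing numeric vector of levels.
#' @export
threshold_levels <- function(surface, ratio = 2, floor = NULL) {
  stopifnot(ratio > 1)
  top <- max(surface$values)
  if (top <= 0) stop("surface has no positive values")
  if (is.null(floor))
    floor <- max(min(surface$points$biomass) / 2, top * 1e-6)
  n <- max(1L, ceiling(log(top / floor) / log(ratio)))
  # start one step below the bare maximum (a level at the single highest
  # cell encloses a degenerate sliver)
  top * ratio^-seq_len(n)
}

#' Export a threshold-area curve summary as CSV
#'
#' @param curve a `vme_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve$summary, path, row.names = FALSE)
  invisible(path)
}

#' Export threshold polygons as GeoJSON
#'
#' Writes one `Polygon` feature per outer ring (holes attached to their
#' containing outer ring) with attributes: threshold level, area in km^2,
#' and -- when the polygons come from a [build_curve()] step -- merge/new
#' flags and enclosed point counts.  Coordinates are planar meters in the
#' declared survey CRS (recorded in the `crs_note` member), not WGS84;
#' consumers must reproject for web mapping.
#'
#' @param polys a `vme_polygons` object.
#' @param path output path.
#' @param crs_note free-text CRS declaration stored in the file.
#' @param properties optional named list of extra feature properties
#'   (recycled across features).
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path, crs_note = "unspecified planar CRS",
                                   properties = NULL) {
  outer_idx <- which(!vapply(polys$rings, `[[`, TRUE, "hole"))
  hole_idx <- setdiff(seq_along(polys$rings), outer_idx)
  # attach each hole to the smallest enclosing outer ring
  assign_to <- function(h) {
    hx <- polys$rings[[h]]$x[1]; hy <- polys$rings[[h]]$y[1]
    cands <- outer_idx[vapply(outer_idx, function(o)
      points_in_ring(hx, hy, polys$rings[[o]]$x, polys$rings[[o]]$y), logical(1))]
    if (!length(cands)) return(NA_integer_)
    cands[which.min(vapply(cands, function(o) polys$rings[[o]]$area_m2, numeric(1)))]
  }
  owner <- vapply(hole_idx, assign_to, integer(1))
  features <- lapply(seq_along(outer_idx), function(i) {
    o <- outer_idx[i]
    ringset <- c(list(cbind(polys$rings[[o]]$x, polys$rings[[o]]$y)),
                 lapply(hole_idx[which(owner == o)], function(h)
                   cbind(polys$rings[[h]]$x, polys$rings[[h]]$y)))
    props <- c(list(threshold = polys$level,
                    area_km2 = (polys$rings[[o]]$area_m2 -
                      sum(vapply(hole_idx[which(owner == o)], function(h)
                        polys$rings[[h]]$area_m2, numeric(1)))) / 1e6,
                    edge_contact = polys$rings[[o]]$edge_contact),
               properties)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = lapply(ringset, function(m)
                           lapply(seq_len(nrow(m)), function(r) c(m[r, 1], m[r, 2])))))
  })
  obj <- list(type = "FeatureCollection", crs_note = crs_note, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
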