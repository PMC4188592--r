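#' Kernel density configuration
#'
#' Bundles the bandwidth (search radius), cell size, analysis extent and
#' scaling mode of a density surface.  Defaults follow the conventional GIS
#' kernel-density tool: search radius = shortest extent dimension / 30, cell
#' size = shortest extent dimension / 250 (see [default_config()]).
#'
#' Two scalings of the same quadratic kernel are supported:
#' \describe{
#'   \item{`"peak"`}{each kernel is scaled so its maximum equals the catch
#'     weight: an isolated 7.3 kg catch produces a surface peaking at 7.3.
#'     Surface values then carry kg-per-tow-equivalent units, directly
#'     comparable to catch-weight thresholds such as "75 kg".  Default.}
#'   \item{`"density"`}{each kernel integrates to the catch weight
#'     (kg m^-2); the surface integral recovers total biomass.  Used for
#'     mass-conservation checks.}
#' }
#' The two modes differ cell-wise by the exact scalar `pi * h^2 / 3`, so
#' polygon geometry at a given *curve level* is mode-invariant.
#'
#' @param extent a [extent()] object.
#' @param search_radius bandwidth h (m): kernels reach exactly zero at this
#'   distance.
#' @param cell_size raster resolution (m); must be smaller than the search
#'   radius.
#' @param scaling `"peak"` or `"density"`.
#' @return Object of class `vme_kde_config`.
#' @export
kde_config <- function(extent, search_radius, cell_size, scaling = c("peak", "density")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(extent, "vme_extent"),
            is.finite(search_radius), search_radius > 0,
            is.finite(cell_size), cell_size > 0)
  if (cell_size >= search_radius)
    stop("cell_size must be smaller than search_radius")
  structure(list(extent = extent, search_radius = search_radius,
                 cell_size = cell_size, scaling = scaling),
            class = "vme_kde_config")
}

#' Default kernel configuration for an extent
#'
#' Search radius = `min(width, height) / 30`; cell size =
#' `min(width, height) / 250`.  For the 678 km wide survey footprint of the
#' original sponge/sea-pen analysis these defaults give h = 22.6 km and a
#' ~2.7 km cell; for the 498 km large-gorgonian extent, h = 16.6 km and a
#' ~2.0 km cell.
#'
#' @param extent a [extent()] object.
#' @param scaling `"peak"` (default) or `"density"`; see [kde_config()].
#' @return A [kde_config()] object.
#' @export
default_config <- function(extent, scaling = c("peak", "density")) {
  s <- min(extent$width, extent$height)
  kde_config(extent, search_radius = s / 30, cell_size = s / 250,
             scaling = match.arg(scaling))
}

# raster geometry: grow the extent by h so kernels are never clipped, snap
# outward to whole cells anchored at (xmin, ymax)
.grid_geometry <- function(config) {
  h <- config$search_radius; cs <- config$cell_size; e <- config$extent
  xmin <- e$xmin - h; xmax <- e$xmax + h
  ymin <- e$ymin - h; ymax <- e$ymax + h
  nc <- ceiling((xmax - xmin) / cs)
  nr <- ceiling((ymax - ymin) / cs)
  list(xll = xmin, yll = ymax - nr * cs, nrow = nr, ncol = nc, cell = cs,
       xc = xmin + (seq_len(nc) - 0.5) * cs,
       yc = ymax - (seq_len(nr) - 0.5) * cs)  # row 1 = north
}

#' Biomass-weighted quadratic (Epanechnikov) kernel density surface
#'
#' Places one radially symmetric quadratic kernel over each positive-biomass
#' trawl-set position and sums them on a raster evaluated at cell centers.
#' The kernel profile is `(1 - (d/h)^2)^2` for `d < h` and exactly zero
#' beyond the search radius, so each observation influences a circular
#' neighbourhood of radius h.  In `"density"` mode the kernel is normalised
#' by `3 / (pi h^2)` so it integrates to the catch weight; in `"peak"` mode
#' it is left with unit maximum so an isolated catch's peak equals its
#' weight (see [kde_config()]).
#'
#' The raster covers the analysis extent grown by h on every side so no
#' kernel is clipped; rows run north to south (top-left origin).
#'
#' @param records a `vme_records` data frame; zero-biomass rows are dropped
#'   (they are absences, carrying no kernel weight).
#' @param config a [kde_config()] object.
#' @return Object of class `vme_surface`: list with `values` (nrow x ncol
#'   matrix, row 1 = northernmost), `xc`/`yc` cell-center coordinates,
#'   `cell` size, `config`, and `points` (the weighted input locations).
#' @export
kde <- function(records, config) {
  df <- as.data.frame(records)
  df <- df[is.finite(df$biomass) & df$biomass > 0, ]
  if (!nrow(df)) stop("no positive-biomass records for KDE")
  g <- .grid_geometry(config)
  h <- config$search_radius
  vals <- matrix(0, g$nrow, g$ncol)
  hc <- h / g$cell
  for (i in seq_len(nrow(df))) {
    px <- df$x[i]; py <- df$y[i]; w <- df$biomass[i]
    ci <- (px - g$xll) / g$cell + 0.5  # fractional col of point
    ri <- (g$yc[1] + g$cell / 2 - py) / g$cell + 0.5
    cols <- max(1, floor(ci - hc)):min(g$ncol, ceiling(ci + hc))
    rows <- max(1, floor(ri - hc)):min(g$nrow, ceiling(ri + hc))
    if (!length(cols) || !length(rows)) next
    dx2 <- (g$xc[cols] - px)^2
    dy2 <- (g$yc[rows] - py)^2
    u2 <- outer(dy2, dx2, "+") / h^2
    k <- (1 - u2)^2
    k[u2 >= 1] <- 0
    vals[rows, cols] <- vals[rows, cols] + w * k
  }
  if (config$scaling == "density") vals <- vals * (3 / (pi * h^2))
  structure(list(values = vals, xc = g$xc, yc = g$yc, cell = g$cell,
                 xll = g$xll, yll = g$yll, config = config,
                 points = df[, c("x", "y", "biomass")]),
            class = "vme_surface")
}

#' @export
print.vme_surface <- function(x, ...) {
  cat(sprintf("<vme_surface> %d x %d cells of %g m, %s scaling, h = %g m\n",
              nrow(x$values), ncol(x$values), x$cell, x$config$scaling,
              x$config$search_radius))
  cat(sprintf("  values in [%.4g, %.4g], %d input points\n",
              min(x$values), max(x$values), nrow(x$points)))
  invisible(x)
}

#' Export a density surface as an ESRI ASCII grid
#'
#' Plain-text single-band raster (`.asc`) readable by standard GIS software;
#' the declared CRS is written alongside as a `.prj.txt` note when the
#' records carried one.
#'
#' @param surface a `vme_surface`.
#' @param path output file path.
#' @param nodata value written for no-data cells (none are produced here,
#'   but the header requires a declaration).
#' @return `path`, invisibly.
#' @export
write_surface_asc <- function(surface, path, nodata = -1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", ncol(surface$values)),
               sprintf("NROWS %d", nrow(surface$values)),
               sprintf("XLLCORNER %.10g", surface$xll),
               sprintf("YLLCORNER %.10g", surface$yll),
               sprintf("CELLSIZE %.10g", surface$cell),
               sprintf("NODATA_VALUE %g", nodata)), con)
  write.table(format(surface$values, digits = 10, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
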