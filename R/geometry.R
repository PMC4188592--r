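# Planar geometry utilities.  Rings are closed polylines (first vertex
# repeated last) in projected meters, as produced by contour tracing.  All
# polygon area and membership logic in the package goes through these.

# shoelace area, unsigned (m^2); accepts an open or closed ring
ring_area <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# even-odd (ray casting) membership of points in a single ring, vectorized
# over points.  With eps > 0 points within eps of a ring edge count as
# inside (thresholds are "at or above", so points on the contour are in).
points_in_ring <- function(px, py, rx, ry, eps = 0) {
  n <- length(rx)
  x1 <- rx[-n]; y1 <- ry[-n]; x2 <- rx[-1]; y2 <- ry[-1]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (k in seq_along(x1)) {
    crosses <- (y1[k] > py) != (y2[k] > py)
    if (any(crosses)) {
      xin <- x1[k] + (py[crosses] - y1[k]) / (y2[k] - y1[k]) * (x2[k] - x1[k])
      idx <- which(crosses)[xin > px[crosses]]
      inside[idx] <- !inside[idx]
    }
    if (eps > 0) {
      dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1[k]) * dx + (py - y1[k]) * dy) / L2)) else 0
      d2 <- (px - (x1[k] + t * dx))^2 + (py - (y1[k] + t * dy))^2
      onedge <- onedge | d2 <= eps^2
    }
  }
  inside | onedge
}

# membership of points in the even-odd union of a list of rings
points_in_rings <- function(px, py, rings, eps = 0) {
  if (!length(rings)) return(logical(length(px)))
  crossings <- integer(length(px))
  onedge <- logical(length(px))
  for (r in rings) {
    ins <- points_in_ring(px, py, r$x, r$y, eps = 0)
    crossings <- crossings + ins
    if (eps > 0) onedge <- onedge | points_in_ring(px, py, r$x, r$y, eps = eps)
  }
  (crossings %% 2L == 1L) | onedge
}

# nesting depth of each ring among the others (0 = outermost, odd = hole).
# Contour rings of one level set never cross, so the first vertex is a valid
# representative.
ring_depths <- function(rings) {
  n <- length(rings)
  depth <- integer(n)
  if (n < 2) return(depth)
  px <- vapply(rings, function(r) r$x[1], numeric(1))
  py <- vapply(rings, function(r) r$y[1], numeric(1))
  for (j in seq_len(n)) {
    ins <- points_in_ring(px, py, rings[[j]]$x, rings[[j]]$y)
    ins[j] <- FALSE
    depth <- depth + ins
  }
  depth
}

# area of the convex hull of a point set (m^2)
convex_hull_area <- function(x, y) {
  i <- chull(x, y)
  ring_area(x[i], y[i])
}

#' Surface value at point locations
#'
#' Bilinear interpolation of the density surface.  The threshold polygons
#' are contours of this same interpolant, so `surface_value_at(s, x, y) >=
#' level` is the authoritative test of whether a point lies inside the
#' level's polygons.
#'
#' @param surface a `vme_surface`.
#' @param px,py planar point coordinates (m).
#' @return Numeric vector of interpolated surface values.
#' @export
surface_value_at <- function(surface, px, py) {
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v); cs <- surface$cell
  fx <- (px - surface$xc[1]) / cs + 1   # fractional column (center coords)
  fy <- (surface$yc[1] - py) / cs + 1   # fractional row, row 1 = north
  c0 <- pmin(pmax(floor(fx), 1), nc - 1)
  r0 <- pmin(pmax(floor(fy), 1), nr - 1)
  tx <- pmin(pmax(fx - c0, 0), 1)
  ty <- pmin(pmax(fy - r0, 0), 1)
  (1 - ty) * ((1 - tx) * v[cbind(r0, c0)]     + tx * v[cbind(r0, c0 + 1)]) +
       ty  * ((1 - tx) * v[cbind(r0 + 1, c0)] + tx * v[cbind(r0 + 1, c0 + 1)])
}

# nearest-cell (row, col) of point locations on a surface grid
cell_of_point <- function(surface, px, py) {
  nr <- nrow(surface$values); nc <- ncol(surface$values); cs <- surface$cell
  col <- pmin(pmax(round((px - surface$xc[1]) / cs + 1), 1), nc)
  row <- pmin(pmax(round((surface$yc[1] - py) / cs + 1), 1), nr)
  cbind(row, col)
}

# 4-connected component labelling of a logical matrix by row-run merging
# with union-find; returns an integer matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  runs <- vector("list", nr)
  nid <- 0L
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    c1 <- starts[rl$values]; c2 <- ends[rl$values]
    ids <- nid + seq_along(c1)
    nid <- nid + length(c1)
    parent <- c(parent, ids)
    runs[[r]] <- list(c1 = c1, c2 = c2, id = ids)
    if (r > 1L && !is.null(runs[[r - 1L]])) {
      p <- runs[[r - 1L]]
      for (k in seq_along(c1)) {
        for (m in which(p$c1 <= c2[k] & p$c2 >= c1[k])) {
          ra <- find(ids[k]); rb <- find(p$id[m])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  lab <- matrix(0L, nr, nc)
  if (nid > 0L) {
    roots <- vapply(seq_len(nid), find, integer(1))
    comp <- match(roots, sort(unique(roots)))
    for (r in seq_len(nr)) {
      rr <- runs[[r]]
      if (is.null(rr)) next
      for (k in seq_along(rr$c1)) lab[r, rr$c1[k]:rr$c2[k]] <- comp[rr$id[k]]
    }
  }
  lab
}
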