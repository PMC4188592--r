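test_that("an isolated kernel's half-weight contour is the analytic disk", {
  h <- 200
  s <- point_surface(w = 1, h = h, cell = h / 50, scaling = "peak")
  p <- polygonize(s, 0.5)
  r <- h * sqrt(1 - sqrt(0.5))  # invert (1 - (r/h)^2)^2 = 1/2
  expect_equal(p$n_polygons, 1)
  expect_equal(p$total_area_km2, pi * r^2 / 1e6, tolerance = 0.02)
})

test_that("a level above the surface maximum yields an empty polygon set", {
  s <- point_surface(w = 1)
  p <- polygonize(s, 2)
  expect_equal(length(p$rings), 0)
  expect_equal(p$total_area_km2, 0)
  expect_equal(p$cell_area_km2, 0)
  expect_error(polygonize(s, -1), "positive")
})

test_that("contour areas agree with the cell-count oracle on random scenes", {
  for (seed in 1:20) {
    s <- random_surface(seed, n = sample(3:12, 1))
    lev <- quantile(s$values[s$values > 0], runif(1, 0.3, 0.9))
    p <- polygonize(s, lev)
    # boundary cells: >= level with a 4-neighbour below, or vice versa
    m <- s$values >= lev
    nb <- function(a, b) sum(a & !b)
    bcells <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
    tol <- bcells * s$cell^2 / 1e6
    expect_lte(abs(p$total_area_km2 - p$cell_area_km2), tol + 1e-12)
  }
})

test_that("point-in-ring agrees with the mgcv::in.out oracle", {
  skip_if_not_installed("mgcv")
  set.seed(3)
  s <- random_surface(3, n = 8)
  p <- polygonize(s, quantile(s$values[s$values > 0], 0.6))
  px <- runif(300, 0, 1000); py <- runif(300, 0, 1000)
  mine <- vmekde:::points_in_rings(px, py, p$rings)
  bnd <- do.call(rbind, lapply(p$rings, function(r)
    rbind(cbind(r$x, r$y), c(NA, NA))))
  oracle <- mgcv::in.out(bnd[-nrow(bnd), ], cbind(px, py))
  expect_equal(mine, as.vector(oracle))
})

test_that("two well-separated equal kernels never merge", {
  h <- 150
  e <- extent(0, 0, 1200, 600)
  s <- kde(records_df(c(300, 300 + 3 * h), c(300, 300), c(1, 1)),
           kde_config(e, h, 10))
  cv <- build_curve(s, levels = c(0.8, 0.5, 0.2))
  expect_equal(cv$summary$n_polygons, c(2, 2, 2))
  expect_equal(cv$summary$n_merges, c(0, 0, 0))
  # both points enter the weight-band accounting at the first level below 1
  expect_equal(cv$summary$n_new_points, c(2, 0, 0))
  expect_equal(cv$summary$n_points_enclosed, c(2, 2, 2))
})

test_that("two kernels 1.2 h apart merge below the saddle value", {
  h <- 150
  e <- extent(0, 0, 1200, 600)
  s <- kde(records_df(c(450, 450 + 1.2 * h), c(300, 300), c(1, 1)),
           kde_config(e, h, 5))
  saddle <- 2 * (1 - 0.6^2)^2   # both kernels at 0.6 h from the midpoint
  cv <- build_curve(s, levels = c(saddle * 1.1, saddle * 0.9))
  expect_equal(cv$summary$n_polygons, c(2, 1))
  expect_equal(cv$summary$n_merges, c(0, 1))
  m <- cv$steps[[2]]$merges[[1]]
  expect_equal(sort(m$predecessors), c(1, 2))
})

test_that("area and enclosure grow monotonically and polygons nest", {
  s <- random_surface(17, n = 15, h = 220, cell = 20)
  lv <- threshold_levels(s, ratio = 1.6)
  cv <- build_curve(s, levels = lv)
  expect_true(all(diff(cv$summary$total_area_km2) >= 0))
  expect_true(all(diff(cv$summary$cell_area_km2) >= 0))
  expect_true(all(diff(cv$summary$n_points_enclosed) >= 0))
  expect_true(all(cv$area_ratios[-1] >= 1 - 1e-9))
  # nesting: any random point inside the polygons at a level is inside the
  # polygons at every lower level
  set.seed(1)
  px <- runif(500, 0, 1000); py <- runif(500, 0, 1000)
  member <- sapply(seq_along(lv), function(k)
    vmekde:::points_in_rings(px, py, cv$steps[[k]]$polygons$rings))
  for (k in seq_len(ncol(member) - 1))
    expect_true(all(member[, k + 1] | !member[, k]))
})

test_that("weight-band point accounting is conservative and consistent", {
  s <- random_surface(23, n = 20, h = 220, cell = 25)
  lv <- threshold_levels(s, ratio = 2)
  cv <- build_curve(s, levels = lv)
  w <- s$points$biomass
  for (k in seq_along(lv)) {
    expect_equal(sum(cv$summary$n_new_points[seq_len(k)]), sum(w >= lv[k]))
    expect_lte(cv$summary$n_new_points_in_new_areas[k],
               cv$summary$n_new_points[k])
    # peak scaling: every record at or above the level is enclosed
    expect_gte(cv$summary$n_points_enclosed[k], sum(w >= lv[k]))
  }
  expect_error(build_curve(s, levels = c(1, 2)), "strictly decreasing")
})

test_that("polygon GeoJSON export preserves areas and attributes", {
  s <- random_surface(9, n = 6)
  p <- polygonize(s, quantile(s$values[s$values > 0], 0.5))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(p, f, crs_note = "EPSG:32623")
  gj <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), p$n_polygons)
  areas <- vapply(gj$features, function(ft) ft$properties$area_km2, numeric(1))
  expect_equal(sum(areas), p$total_area_km2, tolerance = 1e-9)
  expect_equal(gj$crs_note, "EPSG:32623")
})
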