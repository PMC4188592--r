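test_that("default config follows the /30 and /250 extent rules", {
  e <- extent(0, 0, 678e3, 900e3)  # width shortest, as in the survey footprint
  cfg <- default_config(e)
  expect_equal(cfg$search_radius, 22.6e3)
  expect_equal(cfg$cell_size, 2712)
  cfg2 <- default_config(extent(0, 0, 498e3, 700e3))
  expect_equal(cfg2$search_radius, 16.6e3)
  expect_equal(cfg2$cell_size, 1992)
  cfg3 <- default_config(extent(0, 0, 1, 1))
  expect_equal(cfg3$search_radius, 1 / 30)
  expect_equal(cfg3$cell_size, 1 / 250)
  expect_error(kde_config(e, search_radius = 100, cell_size = 100),
               "smaller than")
})

test_that("a single kernel has the closed-form center value and h support", {
  h <- 200
  s <- point_surface(w = 1, h = h, cell = 10, scaling = "density")
  expect_equal(surface_value_at(s, 505, 505), 3 / (pi * h^2), tolerance = 1e-12)
  sp <- point_surface(w = 7.3, h = h, cell = 10, scaling = "peak")
  expect_equal(surface_value_at(sp, 505, 505), 7.3, tolerance = 1e-12)

  # support: exactly the cells with center within h of a point
  d <- sqrt(outer((s$yc - 505)^2, (s$xc - 505)^2, "+"))
  expect_identical(s$values > 0, d < h)
})

test_that("density mode conserves total biomass within 1%", {
  for (seed in 1:3) {
    s <- random_surface(seed, n = 12, h = 250, cell = 25, scaling = "density")
    mass <- sum(s$values) * s$cell^2
    expect_equal(mass, sum(s$points$biomass), tolerance = 0.01)
  }
})

test_that("peak mode is density mode times pi h^2 / 3, cell for cell", {
  h <- 180
  e <- extent(0, 0, 1000, 1000)
  rec <- records_df(c(400, 600, 500), c(400, 450, 700), c(2, 5, 0.3))
  sd_ <- kde(rec, kde_config(e, h, 25, "density"))
  sp <- kde(rec, kde_config(e, h, 25, "peak"))
  expect_equal(sp$values, sd_$values * pi * h^2 / 3, tolerance = 1e-12)
})

test_that("the surface is translation-equivariant and superposable", {
  h <- 180
  rec_a <- records_df(c(400, 650), c(420, 520), c(2, 3))
  rec_b <- records_df(c(300, 500), c(700, 350), c(1, 4))
  cfg <- function(e) kde_config(e, h, 25, "peak")
  e0 <- extent(0, 0, 1000, 1000)

  s_ab <- kde(rbind(rec_a, rec_b), cfg(e0))
  s_a <- kde(rec_a, cfg(e0))
  s_b <- kde(rec_b, cfg(e0))
  expect_equal(s_ab$values, s_a$values + s_b$values, tolerance = 1e-12)

  shift <- c(12345, -6789)
  rec_s <- rec_a
  rec_s$x <- rec_s$x + shift[1]; rec_s$y <- rec_s$y + shift[2]
  s_shift <- kde(rec_s, cfg(extent(shift[1], shift[2],
                                   1000 + shift[1], 1000 + shift[2])))
  expect_equal(s_shift$values, s_a$values, tolerance = 1e-12)
  expect_equal(s_shift$xc, s_a$xc + shift[1])
})

test_that("zero-biomass records carry no kernel weight", {
  e <- extent(0, 0, 1000, 1000)
  s1 <- kde(records_df(c(400, 700), c(400, 700), c(2, 0)),
            kde_config(e, 180, 25))
  s2 <- kde(records_df(400, 400, 2), kde_config(e, 180, 25))
  expect_equal(s1$values, s2$values)
  expect_error(kde(records_df(1, 1, 0), kde_config(e, 180, 25)),
               "no positive-biomass")
})

test_that("the ASCII grid export round-trips the raster", {
  s <- random_surface(5, n = 5, h = 200, cell = 50)
  f <- withr::local_tempfile(fileext = ".asc")
  write_surface_asc(s, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], sprintf("NCOLS %d", ncol(s$values)))
  vals <- as.matrix(read.table(f, skip = 6))
  dimnames(vals) <- NULL
  expect_equal(vals, s$values, tolerance = 1e-9)
})
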