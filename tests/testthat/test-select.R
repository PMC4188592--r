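test_that("a single clear jump after a plateau is the lone candidate", {
  # successive area ratios 1.02, 1.05, 1.58, 1.10
  areas <- 1000 * cumprod(c(1, 1.02, 1.05, 1.58, 1.10))
  cv <- fake_curve(levels = c(16, 8, 4, 2, 1), areas = areas)
  cand <- find_candidates(cv)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$area_ratio, 1.58)
  expect_equal(cand$upper_level, 4)
  expect_equal(cand$lower_level, 2)
  sel <- select_threshold(cv)
  expect_equal(sel$selected_threshold, 4)
})

test_that("a uniformly growing curve is rejected as gradual increase", {
  areas <- 1000 * cumprod(c(1, rep(1.15, 5)))
  cv <- fake_curve(levels = 2^(5:0), areas = areas)
  sel <- select_threshold(cv)
  expect_true(is.na(sel$selected_threshold))
  expect_equal(sel$curve_flags, "gradual-increase")
})

test_that("an established curve with no qualifying jump reports no-large-jump", {
  areas <- 1000 * cumprod(c(1, 1.05, 1.08, 1.1, 1.12))
  cv <- fake_curve(levels = 2^(4:0), areas = areas)
  sel <- select_threshold(cv)
  expect_true(is.na(sel$selected_threshold))
  expect_equal(sel$curve_flags, "no-large-jump")
})

test_that("a jump created by a single datum is vetoed", {
  areas <- 1000 * cumprod(c(1, 1.02, 1.03, 1.6))
  cv <- fake_curve(levels = c(8, 4, 2, 1), areas = areas,
                   n_new = c(10L, 5L, 4L, 1L))
  sel <- select_threshold(cv)
  expect_true(is.na(sel$selected_threshold))
  expect_true("single-point-jump" %in% sel$candidates$flags[[1]])
})

test_that("merges without bridging support are vetoed", {
  areas <- c(1000, 1020, 1050, 1700)
  merges <- list(NULL, NULL, NULL,
                 list(list(component = 1L, predecessors = c(1L, 2L),
                           growth_km2 = 600, support_points = 0L)))
  cv <- fake_curve(levels = c(8, 4, 2, 1), areas = areas, merges = merges)
  sel <- select_threshold(cv)
  expect_true(is.na(sel$selected_threshold))
  expect_true("merge-without-support" %in% sel$candidates$flags[[1]])
  # the same merge with enough interior points stands
  merges[[4]][[1]]$support_points <- 5L
  sel2 <- select_threshold(fake_curve(levels = c(8, 4, 2, 1), areas = areas,
                                      merges = merges))
  expect_equal(sel2$selected_threshold, 2)
})

test_that("new area of very low density is vetoed", {
  areas <- 1000 * cumprod(c(1, 1.02, 1.03, 1.6))
  cv <- fake_curve(levels = c(80, 70, 60, 2), areas = areas,
                   mean_new = c(80, 75, 65, 5))  # 5 < 0.5 * 60
  sel <- select_threshold(cv)
  expect_true(is.na(sel$selected_threshold))
  expect_true("low-density-new-area" %in% sel$candidates$flags[[1]])
})

test_that("selection behaves correctly in the jump_min limits", {
  areas <- 1000 * cumprod(c(1, 1.02, 1.3, 1.02, 1.5, 1.05))
  cv <- fake_curve(levels = 2^(5:0), areas = areas)
  expect_true(is.na(select_threshold(cv,
    selection_criteria(jump_min = 1e6))$selected_threshold))
  sel <- select_threshold(cv, selection_criteria(jump_min = 1.0001))
  expect_equal(sel$selected_threshold, 4)  # upper level of the 1.5 step
})

test_that("selection is invariant to levels above the surface maximum", {
  s <- random_surface(31, n = 15, h = 220, cell = 25)
  lv <- threshold_levels(s, ratio = 2)
  sel1 <- select_threshold(build_curve(s, levels = lv))
  lv2 <- c(max(s$values) * c(8, 4, 2), lv)
  sel2 <- select_threshold(build_curve(s, levels = lv2))
  expect_equal(sel2$selected_threshold, sel1$selected_threshold)
})

test_that("enclosure summary handles totality and emptiness", {
  s <- random_surface(4, n = 8)
  lo <- min(s$points$biomass)
  p <- polygonize(s, lo * 0.5)   # encloses every record (peak scaling)
  rec <- s$points
  enc <- summarize_enclosure(s, p, rec)
  expect_equal(enc$biomass_fraction, 1.0)
  expect_gt(enc$area_fraction, 0)
  empty <- polygonize(s, max(s$values) * 2)
  enc0 <- summarize_enclosure(s, empty, rec)
  expect_equal(enc0$biomass_fraction, 0)
  expect_equal(enc0$area_fraction, 0)
  expect_error(summarize_enclosure(s, p, records_df(1:2, 1:2, c(0, 0))),
               "zero total biomass")
})

test_that("enclosure fractions match ground truth on a concentrated scene", {
  spec <- scene_spec(seed = 5)
  scene <- generate_scene(spec)
  rec <- scene$records
  pos <- rec[rec$biomass > 0, ]
  surf <- kde(pos, default_config(data_extent(pos)))
  sel <- select_threshold(build_curve(surf, levels = threshold_levels(surf)))
  p <- polygonize(surf, sel$selected_threshold)
  enc <- summarize_enclosure(surf, p, rec)
  truth_cluster_share <- sum(pos$biomass[pos$truth == "cluster"]) / sum(pos$biomass)
  # the polygons capture at least the clusters' biomass share, in a minority
  # of the sampled area
  expect_gte(enc$biomass_fraction, truth_cluster_share * 0.95)
  expect_lt(enc$area_fraction, 0.5)
})

test_that("threshold recovery holds across cluster intensities and contrasts", {
  dist <- c()
  for (parents in c(4, 12)) for (mu in log(c(12.5, 50, 200))) {
    spec <- scene_spec(seed = round(parents * 100 + mu * 10),
                       parent_intensity = parents / (300e3 * 360e3),
                       biomass_cluster = c(meanlog = mu, sdlog = 1))
    scene <- generate_scene(spec)
    pos <- scene$records[scene$records$biomass > 0, ]
    surf <- kde(pos, default_config(data_extent(pos)))
    lv <- threshold_levels(surf)
    sel <- select_threshold(build_curve(surf, levels = lv))
    dist <- c(dist, grid_step_distance(lv, sel$selected_threshold,
                                       truth_boundary_level(spec)))
  }
  expect_lte(median(dist), 1)
})
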