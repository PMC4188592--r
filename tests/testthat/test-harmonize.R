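test_that("KS statistic matches hand checks and the brute-force ECDF oracle", {
  k <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k$ks_stat, 0)
  expect_equal(k$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$ks_stat, 1 / 3)

  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    a <- round(rlnorm(n1, 0, 1), sample(0:3, 1))  # rounding induces ties
    b <- round(rlnorm(n2, 0.3, 1.2), sample(0:3, 1))
    expect_equal(ks_two_sample(a, b)$ks_stat, ks_D_brute(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("D is invariant under common monotone transforms and low restrictions", {
  set.seed(1)
  a <- rlnorm(40); b <- rlnorm(35, 0.5)
  d0 <- ks_two_sample(a, b)$ks_stat
  expect_equal(ks_two_sample(log(a), log(b))$ks_stat, d0)
  expect_equal(ks_two_sample(a^3, b^3)$ks_stat, d0)
  # restricting both samples above a level below both minima changes nothing
  t0 <- min(a, b) / 2
  expect_equal(ks_two_sample(a[a >= t0], b[b >= t0])$ks_stat, d0)
})

test_that("null rejection rate at a ladder level is close to alpha", {
  set.seed(99)
  reps <- 400
  rej <- replicate(reps, {
    lad <- threshold_ladder(rlnorm(30), rlnorm(30), thresholds = c(0, 0.5))
    lad$significant
  })
  rate <- rowMeans(rej)  # per ladder level (0 kg and 1 kg)
  expect_true(all(rate > 0.01 & rate < 0.09))
})

test_that("ladder flags levels with insufficient restricted samples", {
  a <- c(0.1, 0.2, 0.3, 5, 6, 7, 8, 9)
  b <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)  # all below the top level
  lad <- threshold_ladder(a, b, thresholds = c(0, 1), min_n = 5)
  expect_false(lad$insufficient_n[1])
  expect_true(lad$insufficient_n[2])
  expect_true(is.na(lad$p_value[2]))
  expect_error(threshold_ladder(a, b, thresholds = c(1, 0.5)),
               "strictly increasing")
})

test_that("identically distributed surveys combine at the lowest ladder level", {
  set.seed(7)
  rec <- records_df(runif(800), runif(800), rlnorm(800, 0, 1),
                    gear = rep(c("Campelen", "Lofoten"), each = 400),
                    duration = 30)
  h <- harmonize_surveys(rec, thresholds = c(0, 0.1, 0.5, 1))
  expect_equal(h$combinable_threshold, 0)
})

test_that("contamination confined below 1 kg is harmonized exactly at 1 kg", {
  set.seed(11)
  a <- rlnorm(400, 0, 1)
  b <- rlnorm(400, 0, 1)
  b[b < 1] <- b[b < 1] * 0.5   # gear effect acting only on sub-kg catches
  rec <- records_df(runif(800), runif(800), c(a, b),
                    gear = rep(c("A", "B"), each = 400), duration = 30)
  h <- harmonize_surveys(rec, thresholds = c(0, 0.1, 0.5, 1))
  expect_equal(h$gear_threshold, 1)
  expect_equal(h$combinable_threshold, 1)
})

test_that("a pooling cut that strands <10% of records recommends split models", {
  set.seed(13)
  a <- rlnorm(400, log(0.1), 1)
  b <- rlnorm(400, log(0.1), 1)
  b[b < 0.5] <- b[b < 0.5] * 0.5
  rec <- records_df(runif(800), runif(800), c(a, b),
                    gear = rep(c("A", "B"), each = 400), duration = 30)
  h <- harmonize_surveys(rec, thresholds = c(0, 0.05, 0.1, 0.2, 0.5, 1))
  expect_equal(h$combinable_threshold, 0.5)
  expect_match(h$decision_note, "per-region")
})

test_that("a single survey group needs no harmonization", {
  rec <- records_df(1:5, 1:5, rlnorm(5), gear = "A", duration = 30)
  h <- harmonize_surveys(rec)
  expect_equal(h$combinable_threshold, 0)
  expect_match(h$decision_note, "no harmonization needed")
})
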