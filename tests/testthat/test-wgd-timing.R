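test_that("multiplicity inference matches expected-VAF arithmetic", {
  expect_equal(infer_multiplicity(0.5, 1, 2, 1), 1L)
  expect_equal(infer_multiplicity(1.0, 1, 2, 2), 2L)
  # purity 0.5, diploid: expected VAF for one copy is 0.25
  expect_equal(infer_multiplicity(0.25, 0.5, 2, 1), 1L)
  expect_equal(infer_multiplicity(0, 1, 2, 2), 0L)
  # bounded by the major allele
  expect_equal(infer_multiplicity(1, 1, 4, 2), 2L)
  # midpoint ties round down (VAF space)
  expect_equal(infer_multiplicity(0.375, 1, 4, 4), 1L)  # c0 = 1.5
  expect_error(infer_multiplicity(0.5, 0, 2, 1), "purity")
  expect_error(infer_multiplicity(0.5, 1, 2, 0), "n_major")
  # the ratio-space criterion has its boundary at 4/3
  expect_equal(infer_multiplicity(1.4 / 4, 1, 4, 4, method = "ratio"), 2L)
  expect_equal(infer_multiplicity(1.4 / 4, 1, 4, 4, method = "vaf"), 1L)
})

test_that("multiplicity recovery at purity 1 exceeds 99% at depth 70", {
  cfg <- sim_config(n_samples = 20, purity = 1, wgd_t = 0.5, lambda = 500)
  w <- simulate_wgd_snvs(cfg, seed = 13)
  mult <- infer_multiplicity(w$snvs$vaf, 1, w$snvs$n_tot, w$snvs$n_major)
  expect_gte(mean(mult == w$snvs$true_multiplicity), 0.99)
})

test_that("WGD counting follows the length-weighted major-allele mode", {
  expect_equal(count_wgd(segment_catalog("a", "1", 1, 1e8, 1, 1)), 0L)
  expect_equal(count_wgd(segment_catalog("a", "1", 1, 1e8, 2, 2)), 1L)
  expect_equal(count_wgd(segment_catalog("a", "1", 1, 1e8, 4, 0)), 2L)
  mixed <- segment_catalog("a", "1", c(1, 6e7 + 1), c(6e7, 9e7),
                           c(2, 1), c(1, 1))
  expect_equal(count_wgd(mixed), 1L)       # 60 Mb at major 2 vs 30 Mb at 1
  tie <- segment_catalog("a", "1", c(1, 5e7 + 1), c(5e7, 1e8),
                         c(1, 2), c(1, 1))
  expect_warning(n <- count_wgd(tie), "tied")
  expect_equal(n, 1L)                      # larger mode wins
})

test_that("timing formulas reproduce their closed forms", {
  expect_equal(time_wgd1(100, 0), 0)
  expect_equal(time_wgd1(0, 50), 1)
  expect_equal(time_wgd1(100, 100), 2 / 3)
  expect_true(is.na(time_wgd1(0, 0)))
  expect_equal(time_wgd2(0, 0, 10), c(t1 = 1, t2 = 1))
  expect_equal(time_wgd2(10, 0, 0), c(t1 = 0, t2 = 0))
  expect_equal(time_wgd2(4, 4, 4), c(t1 = 4 / 7, t2 = 6 / 7))
  expect_true(all(is.na(time_wgd2(0, 0, 0))))
  # estimator identity: expected counts return exactly t; t1 <= t2 always
  for (t in seq(0, 1, by = 0.05)) {
    expect_equal(time_wgd1(2 * 1000 * (1 - t), 1000 * t), t)
  }
  set.seed(8)
  for (i in 1:25) {
    ts <- time_wgd2(stats::rpois(1, 50), stats::rpois(1, 50),
                    stats::rpois(1, 50))
    expect_lte(ts["t1"], ts["t2"])
  }
  # monotonicity in N2 at fixed N1
  t_grid <- time_wgd1(500, seq(0, 1000, by = 100))
  expect_true(all(diff(t_grid) > 0))
})

test_that("bootstrap intervals are seeded and degenerate when appropriate", {
  expect_equal(bootstrap_timing_ci(rep(2L, 50), seed = 4),
               c(lower = 1, upper = 1))
  m <- c(rep(1L, 60), rep(2L, 40))
  ci1 <- bootstrap_timing_ci(m, B = 500, seed = 9)
  expect_identical(ci1, bootstrap_timing_ci(m, B = 500, seed = 9))
  expect_lt(ci1["lower"], time_wgd1(60, 40))
  expect_gt(ci1["upper"], time_wgd1(60, 40))
  expect_error(bootstrap_timing_ci(integer(0)), "eligible")
})

test_that("chronological timing scales the clock by age", {
  rt <- real_time_timing(0.5, 70)
  expect_equal(rt$rt, 35)
  expect_equal(rt$tbd, 35)
  expect_equal(real_time_timing(1, 60)$tbd, 0)
  expect_equal(real_time_timing(0, 60)$tbd, 60)
  expect_error(real_time_timing(1.2, 60), "\\[0, 1\\]")
})

test_that("driver timing places multiplicities around the WGD(s)", {
  expect_equal(time_driver(2, 2, 2, n_wgd = 1), "pre-WGD")
  expect_equal(time_driver(1, 2, 0, n_wgd = 1), "post-WGD")
  expect_equal(time_driver(2, 4, 4, n_wgd = 2), "between-WGDs")
  expect_equal(time_driver(4, 4, 0, n_wgd = 2), "pre-WGD")
  expect_equal(time_driver(1, 3, 1, n_wgd = 1), "not-timeable")
})

test_that("the per-sample wrapper ties the pieces together", {
  w <- simulate_wgd_snvs(sim_config(n_samples = 1, wgd_t = 0.4,
                                    lambda = 800), seed = 19)
  r <- time_sample_wgd(w$snvs, purity = 0.7, age = 50, B = 300, seed = 2)
  expect_lt(abs(r$t["t1"] - 0.4), 0.05)
  expect_true(r$ci["lower"] <= r$t["t1"] && r$t["t1"] <= r$ci["upper"])
  expect_equal(r$rt + r$tbd, 50)
  # two-WGD cohort
  w2 <- simulate_wgd_snvs(sim_config(n_samples = 1, wgd_t = 0.3,
                                     wgd_t2 = 0.8, lambda = 800), seed = 20)
  r2 <- time_sample_wgd(w2$snvs, purity = 0.7, n_wgd = 2, B = 300, seed = 2)
  expect_lt(abs(r2$t["t1"] - 0.3), 0.07)
  expect_lt(abs(r2$t["t2"] - 0.8), 0.07)
  expect_lte(r2$t["t1"], r2$t["t2"])
})
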