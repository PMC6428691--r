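test_that("configuration invariants are enforced", {
  expect_error(sim_config(sv_shape = -1), "positive")
  expect_error(sim_config(wgd_t = 1.5), "wgd_t")
  expect_error(sim_config(purity = 0), "purity")
  W <- default_cn_signatures()
  W[, 2] <- 0
  expect_error(sim_config(signatures = W), "all-zero")
})

test_that("the same seed reproduces catalogs byte-identically", {
  cfg <- sim_config(n_samples = 3, segments_per_sample = 50, sv_scale = 10)
  expect_identical(simulate_cn_catalog(cfg, seed = 2),
                   simulate_cn_catalog(cfg, seed = 2))
  expect_identical(simulate_sv_catalog(cfg, seed = 2),
                   simulate_sv_catalog(cfg, seed = 2))
  expect_identical(simulate_wgd_snvs(cfg, seed = 2),
                   simulate_wgd_snvs(cfg, seed = 2))
})

test_that("classification inverts the copy-number generator exactly", {
  cfg <- sim_config(n_samples = 5, segments_per_sample = 200)
  sim <- simulate_cn_catalog(cfg, seed = 8)
  m <- build_cn_matrix(sim$segments, colnames(sim$counts))
  expect_identical(unname(m), unname(sim$counts))
  expect_equal(colSums(sim$exposures), rep(1, 5), ignore_attr = TRUE)
})

test_that("a pure single-signature sample stays inside its support", {
  W <- default_cn_signatures()[, 1, drop = FALSE]
  cfg <- sim_config(n_samples = 2, segments_per_sample = 150,
                    signatures = W, exposure_alpha = 1)
  sim <- simulate_cn_catalog(cfg, seed = 3)
  cat1 <- classify_segments(sim$segments)
  expect_true(all(W[levels(cat1)[as.integer(cat1)], 1] > 0))
})

test_that("category frequencies match the mixture at 10,000 segments", {
  W <- default_cn_signatures()
  cfg <- sim_config(n_samples = 20, segments_per_sample = 500,
                    exposure_alpha = c(5, 5, 5))
  sim <- simulate_cn_catalog(cfg, seed = 10)
  # pooled expected frequencies: per-sample mixtures weighted by totals
  n_s <- colSums(sim$counts)
  expect_gt(sum(n_s), 9000)
  q <- as.vector((W %*% sim$exposures) %*% n_s) / sum(n_s)
  keep <- q > 0
  gof <- stats::chisq.test(rowSums(sim$counts)[keep],
                           p = q[keep] / sum(q[keep]))
  expect_gt(gof$p.value, 0.01)
})

test_that("breakpoint-partner geometry follows its parameters", {
  cfg <- sim_config(n_samples = 1, p_same_chrom = 1, sv_shape = 50,
                    sv_scale = 1)
  sv <- simulate_sv_catalog(cfg, build = toy_build(), seed = 4)
  expect_true(all(sv$rearrangements$chrom1 == sv$rearrangements$chrom2))
  # empirical same-chromosome fraction ~ p at 10,000 events
  cfg2 <- sim_config(n_samples = 100, p_same_chrom = 0.65, sv_shape = 100,
                     sv_scale = 1)
  sv2 <- simulate_sv_catalog(cfg2, build = toy_build(), seed = 5)
  n <- nrow(sv2$rearrangements)
  expect_gt(n, 5000)
  frac <- mean(sv2$rearrangements$chrom1 == sv2$rearrangements$chrom2)
  se <- sqrt(0.65 * 0.35 / n)
  expect_lt(abs(frac - 0.65), 3 * se)
  expect_error(sim_config(mu_distance = -1), "positive")
})

test_that("configured chromothriptic windows carry their breakpoints", {
  ct <- data.frame(sample = "S001", chrom = "1", start = 5e7, end = 5.3e7,
                   n_breakpoints = 40)
  cfg <- sim_config(n_samples = 1, sv_shape = 10, sv_scale = 1,
                    chromothripsis = ct)
  sv <- simulate_sv_catalog(cfg, build = toy_build(), seed = 6)
  rr <- sv$rearrangements
  pos <- c(rr$pos1[rr$chrom1 == "1"], rr$pos2[rr$chrom2 == "1"])
  expect_gt(sum(pos >= 5e7 & pos <= 5.3e7), 30)
  expect_true(any(rr$chromothriptic))
})

test_that("WGD SNV multiplicities follow the timing extremes", {
  w0 <- simulate_wgd_snvs(sim_config(n_samples = 2, wgd_t = 0), seed = 1)
  expect_true(all(w0$snvs$true_multiplicity == 1))
  w1 <- simulate_wgd_snvs(sim_config(n_samples = 2, wgd_t = 1), seed = 1)
  expect_true(all(w1$snvs$true_multiplicity == 2))
})

test_that("the timing estimator is unbiased on generator output", {
  # single fixed-seed sample lands near truth ...
  w <- simulate_wgd_snvs(sim_config(n_samples = 1, wgd_t = 0.5,
                                    lambda = 1000), seed = 7)
  mult <- infer_multiplicity(w$snvs$vaf, 0.7, w$snvs$n_tot, w$snvs$n_major)
  t_hat <- time_wgd1(sum(mult == 1), sum(mult == 2))
  expect_lt(abs(t_hat - 0.5), 0.05)
  # ... and the mean over 100 replicates is within +/- 0.02
  t_all <- vapply(1:100, function(s) {
    w <- simulate_wgd_snvs(sim_config(n_samples = 1, wgd_t = 0.5,
                                      lambda = 1000), seed = s)
    m <- infer_multiplicity(w$snvs$vaf, 0.7, w$snvs$n_tot, w$snvs$n_major)
    time_wgd1(sum(m == 1), sum(m == 2))
  }, numeric(1))
  expect_lt(abs(mean(t_all) - 0.5), 0.02)
})
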