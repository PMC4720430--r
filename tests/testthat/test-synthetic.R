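test_that("design layout matches the four-group biopsy grid", {
  d16 <- build_design(simulation_config(n_individuals = 16L))
  expect_equal(nrow(d16), 8 * 6 + 8 * 5)   # 88 samples
  expect_equal(sum(d16$series == "early"), 48L)
  expect_equal(sum(!d16$treated), 44L)
  expect_equal(length(unique(d16$individual_id)), 16L)

  d4 <- build_design(simulation_config(n_individuals = 4L))
  expect_equal(nrow(d4), 6 + 6 + 5 + 5)
  expect_setequal(unique(d4$dose), c("high", "none", "low"))

  expect_error(simulation_config(n_individuals = 3L), "multiple of 4")
})

test_that("generator is deterministic and per-gene substreams are stable", {
  cfg <- simulation_config(n_genes = 120, n_composition = 20, n_circadian = 10,
                           n_handling = 10, n_individual_genes = 10,
                           n_treatment = 10, rng_seed = 3)
  d <- build_design(cfg)
  s1 <- simulate_experiment(cfg, d)
  s2 <- simulate_experiment(cfg, d)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth$classes, s2$truth$classes)

  cfg_other <- simulation_config(n_genes = 120, n_composition = 20, n_circadian = 10,
                                 n_handling = 10, n_individual_genes = 10,
                                 n_treatment = 10, rng_seed = 4)
  expect_false(identical(simulate_experiment(cfg_other, d)$matrix, s1$matrix))

  ## dropping the treatment class must not reshuffle other genes' noise
  cfg_no_trt <- simulation_config(n_genes = 120, n_composition = 20, n_circadian = 10,
                                  n_handling = 10, n_individual_genes = 10,
                                  n_treatment = 0, rng_seed = 3)
  s3 <- simulate_experiment(cfg_no_trt, d)
  shared <- names(s1$truth$classes)[s1$truth$classes %in%
                                      c("composition", "circadian", "handling", "individual")]
  expect_identical(s1$matrix[shared, ], s3$matrix[shared, ])
})

test_that("zero-noise generator degenerates to its deterministic skeleton", {
  cfg0 <- simulation_config(n_genes = 20, n_composition = 0, n_circadian = 0,
                            n_handling = 0, n_individual_genes = 0, n_treatment = 0,
                            sigma_e = 0, sigma_m_null = 0, rng_seed = 9)
  s <- simulate_experiment(cfg0)
  expect_true(all(apply(s$matrix, 1L, function(r) diff(range(r))) == 0))
  expect_equal(unname(s$matrix[, 1L]), s$truth$params$mu)
})

test_that("same-cell-type composition genes share centred profiles exactly at zero noise", {
  cfg <- simulation_config(n_genes = 30, n_composition = 10, n_circadian = 0,
                           n_handling = 0, n_individual_genes = 0, n_treatment = 0,
                           sigma_e = 0, sigma_m_null = 0, rng_seed = 11)
  d <- build_design(cfg)
  s <- simulate_experiment(cfg, d)
  p <- s$truth$params
  type1 <- p$gene_id[!is.na(p$cell_type) & p$cell_type == 1][1:2]
  for (iid in unique(d$individual_id)[1:4]) {
    sids <- d$sample_id[d$individual_id == iid]
    prof <- s$matrix[type1, sids]
    expect_equal(stats::cor(prof[1L, ], prof[2L, ]), 1, tolerance = 1e-12)
    centred <- prof - rowMeans(prof)
    expect_equal(centred[1L, ], centred[2L, ], tolerance = 1e-9)
  }
})

test_that("handling genes are linear in effective biopsy order, recovering the slope at zero noise", {
  cfg <- simulation_config(n_genes = 20, n_composition = 0, n_circadian = 0,
                           n_handling = 5, n_individual_genes = 0, n_treatment = 0,
                           sigma_e = 0, sigma_m_null = 0, rng_seed = 13)
  d <- build_design(cfg)
  s <- simulate_experiment(cfg, d)
  hs <- s$truth$params$gene_id[s$truth$params$class == "handling"]
  b <- condiag:::effective_biopsy_step(d)
  for (g in hs) {
    fit <- stats::lm(s$matrix[g, ] ~ b)
    expect_equal(unname(coef(fit)[2L]), cfg$handling_slope, tolerance = 1e-10)
    expect_true(all(diff(s$matrix[g, d$individual_id == "M01"]) >= 0))
  }
})

test_that("null-gene variance follows the law of total variance", {
  cfg <- simulation_config(n_genes = 600, n_composition = 0, n_circadian = 0,
                           n_handling = 0, n_individual_genes = 0, n_treatment = 0,
                           rng_seed = 21)
  d <- build_design(cfg)
  s <- simulate_experiment(cfg, d)
  v <- mean(apply(s$matrix, 1L, stats::var))
  n_i <- length(unique(d$individual_id))
  expected <- cfg$sigma_e^2 + cfg$sigma_m_null^2 * (1 - 1 / n_i)
  expect_equal(v, expected, tolerance = 0.1)
})

test_that("circadian genes correlate across equal-phase individuals and decorrelate when shifted", {
  cfg <- simulation_config(n_genes = 20, n_composition = 0, n_circadian = 10,
                           n_handling = 0, n_individual_genes = 0, n_treatment = 0,
                           sigma_e = 0, sigma_m_null = 0, phase_sd_h = 0, rng_seed = 31)
  d <- build_design(cfg)
  s <- simulate_experiment(cfg, d)
  g <- s$truth$params$gene_id[s$truth$params$class == "circadian"][1L]
  early_untr <- unique(d$individual_id[d$series == "early" & !d$treated])
  prof <- sapply(early_untr, function(i) s$matrix[g, d$sample_id[d$individual_id == i]])
  cc <- stats::cor(prof)
  expect_true(all(cc[upper.tri(cc)] > 0.999))  # same phase, same grid

  cfg_shift <- simulation_config(n_genes = 20, n_composition = 0, n_circadian = 10,
                                 n_handling = 0, n_individual_genes = 0, n_treatment = 0,
                                 sigma_e = 0, sigma_m_null = 0, phase_sd_h = 6, rng_seed = 31)
  s2 <- simulate_experiment(cfg_shift, d)
  ## the 12 h late window exposes the phase shifts clearly
  late_untr <- unique(d$individual_id[d$series == "late" & !d$treated])
  prof2 <- sapply(late_untr, function(i) s2$matrix[g, d$sample_id[d$individual_id == i]])
  cc2 <- stats::cor(prof2)
  expect_true(min(cc2[upper.tri(cc2)]) < 0.8)  # phase shifts break coherence
})
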