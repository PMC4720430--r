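test_that("profile REML matches the balanced one-way closed form and truncates at zero", {
  st <- oneway_table(a = 4, n = 5)
  set.seed(101)
  for (rep in 1:5) {
    y <- rnorm(20, 5, 0.2) + rep(rnorm(4, 0, 0.5), each = 5)
    oracle <- oneway_reml_oracle(y, a = 4, n = 5)
    fit <- fit_mixed_model(y, st, method = "profile")
    expect_equal(fit$sigma_u2, unname(oracle["sigma_u2"]), tolerance = 1e-8)
    expect_equal(fit$sigma_e2, unname(oracle["sigma_e2"]), tolerance = 1e-8)
    expect_equal(sum(fit$individual_coefs), 0, tolerance = 1e-10)
  }

  ## no individual signal in a large balanced fixture: truncated to zero
  st_big <- oneway_table(a = 8, n = 4)
  set.seed(7)
  ## remove all between-individual signal so MSB < MSW
  y0 <- as.vector(scale(matrix(rnorm(32), 4, 8), center = TRUE, scale = FALSE))
  fit0 <- fit_mixed_model(y0, st_big, method = "profile")
  expect_equal(fit0$sigma_u2, 0)
})

test_that("REML with a fixed factor agrees with the lme4 oracle on unbalanced data", {
  skip_if_not_installed("lme4")
  st <- oneway_table(a = 5, n = 4)
  st$condition <- rep(c("a", "a", "b", "b"), 5)
  st <- st[-c(3, 8, 17), ]                     # unbalance it
  set.seed(11)
  y <- 2 + 0.6 * (st$condition == "b") +
    rnorm(5, 0, 0.7)[as.integer(factor(st$individual_id))] + rnorm(nrow(st), 0, 0.3)
  fit <- fit_mixed_model(y, st, fixed = "condition", method = "profile")
  lf <- lme4::lmer(y ~ 0 + condition + (1 | individual_id),
                   data = cbind(st, y = y), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma_u2, vc$vcov[1L], tolerance = 1e-6)
  expect_equal(fit$sigma_e2, vc$vcov[2L], tolerance = 1e-6)
  expect_equal(unname(fit$fixed_coefs), unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$individual_coefs),
               lme4::ranef(lf)$individual_id[, 1L], tolerance = 1e-6)
})

test_that("random_individual = FALSE reduces to ordinary least squares", {
  st <- oneway_table(a = 3, n = 4)
  st$condition <- rep(c("a", "b"), 6)
  set.seed(13)
  y <- rnorm(12)
  fit <- fit_mixed_model(y, st, fixed = "condition", random_individual = FALSE)
  ref <- stats::lm(y ~ 0 + factor(st$condition))
  expect_equal(unname(fit$fixed_coefs), unname(coef(ref)), tolerance = 1e-12)
  expect_equal(fit$sigma_e2, summary(ref)$sigma^2, tolerance = 1e-12)
  expect_true(all(fit$individual_coefs == 0))
})

test_that("matrix-level mixed-model fits agree with the per-gene optimizer", {
  sim <- small_sim()
  du <- make_cells(sim$design[!sim$design$treated, ])
  genes <- rownames(sim$matrix)[c(1, 150, 200, 250, 399)]
  fits <- fit_mixed_models(sim$matrix[, du$sample_id], du, fixed = "cell")
  for (g in genes) {
    single <- fit_mixed_model(sim$matrix[g, du$sample_id], du, fixed = "cell",
                              method = "profile")
    expect_equal(unname(fits$individual_coefs[g, ]),
                 unname(single$individual_coefs), tolerance = 0.05)
  }
})

test_that("variance shrinkage vanishes for homogeneous variances and the Fs reduces to F", {
  expect_equal(condiag:::shrink_variances(rep(2, 6), df = 10), rep(2, 6))

  ## classical-F reduction, independently computed via lm() per gene
  st <- oneway_table(a = 4, n = 4)
  st$condition <- rep(c("c1", "c1", "c2", "c2"), 4)
  set.seed(17)
  m <- expr_fixture(matrix(rnorm(5 * 16), 5, 16), samples = st$sample_id)
  res <- fs_permutation_test(m, st, "condition", c("c1", "c2"), n_perm = 100,
                             seed = 1, random_individual = FALSE, shrink = FALSE)
  for (i in seq_len(5)) {
    ref <- stats::anova(stats::lm(m[i, ] ~ factor(st$condition)))
    expect_equal(res$table$Fs[i], ref$`F value`[1L], tolerance = 1e-10)
  }
})

test_that("Fs permutation test is deterministic and absorbs per-individual constants", {
  sim <- small_sim()
  d <- sim$design
  du <- relabel_biopsy_order(d[!d$treated, ])
  du$biopsy_order <- as.character(du$biopsy_order)
  r1 <- fs_permutation_test(sim$matrix, du, "biopsy_order", c("1", "4"),
                            n_perm = 100, seed = 5)
  r2 <- fs_permutation_test(sim$matrix, du, "biopsy_order", c("1", "4"),
                            n_perm = 100, seed = 5)
  expect_identical(r1$table, r2$table)

  shifted <- sim$matrix
  inds <- unique(du$individual_id)
  shift <- stats::setNames(seq_along(inds) * 0.7, inds)
  for (s in du$sample_id) {
    shifted[, s] <- shifted[, s] + shift[du$individual_id[du$sample_id == s]]
  }
  r3 <- fs_permutation_test(shifted, du, "biopsy_order", c("1", "4"),
                            n_perm = 100, seed = 5)
  expect_equal(r1$table$Fs, r3$table$Fs, tolerance = 1e-9)
  expect_equal(r1$table$p, r3$table$p, tolerance = 1e-12)
})

test_that("between-individual contrasts demand the fixed model and permute arms", {
  sim <- small_sim()
  dx <- make_cells(sim$design[sim$design$series == "early", ])
  expect_error(fs_permutation_test(sim$matrix, dx, "cell",
                                   c("high_t3", "none_early_t3"),
                                   n_perm = 100, seed = 2),
               "between-individual")
  res <- fs_permutation_test(sim$matrix, dx, "cell", c("high_t3", "none_early_t3"),
                             n_perm = 100, seed = 2, random_individual = FALSE)
  expect_identical(res$permutation_scheme, "between_individual")
  trt <- names(sim$truth$classes)[sim$truth$classes == "treatment"]
  nulls <- names(sim$truth$classes)[sim$truth$classes == "null"]
  expect_gt(mean(res$table$p[res$table$gene_id %in% trt] <= 0.05),
            mean(res$table$p[res$table$gene_id %in% nulls] <= 0.05))
})

test_that("q-value estimation reproduces Benjamini-Hochberg at pi0 = 1 and stays monotone", {
  q <- estimate_qvalues(c(0.01, 0.02, 0.03, 0.5), pi0 = 1)
  expect_equal(q$qvalues, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)

  ## BH equivalence on arbitrary input
  set.seed(23)
  p <- c(runif(200)^2, runif(100))
  expect_equal(estimate_qvalues(p, pi0 = 1)$qvalues, stats::p.adjust(p, "BH"),
               tolerance = 1e-12)

  q1 <- estimate_qvalues(rep(1, 10))
  expect_equal(q1$pi0, 1)
  expect_true(all(q1$qvalues == 1))

  set.seed(29)
  pr <- runif(500)
  qr <- estimate_qvalues(pr)
  ord <- order(pr)
  expect_true(all(diff(qr$qvalues[ord]) >= -1e-12))
  expect_true(all(qr$qvalues >= pr * qr$pi0 - 1e-12))

  expect_error(estimate_qvalues(numeric(0)), "empty")
  expect_error(estimate_qvalues(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(estimate_qvalues(runif(10), lambda = c(0.9, 0.5)), "increasing")
})

test_that("contrast scans validate contrasts upfront and respect the q threshold", {
  sim <- small_sim()
  du <- make_cells(sim$design[!sim$design$treated & sim$design$series == "early", ])
  expect_error(run_contrast_scan(sim$matrix, du, list(c("nope", "none_early_t0")),
                                 n_perm = 100),
               "invalid contrast")
  scan0 <- run_contrast_scan(sim$matrix, du,
                             list(c("none_early_t3", "none_early_t0")),
                             q_threshold = 0, n_perm = 100, seed = 3)
  expect_length(scan0$deg_sets[[1L]]$genes, 0L)
})

test_that("ANOVA decomposition conserves the data and recovers exact additive structure", {
  d <- build_design(simulation_config(n_individuals = 8L))
  d <- make_cells(d)
  cells <- sort(unique(d$cell))
  inds <- unique(d$individual_id)
  grp_of <- stats::setNames(d$group[!duplicated(d$individual_id)],
                            d$individual_id[!duplicated(d$individual_id)])

  ## exact additive truth, constraints as declared
  set.seed(31)
  ce <- stats::setNames(rnorm(length(cells)), cells)
  ce <- ce - mean(ce)
  ie <- stats::setNames(rnorm(length(inds), 0, 0.5), inds)
  for (g in unique(grp_of)) {
    sel <- names(ie)[grp_of[names(ie)] == g]
    ie[sel] <- ie[sel] - mean(ie[sel])
  }
  y <- 3 + ce[d$cell] + ie[d$individual_id]
  m <- matrix(y, 2, nrow(d), byrow = TRUE, dimnames = list(c("gA", "gB"), d$sample_id))
  dec <- anova_decomposition(m, d)
  expect_equal(unname(dec$mu), c(3, 3), tolerance = 1e-10)
  expect_equal(dec$cell_effects["gA", cells], ce, tolerance = 1e-10)
  expect_equal(dec$individual_effects["gA", inds], ie, tolerance = 1e-10)
  expect_lt(max(abs(dec$residuals)), 1e-10)

  ## conservation and sum-to-zero on arbitrary data
  set.seed(37)
  mr <- expr_fixture(matrix(rnorm(10 * nrow(d)), 10, nrow(d)), samples = d$sample_id)
  dr <- anova_decomposition(mr, d)
  recon <- anova_fitted(dr) + dr$residuals
  expect_lt(max(abs(recon - mr[, colnames(recon)])), 1e-9)
  expect_lt(max(abs(rowSums(dr$cell_effects))), 1e-9)
  expect_lt(max(abs(rowSums(dr$individual_effects))), 1e-9)

  ## a sample missing from one individual's grid is reported as an empty cell
  d_missing <- d[-2L, ]
  expect_error(anova_decomposition(mr[, d_missing$sample_id], d_missing),
               "empty design cell")
})
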