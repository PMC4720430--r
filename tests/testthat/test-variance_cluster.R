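test_that("variance ranking matches a two-pass SD oracle and breaks ties by gene ID", {
  vals <- matrix(c(1, 2, 3, 4,
                   5, 5, 5, 5,
                   0, 4, 2, 6), 3, 4, byrow = TRUE)
  m <- expr_fixture(vals, genes = c("gB", "gC", "gA"))
  rk <- top_variable_genes(m, n = 2)
  manual <- apply(vals, 1L, function(r) sqrt(sum((r - mean(r))^2) / 3))
  expect_equal(rk$table$sd, unname(manual))
  expect_identical(rk$top, c("gA", "gB"))
  expect_equal(rk$table$rank[rk$table$gene_id == "gC"], 3L)  # constant gene last

  tie <- expr_fixture(rbind(c(0, 1), c(0, 1), c(0, 2)), genes = c("gB", "gA", "gC"))
  rk2 <- top_variable_genes(tie, n = 3)
  expect_identical(rk2$top, c("gC", "gA", "gB"))  # tie gA/gB resolved lexicographically

  expect_error(top_variable_genes(m, n = 10), "between 1 and")
  expect_error(top_variable_genes(m, samples = "s01", n = 1), "at least 2 samples")
})

test_that("Ward merges and delta-ESS heights equal the brute-force oracle", {
  pts <- c(0, 0.1, 10, 10.1)
  m <- expr_fixture(cbind(pts, 0), samples = c("s1", "s2"))
  dn <- ward_cluster(m, rownames(m), scale = FALSE)
  oracle <- ward_oracle(cbind(pts, 0))
  expect_equal(sort(dn$heights), sort(oracle$heights), tolerance = 1e-10)
  ## first two merges pair the close points at height d^2/2 = 0.005
  expect_equal(dn$heights[1:2], c(0.005, 0.005), tolerance = 1e-12)
  ## final partition before the root matches the oracle's
  grp <- stats::cutree(dn$hclust, k = 2)
  expect_equal(unname(grp), c(1, 1, 2, 2))

  ## a 5-point layout with unequal gaps
  pts5 <- c(0, 0.3, 1.1, 5, 5.4)
  m5 <- expr_fixture(cbind(pts5, 1), samples = c("s1", "s2"))
  dn5 <- ward_cluster(m5, rownames(m5), scale = FALSE)
  or5 <- ward_oracle(cbind(pts5, 1))
  expect_equal(sort(dn5$heights), sort(or5$heights), tolerance = 1e-10)

  ## single pair: one merge at squared distance / 2
  mp <- expr_fixture(rbind(c(0, 0), c(3, 4)))
  dnp <- ward_cluster(mp, rownames(mp), scale = FALSE)
  expect_equal(dnp$heights, 25 / 2)
})

test_that("Ward heights are monotone and identical pairs merge first at height zero", {
  set.seed(7)
  base <- matrix(rnorm(40), 4, 10)
  m <- expr_fixture(rbind(base[1, ], base[1, ], base[3, ], base[3, ]),
                    genes = c("a1", "a2", "b1", "b2"))
  dn <- ward_cluster(m, rownames(m))
  expect_equal(dn$heights[1:2], c(0, 0), tolerance = 1e-20)
  expect_true(all(diff(dn$heights) >= -1e-12))
  ord <- dn$order
  expect_true(abs(match("a1", ord) - match("a2", ord)) == 1)  # pairs adjacent

  set.seed(8)
  big <- expr_fixture(matrix(rnorm(50 * 8), 50, 8))
  dnb <- ward_cluster(big, rownames(big))
  expect_true(all(diff(dnb$heights) >= -1e-10))
})

test_that("seeded cluster extraction returns the minimal node containing all seeds", {
  set.seed(21)
  ## five co-expressed genes laid out as a tight chain; seeding with its two
  ## extremes forces the lowest common node to be the whole chain
  tight <- outer(c(0, 0.01, 0.02, 0.03, 0.04), rep(1, 12)) +
    matrix(rep(sin(1:12), each = 5), 5, 12)
  rest <- matrix(rnorm(95 * 12, 0, 3), 95, 12)
  m <- expr_fixture(rbind(tight, rest),
                    genes = c(sprintf("core%02d", 1:5), sprintf("bg%03d", 1:95)))
  dn <- ward_cluster(m, rownames(m), scale = FALSE)
  cl <- extract_seeded_cluster(dn, c("core01", "core05"), max_size = 20)
  expect_setequal(cl$genes, sprintf("core%02d", 1:5))
  expect_false(attr(cl, "oversize"))

  ## minimality: no child of the returned node contains all seeds
  merge <- dn$hclust$merge
  labels <- dn$labels
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    mem <- function(k) if (k < 0) labels[-k] else members[[k]]
    members[[i]] <- c(mem(merge[i, 1L]), mem(merge[i, 2L]))
  }
  node <- which(vapply(members, function(x) setequal(x, cl$genes), logical(1)))[1L]
  for (child in merge[node, ]) {
    child_mem <- if (child < 0) labels[-child] else members[[child]]
    expect_false(all(c("core01", "core05") %in% child_mem))
  }

  ## a single seed yields the smallest non-leaf node containing it
  cl1 <- extract_seeded_cluster(dn, "core03")
  expect_true("core03" %in% cl1$genes)
  expect_gte(length(cl1$genes), 2L)
  expect_lte(length(cl1$genes), 5L)

  ## seeds forced across the root come back as all leaves, flagged over-size
  two_blocks <- expr_fixture(rbind(matrix(0:3, 2, 2), matrix(100 + (0:3), 2, 2)),
                             genes = c("x1", "x2", "y1", "y2"))
  dnf <- ward_cluster(two_blocks, rownames(two_blocks), scale = FALSE)
  clf <- extract_seeded_cluster(dnf, c("x1", "y1"), max_size = 3)
  expect_setequal(clf$genes, rownames(two_blocks))
  expect_true(attr(clf, "oversize"))

  expect_error(extract_seeded_cluster(dn, "nope"), "nope")
})

test_that("PCA subsets separate orthogonal blocks and match an eigen oracle", {
  set.seed(5)
  u <- rnorm(12); v <- rnorm(12)
  v <- v - sum(u * v) / sum(u^2) * u        # orthogonalize
  block1 <- outer(rep(5, 50), u) + matrix(rnorm(600, 0, 0.05), 50, 12)
  block2 <- outer(rep(5, 50), -u) + matrix(rnorm(600, 0, 0.05), 50, 12)
  m <- expr_fixture(rbind(block1, block2))
  res <- pca_gene_subsets(m, rownames(m),
                          rule = list(list(name = "I", pc1_min = 0),
                                      list(name = "II", pc1_max = 0)))
  s1 <- res$sets[[1L]]$genes; s2 <- res$sets[[2L]]$genes
  expect_equal(length(s1) + length(s2), 100L)
  expect_true(setequal(s1, rownames(m)[1:50]) || setequal(s1, rownames(m)[51:100]))

  ## eigen oracle for variance explained
  centred <- sweep(m, 2L, colMeans(m))
  ev <- eigen(stats::cov(centred), symmetric = TRUE)$values  # sample-space covariance
  total_pc1 <- ev[1L] / sum(ev[ev > 1e-12])
  expect_equal(res$var_explained[1L] / sum(res$var_explained), total_pc1,
               tolerance = 1e-6)

  ## deterministic sign: largest-magnitude PC1 loading is positive
  res2 <- pca_gene_subsets(m, rownames(m), rule = list(list(name = "I", pc1_min = 0)))
  expect_identical(res$sets[[1L]]$genes, res2$sets[[1L]]$genes)

  flat <- expr_fixture(matrix(1, 5, 4))
  expect_error(pca_gene_subsets(flat, rownames(flat), rule = list(list(name = "x"))),
               "no principal structure")
})
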