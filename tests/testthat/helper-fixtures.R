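# Shared fixtures and independent oracles, built in code at test time.

# Balanced one-way sample table: `a` individuals x `n` consecutive samples.
oneway_table <- function(a = 4, n = 5) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(a * n)),
    individual_id = rep(sprintf("M%02d", seq_len(a)), each = n),
    series = "early",
    recovery_time_h = rep(seq_len(n) - 1, a),
    dose = "none",
    treated = FALSE,
    stringsAsFactors = FALSE
  )
}

# A small labelled expression matrix from a numeric matrix.
expr_fixture <- function(values, genes = sprintf("g%02d", seq_len(nrow(values))),
                         samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  values
}

# Brute-force Ward clustering oracle: at every step, recompute the exact
# increase in within-cluster sum of squares for every cluster pair from the
# raw points and merge the minimum.  Returns merge heights (delta-ESS) and
# the member partition after each merge.
ward_oracle <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  clusters <- lapply(seq_len(nrow(points)), identity)
  ess <- function(idx) {
    x <- points[idx, , drop = FALSE]
    sum(sweep(x, 2L, colMeans(x))^2)
  }
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best[1L]) best <- c(d, i, j)
      }
    }
    i <- best[2L]; j <- best[3L]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
    heights <- c(heights, best[1L])
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Exhaustive hypergeometric upper tail: enumerate all possible draws of size
# n from a background of size N containing K successes.
hyper_tail_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# Closed-form REML for the balanced one-way layout.
oneway_reml_oracle <- function(y, a, n) {
  im <- colMeans(matrix(y, n, a))
  gm <- mean(y)
  msb <- n * sum((im - gm)^2) / (a - 1)
  msw <- sum((y - rep(im, each = n))^2) / (a * (n - 1))
  if (msb >= msw) {
    c(sigma_u2 = (msb - msw) / n, sigma_e2 = msw)
  } else {
    c(sigma_u2 = 0, sigma_e2 = sum((y - gm)^2) / (a * n - 1))
  }
}

# Small simulated experiment shared by several slow-ish tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 400, n_composition = 60,
                               n_circadian = 30, n_handling = 20,
                               n_individual_genes = 40, n_treatment = 30,
                               rng_seed = 42)
      cache <<- c(simulate_experiment(cfg), list(design = build_design(cfg), config = cfg))
    }
    cache
  }
})
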