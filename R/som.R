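## Per-individual 2x2 self-organizing maps over scaled gene profiles, and a
## quantitative within/between-individual profile-coherence score.

# 2x2 grid node coordinates.
SOM_GRID <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))

#' Fit a 2x2 self-organizing map to one individual's gene profiles
#'
#' Gene profiles (one value per time point of the individual) are scaled to
#' mean 0 / SD 1, then fitted with the batch Kohonen algorithm on a 2x2
#' grid: Gaussian neighbourhood whose radius decays linearly from 1 to 0
#' over the first half of the epochs, after which updates are plain batch
#' k-means (so the quantization error is non-increasing).  The codebook is
#' initialised from the first two principal components of the profiles,
#' making the fit deterministic; `seed` is accepted for interface stability
#' but the batch fit draws no random numbers.
#'
#' @param matrix expression matrix.
#' @param genes gene set (IDs) to map.
#' @param individual individual ID.
#' @param samples that individual's sample IDs (>= 3); defaults to all
#'   samples of `individual` in `sample_table` when given.
#' @param sample_table optional sample table used to look up `samples`.
#' @param seed integer, kept for API symmetry.
#' @param epochs batch epochs.
#' @return list of class `som_fit`: `codebook` (4 x time points),
#'   `assignment` (node index per gene), `occupancy` (counts per node),
#'   `qe_per_epoch` (mean squared quantization error after each epoch),
#'   `excluded` (constant genes dropped, with warning).
#' @export
fit_som_grid <- function(matrix, genes, individual, samples = NULL,
                         sample_table = NULL, seed = 1L, epochs = 20L) {
  validate_expression_matrix(matrix)
  if (is.null(samples)) {
    if (is.null(sample_table)) stop("give either `samples` or `sample_table`")
    samples <- sample_table$sample_id[sample_table$individual_id == individual]
  }
  if (!length(samples)) stop("individual '", individual, "' has no samples")
  if (length(samples) < 3L) stop("need >= 3 samples for individual '", individual, "'")
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  x <- matrix[genes, samples, drop = FALSE]
  xs <- scale_rows(x)
  excluded <- attr(xs, "zero_sd")
  if (length(excluded)) {
    warning(length(excluded), " all-constant gene(s) excluded from SOM fit")
    xs <- xs[setdiff(rownames(xs), excluded), , drop = FALSE]
  }
  if (nrow(xs) < 1L) stop("no non-constant genes left to map")

  ## codebook init from the first two principal components
  ctr <- colMeans(xs)
  sv <- svd(sweep(xs, 2L, ctr))
  k <- ncol(xs)
  ## singular values at numerical-noise level count as zero, so identical
  ## profiles collapse onto a single node
  d_tol <- 1e-8 * max(1, sqrt(sum(xs^2)))
  pc1 <- if (length(sv$d) >= 1L && sv$d[1L] > d_tol) sv$v[, 1L] * sv$d[1L] / sqrt(max(1, nrow(xs))) else rep(0, k)
  pc2 <- if (length(sv$d) >= 2L && sv$d[2L] > d_tol) sv$v[, 2L] * sv$d[2L] / sqrt(max(1, nrow(xs))) else rep(0, k)
  code <- rbind(ctr - pc1 - pc2, ctr + pc1 - pc2, ctr - pc1 + pc2, ctr + pc1 + pc2)

  assign_nodes <- function(code) {
    d2 <- outer(rowSums(xs^2), rowSums(code^2), "+") - 2 * tcrossprod(xs, code)
    ## near-ties (within numerical noise) resolve to the first node, so
    ## coincident codebooks behave as one
    dmin <- do.call(pmin, as.data.frame(d2))
    tol <- 1e-9 * (1 + max(abs(d2)))
    max.col(d2 <= dmin + tol, ties.method = "first")
  }
  qe <- numeric(epochs)
  assignment <- assign_nodes(code)
  half <- ceiling(epochs / 2)
  for (e in seq_len(epochs)) {
    r <- if (e <= half) 1 - (e - 1) / half else 0
    assignment <- assign_nodes(code)
    if (r > 0) {
      gd2 <- as.matrix(stats::dist(SOM_GRID))^2
      h <- exp(-gd2 / (2 * r^2))
      w <- h[assignment, , drop = FALSE]           # genes x nodes
      denom <- colSums(w)
      upd <- crossprod(w, xs) / denom
      ok <- denom > 0
      code[ok, ] <- upd[ok, ]
    } else {
      for (kk in 1:4) {
        sel <- assignment == kk
        if (any(sel)) code[kk, ] <- colMeans(xs[sel, , drop = FALSE])
      }
    }
    assignment <- assign_nodes(code)
    qe[e] <- mean(rowSums((xs - code[assignment, , drop = FALSE])^2))
  }
  occupancy <- tabulate(assignment, nbins = 4L)
  names(assignment) <- rownames(xs)
  structure(list(codebook = code, assignment = assignment,
                 occupancy = occupancy, qe_per_epoch = qe,
                 excluded = excluded, individual = individual,
                 samples = samples),
            class = "som_fit")
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> individual %s: occupancy %s, final QE %.4g\n",
              x$individual, paste(x$occupancy, collapse = "/"),
              utils::tail(x$qe_per_epoch, 1)))
  invisible(x)
}

#' Within/between-individual profile coherence of a gene set
#'
#' Quantifies the composition fingerprint: for each individual, the mean
#' pairwise Pearson correlation of the member genes' profiles over that
#' individual's time points (within-coherence); and, across individuals
#' sharing a sampling grid (same series), the mean pairwise correlation of
#' the per-individual mean scaled profiles (between-coherence).  The
#' composition-signature flag is raised when within-coherence is high while
#' between-coherence is low.
#'
#' @param matrix expression matrix.
#' @param genes gene set (>= 2 IDs).
#' @param sample_table sample table.
#' @param group optional sample IDs restricting the analysis (default: all).
#' @param within_threshold,between_threshold flag thresholds.
#' @return list of class `coherence_report`: `within` (overall mean),
#'   `within_by_individual`, `between`, `between_by_series`, `flag`,
#'   `n_undefined` (zero-variance profiles excluded), `skipped` individuals
#'   (< 3 time points, with warning).
#' @export
profile_coherence <- function(matrix, genes, sample_table,
                              group = sample_table$sample_id,
                              within_threshold = 0.8, between_threshold = 0.3) {
  validate_expression_matrix(matrix)
  validate_sample_table(sample_table)
  if (length(genes) < 2L) stop("need >= 2 genes for a coherence score")
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  st <- sample_table[sample_table$sample_id %in% group, , drop = FALSE]
  inds <- unique(st$individual_id)
  if (length(inds) < 2L) stop("need >= 2 individuals in the group")

  n_undef <- 0L
  skipped <- character(0)
  within_by <- c()
  mean_profiles <- list()
  for (iid in inds) {
    sids <- st$sample_id[st$individual_id == iid]
    if (length(sids) < 3L) {
      warning("individual '", iid, "' has < 3 time points; skipped")
      skipped <- c(skipped, iid)
      next
    }
    x <- matrix[genes, sids, drop = FALSE]
    sds <- row_sds(x)
    ok <- sds > 0
    n_undef <- n_undef + sum(!ok)
    if (sum(ok) < 2L) { skipped <- c(skipped, iid); next }
    cc <- stats::cor(t(x[ok, , drop = FALSE]))
    within_by[iid] <- mean(cc[upper.tri(cc)])
    mean_profiles[[iid]] <- colMeans(scale_rows(x[ok, , drop = FALSE]))
  }
  if (!length(within_by)) stop("no individual had enough usable profiles")

  between_by <- c()
  pair_cors <- numeric(0)
  for (ser in unique(st$series)) {
    iids <- intersect(names(mean_profiles),
                      unique(st$individual_id[st$series == ser]))
    if (length(iids) < 2L) next
    prof <- do.call(rbind, mean_profiles[iids])
    sds <- row_sds(prof)
    prof <- prof[sds > 0, , drop = FALSE]
    n_undef <- n_undef + sum(sds == 0)
    if (nrow(prof) < 2L) next
    cc <- stats::cor(t(prof))
    between_by[ser] <- mean(cc[upper.tri(cc)])
    pair_cors <- c(pair_cors, cc[upper.tri(cc)])
  }
  within <- mean(within_by)
  between <- if (length(pair_cors)) mean(pair_cors) else NA_real_
  flag <- isTRUE(within >= within_threshold) && isTRUE(between <= between_threshold)
  structure(list(within = within, within_by_individual = within_by,
                 between = between, between_by_series = between_by,
                 flag = flag, n_undefined = n_undef, skipped = skipped),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("<coherence_report> within = %.3f, between = %.3f, composition flag: %s\n",
              x$within, x$between, x$flag))
  invisible(x)
}
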