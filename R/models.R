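## Statistical core: per-gene mixed linear model (random individual
## intercept, REML by profile likelihood), the permutation-based shrinkage
## Fs test, Storey-Tibshirani q-values, contrast scans, and the additive
## ANOVA decomposition.

#' Add the group-means design cell to a sample table
#'
#' The cell label is `<group>_t<time>`, with `group` taken from the table's
#' `group` column when present, else derived as `<series>_<dose>`.  Cells are
#' the units of the group-means parameterization: one mean per
#' dose-by-recovery-time combination, kept separate per series.
#'
#' @param samples sample table.
#' @return the table with a `cell` character column.
#' @export
make_cells <- function(samples) {
  validate_sample_table(samples)
  grp <- if ("group" %in% colnames(samples)) samples$group else
    paste(samples$series, samples$dose, sep = "_")
  samples$cell <- paste0(grp, "_t", fmt_time(samples$recovery_time_h))
  samples
}

# REML criterion pieces for V = I + theta * Z Z' with Z the individual
# indicator.  All quantities use block identities (no n x n matrices).
.reml_pieces <- function(theta, XtX, Xty, yty, X1, S, n_i) {
  w <- theta / (1 + theta * n_i)
  A <- XtX - X1 %*% (w * t(X1))
  b <- Xty - X1 %*% (w * S)
  q <- yty - sum(w * S^2)
  beta <- solve(A, b)
  rss <- q - sum(b * beta)
  list(A = A, beta = drop(beta), rss = max(rss, 1e-300), w = w)
}

.reml_criterion <- function(theta, XtX, Xty, yty, X1, S, n_i, n, p) {
  pc <- .reml_pieces(theta, XtX, Xty, yty, X1, S, n_i)
  (n - p) * log(pc$rss / (n - p)) + sum(log(1 + theta * n_i)) +
    determinant(pc$A, logarithm = TRUE)$modulus[1L]
}

# Analytic derivative of the REML criterion in theta; used to polish the
# optimum to machine precision.
.reml_score <- function(theta, XtX, Xty, yty, X1, S, n_i, n, p) {
  pc <- .reml_pieces(theta, XtX, Xty, yty, X1, S, n_i)
  dw <- 1 / (1 + theta * n_i)^2
  dA <- -X1 %*% (dw * t(X1))
  db <- -X1 %*% (dw * S)
  dq <- -sum(dw * S^2)
  beta <- pc$beta
  drss <- dq - (2 * sum(db * beta) - drop(crossprod(beta, dA %*% beta)))
  (n - p) * drss / pc$rss + sum(n_i / (1 + theta * n_i)) +
    sum(diag(solve(pc$A, dA)))
}

#' Fit a per-gene linear model with an individual random intercept
#'
#' Fixed effects use a group-means parameterization of `fixed` (one mean per
#' factor level; `fixed = NULL` fits an intercept only).  With
#' `random_individual = TRUE` the individual variance component is estimated
#' by REML, profiling the likelihood over the variance ratio
#' `theta = sigma_u^2 / sigma_e^2` (one-dimensional Brent search with a
#' narrow refinement pass; boundary `theta = 0` compared explicitly, so
#' `sigma_u^2` is truncated at zero).  Individual coefficients are the best
#' linear unbiased predictions of the random intercepts.  On a balanced
#' one-way layout the closed-form ANOVA/REML solution is used
#' (`method = "auto"`); `method = "profile"` forces the optimizer.
#'
#' @param y numeric vector, one gene's expression over `samples` rows.
#' @param samples sample table (defines the individual blocking).
#' @param fixed name of a factor column in `samples` (e.g. `"cell"`,
#'   `"biopsy_order"`), or `NULL` for intercept-only.
#' @param random_individual if `FALSE`, ordinary least squares.
#' @param method `"auto"`, `"profile"` or `"closed_form"`.
#' @return list of class `mixed_model_fit`: `mu` (intercept / grand cell
#'   mean), `fixed_coefs` (per-level means), `individual_coefs` (BLUPs,
#'   named), `sigma_u2`, `sigma_e2`, `theta`, `df_residual`.
#' @export
fit_mixed_model <- function(y, samples, fixed = NULL, random_individual = TRUE,
                            method = c("auto", "profile", "closed_form")) {
  method <- match.arg(method)
  validate_sample_table(samples)
  n <- length(y)
  if (n != nrow(samples)) stop("length(y) must match nrow(samples)")
  ind <- factor(samples$individual_id)
  n_i <- as.vector(table(ind))
  if (random_individual && nlevels(ind) < 2L) stop("need >= 2 individuals for a random intercept")

  if (is.null(fixed)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    f_levels <- NULL
  } else {
    f <- factor(samples[[fixed]])
    if (any(is.na(f))) stop("fixed factor '", fixed, "' has missing values")
    X <- stats::model.matrix(~ 0 + f)
    colnames(X) <- levels(f)
    f_levels <- levels(f)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed design; confounded level(s): ", paste(aliased, collapse = ", "))
  }
  p <- ncol(X)

  if (!random_individual) {
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    out <- list(mu = mean(fit$fitted.values), fixed_coefs = fit$coefficients,
                individual_coefs = stats::setNames(rep(0, nlevels(ind)), levels(ind)),
                sigma_u2 = 0, sigma_e2 = s2, theta = 0, df_residual = n - p,
                fixed_levels = f_levels, random_individual = FALSE)
    class(out) <- "mixed_model_fit"
    return(out)
  }

  Ind <- stats::model.matrix(~ 0 + ind)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  X1 <- crossprod(X, Ind)       # p x n_ind, per-individual column sums of X
  S <- drop(crossprod(Ind, y))  # per-individual sums of y

  balanced_oneway <- p == 1L && is.null(fixed) && length(unique(n_i)) == 1L
  if (method == "closed_form" && !balanced_oneway) {
    stop("closed_form method requires a balanced one-way (intercept-only) layout")
  }

  if (balanced_oneway && method != "profile") {
    a <- nlevels(ind); m <- n_i[1L]
    gm <- mean(y); im <- S / m
    msb <- m * sum((im - gm)^2) / (a - 1)
    msw <- sum((y - im[as.integer(ind)])^2) / (a * (m - 1))
    if (msb >= msw) {
      sigma_u2 <- (msb - msw) / m
      sigma_e2 <- msw
    } else {
      sigma_u2 <- 0
      sigma_e2 <- sum((y - gm)^2) / (n - 1)  # boundary REML
    }
    theta <- if (sigma_e2 > 0) sigma_u2 / sigma_e2 else 0
  } else {
    crit <- function(th) .reml_criterion(th, XtX, Xty, yty, X1, S, n_i, n, p)
    score <- function(th) .reml_score(th, XtX, Xty, yty, X1, S, n_i, n, p)
    if (score(0) >= 0) {
      theta <- 0  # criterion increasing at the boundary: truncate
    } else {
      opt <- stats::optimize(crit, interval = c(0, 1e4), tol = 1e-8)
      th <- max(opt$minimum, 1e-10)
      lo <- th / 2; hi <- th * 2
      while (score(hi) < 0 && hi < 1e8) { lo <- hi; hi <- hi * 4 }
      while (score(lo) > 0 && lo > 1e-12) lo <- lo / 4
      theta <- if (score(hi) < 0) hi
        else if (score(lo) > 0) 0
        else stats::uniroot(score, c(lo, hi), tol = 1e-14 * max(1, th))$root
      if (crit(0) <= crit(theta)) theta <- 0
    }
    pc <- .reml_pieces(theta, XtX, Xty, yty, X1, S, n_i)
    sigma_e2 <- pc$rss / (n - p)
    sigma_u2 <- theta * sigma_e2
  }

  pc <- .reml_pieces(theta, XtX, Xty, yty, X1, S, n_i)
  beta <- pc$beta
  Sres <- S - drop(crossprod(X1, beta))
  blup <- theta * Sres / (1 + theta * n_i)
  names(blup) <- levels(ind)
  out <- list(mu = mean(X %*% beta), fixed_coefs = stats::setNames(beta, colnames(X)),
              individual_coefs = blup, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              theta = theta, df_residual = n - p - (nlevels(ind) - 1L),
              fixed_levels = f_levels, random_individual = TRUE)
  class(out) <- "mixed_model_fit"
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> sigma_u^2 = %.4g, sigma_e^2 = %.4g, %d individual coefficient(s)\n",
              x$sigma_u2, x$sigma_e2, length(x$individual_coefs)))
  invisible(x)
}

#' Fit the individual-intercept model to every gene of a matrix
#'
#' Vectorized REML over a fixed grid of variance ratios (the profile
#' criterion is evaluated for all genes at once per grid point), returning
#' per-gene variance components and individual-coefficient BLUPs.  Intended
#' for screening rules over thousands of genes; use [fit_mixed_model()] when
#' a single gene needs full-precision estimates.
#'
#' @param matrix expression matrix (genes x samples).
#' @param samples sample table matching the matrix columns.
#' @param fixed factor column name for the group-means fixed effects.
#' @param theta_grid grid of variance ratios (0 included automatically).
#' @return list of class `mixed_model_fits`: `individual_coefs` (genes x
#'   individuals), `sigma_u2`, `sigma_e2`, `theta` (per gene).
#' @export
fit_mixed_models <- function(matrix, samples, fixed = "cell",
                             theta_grid = c(0, exp(seq(log(1e-4), log(500), length.out = 100)))) {
  validate_expression_matrix(matrix)
  validate_sample_table(samples)
  st <- samples[match(colnames(matrix), samples$sample_id), ]
  if (anyNA(st$sample_id)) stop("matrix columns missing from sample table")
  Y <- matrix
  n <- ncol(Y)
  ind <- factor(st$individual_id)
  n_i <- as.vector(table(ind))
  f <- factor(st[[fixed]])
  X <- stats::model.matrix(~ 0 + f)
  colnames(X) <- levels(f)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular fixed design in fit_mixed_models()")
  p <- ncol(X)
  Ind <- stats::model.matrix(~ 0 + ind)

  XtX <- crossprod(X)
  X1 <- crossprod(X, Ind)
  Sg <- Y %*% Ind                      # G x n_ind block sums
  XtY <- tcrossprod(t(X), Y)           # p x G
  yty <- rowSums(Y^2)

  G <- nrow(Y)
  best_crit <- rep(Inf, G)
  best_theta <- numeric(G)
  for (th in theta_grid) {
    w <- th / (1 + th * n_i)
    A <- XtX - X1 %*% (w * t(X1))
    b <- XtY - X1 %*% (w * t(Sg))      # p x G
    q <- yty - drop(Sg^2 %*% w)
    Cb <- solve(A, b)
    rss <- pmax(q - colSums(b * Cb), 1e-300)
    crit <- (n - p) * log(rss / (n - p)) + sum(log(1 + th * n_i)) +
      determinant(A, logarithm = TRUE)$modulus[1L]
    upd <- crit < best_crit
    best_crit[upd] <- crit[upd]
    best_theta[upd] <- th
  }

  blup <- matrix(0, G, nlevels(ind), dimnames = list(rownames(Y), levels(ind)))
  sigma_e2 <- numeric(G)
  for (th in unique(best_theta)) {
    sel <- best_theta == th
    w <- th / (1 + th * n_i)
    A <- XtX - X1 %*% (w * t(X1))
    b <- XtY[, sel, drop = FALSE] - X1 %*% (w * t(Sg[sel, , drop = FALSE]))
    beta <- solve(A, b)                # p x g
    q <- yty[sel] - drop(Sg[sel, , drop = FALSE]^2 %*% w)
    rss <- pmax(q - colSums(b * beta), 1e-300)
    sigma_e2[sel] <- rss / (n - p)
    Sres <- Sg[sel, , drop = FALSE] - t(crossprod(X1, beta))
    blup[sel, ] <- sweep(Sres, 2L, th / (1 + th * n_i), "*")
  }
  structure(list(individual_coefs = blup, sigma_u2 = best_theta * sigma_e2,
                 sigma_e2 = sigma_e2, theta = best_theta, fixed = fixed),
            class = "mixed_model_fits")
}

# Shrink per-gene log residual variances toward their across-gene mean with
# a James-Stein factor whose noise scale is trigamma(df/2), the theoretical
# variance of a log chi-square.  The common log-scale bias term
# digamma(df/2) - log(df/2) is identical for all genes and cancels from the
# permutation p-values, so it is not applied.
shrink_variances <- function(s2, df, n_genes = length(s2)) {
  x <- log(pmax(s2, 1e-300))
  xbar <- mean(x)
  ssq <- sum((x - xbar)^2)
  nu <- trigamma(df / 2)
  B <- if (ssq > 0 && n_genes > 3L) max(0, 1 - (n_genes - 3) * nu / ssq) else 0
  exp(xbar + B * (x - xbar))
}

# Moore-Penrose machinery for one design: returns the per-gene contrast
# estimate vector `a` (so est = Y %*% a), the contrast quadratic form
# denominator, an orthonormal basis U of the column space (fitted SS), and
# the design rank.
.contrast_machinery <- function(Xw, cvec) {
  sv <- svd(Xw)
  pos <- sv$d > max(dim(Xw)) * max(sv$d, 0) * 1e-10
  r <- sum(pos)
  if (r == 0L) stop("design has rank 0 after absorption")
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  d <- sv$d[pos]
  cproj <- V %*% crossprod(V, cvec)
  if (max(abs(cproj - cvec)) > 1e-8 * max(1, max(abs(cvec)))) {
    stop("contrast is not estimable in this design (between-individual ",
         "contrast under individual absorption?)")
  }
  a <- U %*% ((crossprod(V, cvec)) / d)
  denom <- sum((crossprod(V, cvec) / d)^2)
  list(a = drop(a), denom = denom, U = U, rank = r)
}

# Center columns of M within individual blocks.
.absorb_individuals <- function(M, ind) {
  mns <- rowsum(M, ind) / as.vector(table(ind))
  M - mns[as.character(ind), , drop = FALSE]
}

#' Permutation-based shrinkage Fs test for a contrast
#'
#' Tests differential expression between two levels of a design factor with
#' an F-like statistic whose gene-specific residual variance is replaced by
#' a James-Stein-shrunken estimate (stabilizing tests with few replicates),
#' and whose null distribution is built by permutation.
#'
#' With `random_individual = TRUE` the individual blocking is handled by
#' absorption: response and design are centred within individuals, which
#' makes the statistic exactly invariant to per-individual constants and
#' matches the mixed model's generalized-least-squares estimate for
#' within-individual contrasts.  Labels are then permuted within each
#' individual.  For contrasts whose levels never co-occur within an
#' individual (e.g. treated vs time-matched untreated), whole-individual
#' group labels are permuted within each series instead, and
#' `random_individual` must be `FALSE`.
#'
#' The permutation null is pooled across genes by default:
#' `p_g = (1 + #\{pooled permuted Fs >= Fs_g\}) / (1 + G * n_perm)`.
#'
#' @param matrix expression matrix.
#' @param samples sample table covering the matrix columns.
#' @param factor_name design-factor column in `samples` (e.g.
#'   `"biopsy_order"` or `"cell"`); rows with `NA` are dropped.
#' @param contrast length-2 character vector of factor levels (A vs B).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; results are bit-identical given it.
#' @param random_individual absorb the individual blocking (see above).
#' @param pooling `"pooled"` (default) or `"per_gene"` null.
#' @param shrink apply the variance shrinkage (set `FALSE` for the
#'   classical per-gene F).
#' @return list of class `fs_test_result`: `table` (gene_id, ms_contrast,
#'   s2_raw, s2_shrunk, Fs, p), `df_residual`, `contrast`, `n_perm`,
#'   `excluded_individuals`, `permutation_scheme`.
#' @export
fs_permutation_test <- function(matrix, samples, factor_name, contrast,
                                n_perm = 300L, seed = 1L,
                                random_individual = TRUE,
                                pooling = c("pooled", "per_gene"),
                                shrink = TRUE) {
  pooling <- match.arg(pooling)
  validate_expression_matrix(matrix)
  validate_sample_table(samples)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (length(contrast) != 2L) stop("contrast must be two factor levels")
  st <- samples[samples$sample_id %in% colnames(matrix), , drop = FALSE]
  fvals <- as.character(st[[factor_name]])
  st <- st[!is.na(fvals), , drop = FALSE]
  fvals <- fvals[!is.na(fvals)]
  if (!all(contrast %in% fvals)) {
    stop("contrast level(s) absent from '", factor_name, "': ",
         paste(setdiff(contrast, fvals), collapse = ", "))
  }

  ## which individuals see both contrast levels?
  has_level <- function(iid, lev) any(fvals[st$individual_id == iid] == lev)
  inds_all <- unique(st$individual_id)
  both <- vapply(inds_all, function(i) has_level(i, contrast[1L]) && has_level(i, contrast[2L]), logical(1))
  scheme <- if (any(both)) "within_individual" else "between_individual"

  excluded <- character(0)
  if (scheme == "within_individual") {
    excluded <- inds_all[!both]
    if (length(excluded)) {
      warning(length(excluded), " individual(s) missing a contrast level excluded: ",
              paste(utils::head(excluded, 8), collapse = ", "))
    }
    st <- st[st$individual_id %in% inds_all[both], , drop = FALSE]
    if (!nrow(st)) stop("all individuals excluded for contrast ", paste(contrast, collapse = " vs "))
    fvals <- as.character(st[[factor_name]])
  } else {
    if (random_individual) {
      stop("contrast ", paste(contrast, collapse = " vs "),
           " is between-individual; refit with random_individual = FALSE ",
           "(whole-individual labels are then permuted within series)")
    }
    any_lvl <- vapply(inds_all, function(i) has_level(i, contrast[1L]) || has_level(i, contrast[2L]), logical(1))
    excluded <- inds_all[!any_lvl]
  }

  Y <- matrix[, st$sample_id, drop = FALSE]
  G <- nrow(Y)
  n <- ncol(Y)
  ind <- factor(st$individual_id)
  f <- factor(fvals)
  cvec_for <- function(f) {
    v <- stats::setNames(rep(0, nlevels(f)), levels(f))
    v[contrast[1L]] <- 1; v[contrast[2L]] <- -1
    v
  }

  stats_for <- function(f, Yw) {
    X <- stats::model.matrix(~ 0 + f)
    colnames(X) <- levels(f)
    if (random_individual) X <- .absorb_individuals(X, ind)
    mach <- .contrast_machinery(X, cvec_for(f))
    est <- drop(Yw %*% mach$a)                        # contrast estimate c'beta
    ms <- est^2 / mach$denom                          # contrast mean-square
    fit_ss <- rowSums((Yw %*% mach$U)^2)
    rss <- pmax(rowSums(Yw^2) - fit_ss, 0)
    df <- n - mach$rank - if (random_individual) (nlevels(ind)) else 0L
    list(ms = ms, rss = rss, df = df)
  }

  Yw <- if (random_individual) t(.absorb_individuals(t(Y), ind)) else Y
  obs <- stats_for(f, Yw)
  if (obs$df < 1L) stop("no residual degrees of freedom")
  s2 <- obs$rss / obs$df
  s2_shrunk <- if (shrink) shrink_variances(s2, obs$df, G) else s2
  Fs <- obs$ms / s2_shrunk

  perm_fs <- with_seed(seed, {
    out <- matrix(0, G, n_perm)
    idx <- seq_len(n)
    for (b in seq_len(n_perm)) {
      if (scheme == "within_individual") {
        pidx <- stats::ave(idx, ind, FUN = function(ii) ii[sample.int(length(ii))])
        fp <- factor(fvals[pidx], levels = levels(f))
      } else {
        ## permute whole-individual group labels within series
        fp_chr <- fvals
        for (ser in unique(st$series)) {
          iids <- unique(st$individual_id[st$series == ser])
          newmap <- sample(iids)
          names(newmap) <- iids
          sel <- st$series == ser
          donor <- newmap[st$individual_id[sel]]
          fp_chr[sel] <- vapply(seq_len(sum(sel)), function(j) {
            dsel <- st$individual_id == donor[j] &
              st$recovery_time_h == st$recovery_time_h[sel][j]
            fvals[dsel][1L]
          }, character(1))
        }
        fp <- factor(fp_chr, levels = levels(f))
      }
      pb <- stats_for(fp, Yw)
      s2b <- pb$rss / pb$df
      s2b_sh <- if (shrink) shrink_variances(s2b, pb$df, G) else s2b
      out[, b] <- pb$ms / s2b_sh
    }
    out
  })

  if (pooling == "pooled") {
    pool <- sort(as.vector(perm_fs))
    N <- length(pool)
    n_ge <- N - findInterval(Fs, pool, left.open = TRUE)
    p <- (1 + n_ge) / (1 + N)
  } else {
    p <- (1 + rowSums(perm_fs >= Fs)) / (1 + n_perm)
  }

  tab <- data.frame(gene_id = rownames(Y), ms_contrast = obs$ms, s2_raw = s2,
                    s2_shrunk = s2_shrunk, Fs = Fs, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, df_residual = obs$df, contrast = contrast,
                 n_perm = n_perm, excluded_individuals = excluded,
                 permutation_scheme = scheme, pooling = pooling),
            class = "fs_test_result")
}

#' @export
print.fs_test_result <- function(x, ...) {
  cat(sprintf("<fs_test_result> %s vs %s: %d genes, df = %d, %d permutations (%s null)\n",
              x$contrast[1L], x$contrast[2L], nrow(x$table), x$df_residual,
              x$n_perm, x$pooling))
  invisible(x)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion `pi0` from the flat right tail of the
#' p-value histogram -- `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' over a lambda grid, smoothed with a cubic spline and read off at the
#' largest lambda, capped at 1 -- and converts p-values to q-values by
#' step-up monotonization of `pi0 * m * p / rank`.  Forcing `pi0 = 1`
#' reproduces Benjamini-Hochberg exactly.
#'
#' @param p p-values in (0, 1].
#' @param lambda strictly increasing grid in [0, 1).
#' @param pi0 optional override of the estimate (e.g. 1 for BH).
#' @return list of class `qvalue_result`: `pi0`, `lambda`, `pi0_lambda`,
#'   `qvalues` (order of `p`).
#' @export
estimate_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  m <- length(p)
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (is.unsorted(lambda, strictly = TRUE) || any(lambda < 0) || max(lambda) >= 1) {
      stop("lambda grid must be strictly increasing within [0, 1)")
    }
    pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
    if (length(lambda) >= 4L) {
      sp <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
    } else {
      pi0 <- pi0_lambda[length(pi0_lambda)]
    }
    pi0 <- min(1, max(pi0, 1e-8))
  }
  ord <- order(p, decreasing = TRUE)
  qv <- numeric(m)
  rank_desc <- m:1
  running <- Inf
  pi0m <- pi0 * m
  q_sorted <- pmin(pi0m * p[ord] / rank_desc, 1)
  for (i in seq_len(m)) {
    running <- min(running, q_sorted[i])
    qv[ord[i]] <- running
  }
  structure(list(pi0 = pi0, lambda = if (is.null(pi0_lambda)) NULL else lambda,
                 pi0_lambda = pi0_lambda, qvalues = qv),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("<qvalue_result> m = %d, pi0 = %.3f\n", length(x$qvalues), x$pi0))
  invisible(x)
}

#' Scan a list of contrasts for differentially expressed genes
#'
#' Runs [fs_permutation_test()] for each contrast, converts p-values to
#' q-values, and returns the DEG set (q <= threshold) per contrast.
#' All contrasts are validated against the design before any computation.
#'
#' @param matrix expression matrix.
#' @param samples sample table.
#' @param contrasts list of length-2 character vectors of `factor_name`
#'   levels.
#' @param factor_name design factor column (see [fs_permutation_test()]).
#' @param random_individual passed through.
#' @param q_threshold DEG significance cut on the q-value.
#' @param n_perm,seed permutation settings; contrast `k` uses seed
#'   `seed + k - 1` so contrasts are independently reproducible.
#' @param ... passed to [fs_permutation_test()].
#' @return list of class `contrast_scan`: `results` (per contrast:
#'   `fs_test_result` plus `q` column in the table), `deg_sets` (named list
#'   of [gene_set()]s, provenance `DEG`), `q_threshold`.
#' @export
run_contrast_scan <- function(matrix, samples, contrasts, factor_name = "cell",
                              random_individual = TRUE, q_threshold = 0.05,
                              n_perm = 300L, seed = 1L, ...) {
  validate_sample_table(samples)
  lv <- unique(as.character(samples[[factor_name]]))
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% lv)) {
      stop("invalid contrast: ", paste(ct, collapse = " vs "))
    }
  }
  results <- list()
  deg_sets <- list()
  for (k in seq_along(contrasts)) {
    ct <- contrasts[[k]]
    nm <- paste(ct, collapse = "_vs_")
    res <- fs_permutation_test(matrix, samples, factor_name, ct,
                               n_perm = n_perm, seed = seed + k - 1L,
                               random_individual = random_individual, ...)
    qr_ <- estimate_qvalues(res$table$p)
    res$table$q <- qr_$qvalues
    res$pi0 <- qr_$pi0
    results[[nm]] <- res
    deg_sets[[nm]] <- gene_set(nm, res$table$gene_id[res$table$q <= q_threshold],
                               provenance = "DEG", empty_ok = TRUE,
                               description = sprintf("q <= %g in %s", q_threshold, nm))
  }
  structure(list(results = results, deg_sets = deg_sets,
                 q_threshold = q_threshold, factor_name = factor_name,
                 random_individual = random_individual),
            class = "contrast_scan")
}

#' Additive ANOVA decomposition of an expression matrix
#'
#' Decomposes each gene as `Y = mu + individual effect + dose-and-time
#' (cell) effect + error`: cell means are fitted first (cells =
#' group-by-time, kept separate per series), then per-individual constants
#' on the residuals.  Cell effects sum to zero over cells; individual
#' effects sum to zero within each design group (individuals are nested in
#' groups, so their between-group mean is not separable from the cell
#' effects).  Fitted plus residual reproduces `Y` exactly.
#'
#' @param matrix expression matrix.
#' @param samples sample table covering the matrix columns.
#' @return list of class `anova_decomposition`: `mu` (per gene),
#'   `cell_effects` (genes x cells), `individual_effects` (genes x
#'   individuals), `residuals` (genes x samples), `cell_of` / `individual_of`
#'   sample maps.
#' @export
anova_decomposition <- function(matrix, samples) {
  validate_expression_matrix(matrix)
  st <- make_cells(samples)
  st <- st[match(colnames(matrix), st$sample_id), ]
  if (anyNA(st$sample_id)) stop("matrix columns missing from sample table")
  if (length(unique(st$individual_id)) < 2L) stop("need >= 2 individuals")
  if (length(unique(st$cell)) < 2L) stop("need >= 2 design cells")
  grp <- if ("group" %in% colnames(st)) st$group else paste(st$series, st$dose, sep = "_")

  ## every individual must cover every cell of its group
  missing_cells <- character(0)
  for (g in unique(grp)) {
    cells_g <- unique(st$cell[grp == g])
    for (iid in unique(st$individual_id[grp == g])) {
      absent <- setdiff(cells_g, st$cell[st$individual_id == iid])
      if (length(absent)) {
        missing_cells <- c(missing_cells, paste0(iid, ":", absent))
      }
    }
  }
  if (length(missing_cells)) {
    stop("empty design cell(s): ", paste(utils::head(missing_cells, 10), collapse = ", "))
  }

  Y <- matrix
  cellf <- factor(st$cell)
  indf <- factor(st$individual_id)
  n_cell <- as.vector(table(cellf))
  cell_means <- t(rowsum(t(Y), cellf) / n_cell)          # genes x cells
  mu <- rowMeans(cell_means)                             # unweighted over cells
  cell_eff <- cell_means - mu
  resid1 <- Y - cell_means[, as.character(cellf), drop = FALSE]
  n_ind <- as.vector(table(indf))
  ind_eff <- t(rowsum(t(resid1), indf) / n_ind)          # genes x individuals
  residual <- resid1 - ind_eff[, as.character(indf), drop = FALSE]
  structure(list(mu = mu, cell_effects = cell_eff, individual_effects = ind_eff,
                 residuals = residual,
                 cell_of = stats::setNames(as.character(cellf), st$sample_id),
                 individual_of = stats::setNames(as.character(indf), st$sample_id)),
            class = "anova_decomposition")
}

#' Reassemble the fitted matrix from an ANOVA decomposition
#' @param decomp an `anova_decomposition`.
#' @return genes x samples matrix `mu + cell + individual` (no residual).
#' @export
anova_fitted <- function(decomp) {
  stopifnot(inherits(decomp, "anova_decomposition"))
  out <- decomp$mu +
    decomp$cell_effects[, decomp$cell_of, drop = FALSE] +
    decomp$individual_effects[, decomp$individual_of, drop = FALSE]
  colnames(out) <- names(decomp$cell_of)
  out
}
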