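## The four confounder selection rules: biopsy-order relabeling, the
## per-individual fold-change screen, the low-variance tail, the
## handling-stress SD filter, and the individual-effect coefficient rule.

#' Relabel recovery time points as biopsy-order numbers
#'
#' Early series: t0..t5 become b1..b6.  Late series: the biopsy-stress
#' sequence restarts at 7.5 h (the animal is assumed recovered from the t0
#' biopsy by then), so t0 and t7.5 both map to b1, then t9 to b2, t10.5 to
#' b3, t12 to b4.  The alternative scheme `"drop_t0"` leaves the late t0
#' unlabelled (`NA`) instead of doubling b1.
#'
#' @param samples sample table with `series` and `recovery_time_h` set.
#' @param late_scheme `"restart"` (default) or `"drop_t0"`.
#' @return the sample table with `biopsy_order` filled in.
#' @export
relabel_biopsy_order <- function(samples, late_scheme = c("restart", "drop_t0")) {
  late_scheme <- match.arg(late_scheme)
  validate_sample_table(samples)
  bo <- rep(NA_integer_, nrow(samples))
  early <- samples$series == "early"
  bo[early] <- match(samples$recovery_time_h[early], EARLY_TIMES)
  late_map <- c(1L, 1L, 2L, 3L, 4L)
  if (late_scheme == "drop_t0") late_map[1L] <- NA_integer_
  bo[!early] <- late_map[match(samples$recovery_time_h[!early], LATE_TIMES)]
  if (any(early & is.na(bo))) stop("early-series time outside the {0..5} h grid")
  if (anyNA(match(samples$recovery_time_h[!early], LATE_TIMES))) {
    stop("late-series time outside the {0,7.5,9,10.5,12} h grid")
  }
  samples$biopsy_order <- bo
  samples
}

#' Per-individual fold-change range screen
#'
#' For each gene and each individual in the group, the log2 range (max -
#' min over that individual's samples).  A gene passes when the range meets
#' the threshold in \emph{every} individual of the group -- the screen for
#' genes with a >= 2-fold swing between some pair of time points in each
#' animal, the signature of circadian (time-of-day) control.
#'
#' @param matrix expression matrix.
#' @param samples sample table.
#' @param group sample IDs defining the screen group.
#' @param threshold_log2 range threshold (log2 units; 1.0 = 2-fold).
#' @return list of class `fc_screen`: `ranges` (genes x individuals),
#'   `pass` (named logical), `candidates` (gene IDs passing), `threshold`.
#' @export
fc_screen <- function(matrix, samples, group = samples$sample_id,
                      threshold_log2 = 1.0) {
  validate_expression_matrix(matrix)
  validate_sample_table(samples)
  st <- samples[samples$sample_id %in% group, , drop = FALSE]
  if (!nrow(st)) stop("empty screen group")
  missing <- setdiff(st$sample_id, colnames(matrix))
  if (length(missing)) stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  inds <- unique(st$individual_id)
  ranges <- sapply(inds, function(iid) {
    sids <- st$sample_id[st$individual_id == iid]
    if (length(sids) < 2L) stop("individual '", iid, "' has a single sample; range undefined")
    x <- matrix[, sids, drop = FALSE]
    apply(x, 1L, max) - apply(x, 1L, min)
  })
  pass <- rowSums(ranges >= threshold_log2) == length(inds)
  names(pass) <- rownames(matrix)
  structure(list(ranges = ranges, pass = pass,
                 candidates = rownames(matrix)[pass],
                 threshold = threshold_log2),
            class = "fc_screen")
}

#' Low-variance tail of a candidate gene list
#'
#' Keeps the `k` candidates with the lowest SD in `ranking` (ties by gene
#' ID) -- circadian-driven genes change gradually, so among fold-change
#' candidates they sit in the low-variance tail.
#'
#' @param candidates candidate gene IDs (e.g. from [fc_screen()]).
#' @param ranking a `variance_ranking` covering the candidates.
#' @param k tail size, `k <= length(candidates)`.
#' @param name set name.
#' @return [gene_set()] with provenance `TD`.
#' @export
low_variance_tail <- function(candidates, ranking, k, name = "TD_tail") {
  stopifnot(inherits(ranking, "variance_ranking"))
  candidates <- unique(as.character(candidates))
  missing <- setdiff(candidates, ranking$table$gene_id)
  if (length(missing)) stop("candidate(s) not in ranking: ", paste(utils::head(missing, 5), collapse = ", "))
  if (k > length(candidates)) {
    stop("k (", k, ") exceeds the number of candidates (", length(candidates), ")")
  }
  tab <- ranking$table[match(candidates, ranking$table$gene_id), ]
  ord <- order(tab$sd, tab$gene_id)
  gene_set(name, tab$gene_id[ord][seq_len(k)], provenance = "TD",
           description = "low-variance tail of fold-change candidates",
           empty_ok = k == 0L)
}

#' Handling-stress set: low-SD biopsy DEGs
#'
#' Keeps the biopsy-contrast DEGs whose SD over the reference samples is
#' strictly below `sd_threshold`.  Handling/biopsy-stress genes respond to
#' every biopsy alike, so they sit among the DEGs with the lowest overall
#' variation; the filter drops composition- and circadian-driven genes that
#' leak into the biopsy contrasts with much larger swings.
#'
#' @param deg_genes biopsy-contrast DEG gene IDs.
#' @param ranking a `variance_ranking` over the reference samples.
#' @param sd_threshold strict SD cut (default convention 0.32).
#' @param name set name.
#' @return [gene_set()] with provenance `HS` (may be empty).
#' @export
handling_stress_set <- function(deg_genes, ranking, sd_threshold = 0.32,
                                name = "HS_lowvar") {
  stopifnot(inherits(ranking, "variance_ranking"))
  deg_genes <- unique(as.character(deg_genes))
  missing <- setdiff(deg_genes, ranking$table$gene_id)
  if (length(missing)) stop("DEG(s) not in ranking: ", paste(utils::head(missing, 5), collapse = ", "))
  tab <- ranking$table[match(deg_genes, ranking$table$gene_id), ]
  keep <- tab$gene_id[tab$sd < sd_threshold]
  gene_set(name, keep[order(keep)], provenance = "HS",
           description = sprintf("biopsy DEGs with SD < %g", sd_threshold),
           empty_ok = TRUE)
}

#' Individual-effect gene selection
#'
#' Selects genes whose largest absolute per-individual coefficient (the
#' predicted random intercept from the mixed model) exceeds the threshold,
#' then removes genes already claimed by any exclusion set -- the
#' individual-effect group is defined as what the other confounder screens
#' do not explain.
#'
#' @param fits per-gene individual coefficients: either a numeric matrix
#'   (genes x individuals) or a `mixed_model_fits` object.
#' @param coef_threshold coefficient threshold (log2 units).
#' @param exclude list of [gene_set()]s to subtract.
#' @param inclusive if `TRUE` use `>=` instead of the default strict `>`.
#' @param name set name.
#' @return [gene_set()] with provenance `IM` (may be empty).
#' @export
individual_effect_set <- function(fits, coef_threshold = 0.5, exclude = list(),
                                  inclusive = FALSE, name = "IM_set") {
  coefs <- if (inherits(fits, "mixed_model_fits")) fits$individual_coefs else fits
  if (!is.matrix(coefs) || !nrow(coefs)) stop("empty fits: need a genes x individuals coefficient matrix")
  maxabs <- apply(abs(coefs), 1L, max)
  sel <- if (inclusive) maxabs >= coef_threshold else maxabs > coef_threshold
  genes <- rownames(coefs)[sel]
  for (s in exclude) {
    ex <- if (inherits(s, "gene_set")) s$genes else as.character(s)
    genes <- setdiff(genes, ex)
  }
  gene_set(name, genes[order(genes)], provenance = "IM",
           description = sprintf("max |individual coefficient| %s %g, after exclusions",
                                 if (inclusive) ">=" else ">", coef_threshold),
           empty_ok = TRUE)
}
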