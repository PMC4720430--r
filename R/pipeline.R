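## End-to-end orchestration of the confounder scan.  Order matters: the
## individual-effect group is defined as what the sample-composition,
## time-of-day and handling screens do not already explain, so those sets
## are built first.

#' Within-arm contrasts (each time point vs t0) on the design cells
#'
#' @param samples sample table (a `cell` column is added via [make_cells()]).
#' @param groups design groups to scan (default all).
#' @return named list of length-2 character vectors of cell labels.
#' @export
within_arm_contrasts <- function(samples, groups = NULL) {
  st <- make_cells(samples)
  grp <- if ("group" %in% colnames(st)) st$group else paste(st$series, st$dose, sep = "_")
  if (is.null(groups)) groups <- unique(grp)
  out <- list()
  for (g in groups) {
    sel <- grp == g
    times <- sort(unique(st$recovery_time_h[sel]))
    cells <- vapply(times, function(t) unique(st$cell[sel & st$recovery_time_h == t]), character(1))
    t0 <- cells[times == 0]
    for (j in which(times > 0)) {
      out[[paste0(cells[j], "_vs_t0")]] <- c(cells[j], t0)
    }
  }
  out
}

#' Run the full confounder diagnostic scan
#'
#' Executes the four screens on the untreated samples of a
#' repeated-measures expression experiment, in dependency order:
#'
#' 1. variance screen: top-`top_n_variance` genes by SD over untreated
#'    samples, Ward-clustered;
#' 2. sample composition (SC): for each marker seed list, the smallest Ward
#'    cluster containing the seeds, kept when the within/between-individual
#'    coherence signature flags it as composition-driven;
#' 3. time of day (TD): per-individual fold-change screen on the early and
#'    late untreated series, each reduced to its low-variance tail, then
#'    united;
#' 4. handling stress (HS): biopsy-order relabeling, mixed-model Fs
#'    permutation scan of b1 vs b2/b3/b4, FDR cut, then the strict low-SD
#'    filter;
#' 5. individual (IM): per-gene individual coefficients (BLUPs) from the
#'    group-means mixed model, the |coefficient| threshold rule, minus all
#'    genes claimed by SC/TD/HS.
#'
#' @param matrix expression matrix (genes x samples, log2).
#' @param samples sample table covering (at least) the untreated samples.
#' @param config a [pipeline_config()].
#' @param marker_seeds named list of marker seed gene vectors for the SC
#'   stage (e.g. from [composition_marker_seeds()]); may be empty.
#' @param max_cluster_size over-size guard for seeded clusters.
#' @return list of class `confounder_scan`: `sets` (named list of
#'   [gene_set()]s: the flagged `SC_*` sets, `TD`, `HS`, `IM`), `ranking`,
#'   `dendrogram`, `fc_early`, `fc_late`, `biopsy_scan`, `coherence`
#'   (per marker set), `fits` (individual coefficients), `config`.
#' @export
run_confounder_pipeline <- function(matrix, samples, config = pipeline_config(),
                                    marker_seeds = list(),
                                    max_cluster_size = ceiling(0.2 * nrow(matrix))) {
  validate_expression_matrix(matrix)
  validate_sample_table(samples)
  st_u <- samples[!samples$treated, , drop = FALSE]
  st_u <- st_u[st_u$sample_id %in% colnames(matrix), , drop = FALSE]
  if (!nrow(st_u)) stop("no untreated samples available")
  condiag_log("variance screen over ", nrow(st_u), " untreated samples")
  n_top <- min(config$top_n_variance, nrow(matrix))
  ranking <- top_variable_genes(matrix, st_u$sample_id, n = n_top)
  dendro <- ward_cluster(matrix, ranking$top, samples = st_u$sample_id)

  ## --- sample composition ---
  sc_sets <- list()
  coherence <- list()
  for (nm in names(marker_seeds)) {
    seeds <- intersect(marker_seeds[[nm]], dendro$labels)
    if (length(seeds) < 1L) {
      warning("marker set '", nm, "': no seed in the top-variance tree; skipped")
      next
    }
    cl <- extract_seeded_cluster(dendro, seeds, max_size = max_cluster_size,
                                 name = paste0("SC_", nm))
    coh <- profile_coherence(matrix, cl$genes, st_u,
                             within_threshold = config$coherence_within,
                             between_threshold = config$coherence_between)
    coherence[[nm]] <- coh
    if (isTRUE(coh$flag) && !isTRUE(attr(cl, "oversize"))) sc_sets[[cl$name]] <- cl
  }
  condiag_log(length(sc_sets), " composition cluster(s) flagged")

  ## --- time of day ---
  tail_pick <- function(scr, k_cfg) {
    cand <- scr$candidates
    if (!length(cand)) return(character(0))
    k <- if (!is.null(k_cfg)) min(k_cfg, length(cand)) else
      max(1L, ceiling(config$variance_tail_quantile * length(cand)))
    low_variance_tail(cand, ranking, k)$genes
  }
  fc_early <- fc_screen(matrix, st_u, st_u$sample_id[st_u$series == "early"],
                        threshold_log2 = config$fc_threshold_log2)
  fc_late <- fc_screen(matrix, st_u, st_u$sample_id[st_u$series == "late"],
                       threshold_log2 = config$fc_threshold_log2)
  td_genes <- union(tail_pick(fc_early, config$variance_tail_k_early),
                    tail_pick(fc_late, config$variance_tail_k_late))
  td_set <- gene_set("TD", sort(td_genes), provenance = "TD", empty_ok = TRUE,
                     description = "union of early/late low-variance fold-change tails")
  condiag_log("time-of-day set: ", length(td_genes), " genes")

  ## --- handling stress ---
  st_b <- relabel_biopsy_order(st_u, late_scheme = config$late_biopsy_scheme)
  st_b$biopsy_order <- as.character(st_b$biopsy_order)
  biopsy_contrasts <- list(c("1", "2"), c("1", "3"), c("1", "4"))
  biopsy_scan <- run_contrast_scan(matrix, st_b, biopsy_contrasts,
                                   factor_name = "biopsy_order",
                                   random_individual = TRUE,
                                   q_threshold = config$q_threshold,
                                   n_perm = config$n_permutations,
                                   seed = config$rng_seed)
  biopsy_degs <- unique(unlist(lapply(biopsy_scan$deg_sets, function(s) s$genes)))
  hs_set <- handling_stress_set(biopsy_degs, ranking,
                                sd_threshold = config$handling_sd_threshold,
                                name = "HS")
  condiag_log("handling-stress set: ", length(hs_set$genes), " of ",
              length(biopsy_degs), " biopsy DEGs")

  ## --- individual ---
  st_c <- make_cells(st_u)
  fits <- fit_mixed_models(matrix[, st_c$sample_id, drop = FALSE], st_c, fixed = "cell")
  exclude <- c(unname(sc_sets), list(td_set, hs_set))
  im_set <- individual_effect_set(fits, config$individual_coef_threshold,
                                  exclude = exclude,
                                  inclusive = config$individual_coef_inclusive,
                                  name = "IM")
  condiag_log("individual-effect set: ", length(im_set$genes), " genes")

  sets <- c(sc_sets, list(TD = td_set, HS = hs_set, IM = im_set))
  structure(list(sets = sets, ranking = ranking, dendrogram = dendro,
                 fc_early = fc_early, fc_late = fc_late,
                 biopsy_scan = biopsy_scan, coherence = coherence,
                 fits = fits, config = config),
            class = "confounder_scan")
}

#' @export
print.confounder_scan <- function(x, ...) {
  cat("<confounder_scan>\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-12s %5d genes\n", nm, length(x$sets[[nm]]$genes)))
  }
  invisible(x)
}
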