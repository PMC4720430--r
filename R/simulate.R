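## Synthetic-data generator: plants the confounder classes the diagnostics
## are meant to recover, with full ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic repeated-measures experiment.  The design
#' mirrors the wild-type arm of the emulated study: individuals split evenly
#' over four groups (high-dose treated early series, untreated early,
#' low-dose treated late series, untreated late), with 6 biopsies at
#' 0,1,2,3,4,5 h (early) or 5 biopsies at 0,7.5,9,10.5,12 h (late).
#'
#' Planted gene classes and their generative models (log2 scale; `eps ~
#' N(0, sigma_e^2)` everywhere):
#' \describe{
#'   \item{composition}{`log2(sum_c f_cs * 2^(a_gc)) + eps`; mixing of cell
#'     populations is additive in RNA mass, so fractions act on the intensity
#'     scale and are logged afterwards.  Per-sample fractions `f_s` are
#'     Dirichlet draws centred on a per-individual mean composition.}
#'   \item{circadian}{`mu_g + A * sin(2*pi*(t + phase_i)/period) + eps`; the
#'     recovery clock is the day clock (all series start at the same clock
#'     hour), reproducing the recovery-time/time-of-day confounding.}
#'   \item{handling}{`mu_g + slope * (b - 1) + eps` with `b` the effective
#'     biopsy-stress order (the late series restarts at 7.5 h).}
#'   \item{individual}{`mu_g + m_gi + eps`, `m_gi ~ N(0, sigma_m^2)`.}
#'   \item{treatment}{adds `delta * ramp(t)` on treated samples (`ramp`
#'     rises linearly from 0 at t0 to 1 at the last time point; low dose
#'     counts half).}
#'   \item{null}{`mu_g + m_gi + eps` with the small baseline
#'     `sigma_m_null`.}
#' }
#'
#' The baseline per-individual offset (`sigma_m_null`) applies to every
#' class except `individual` (which uses `sigma_m` instead): mouse-to-mouse
#' baseline differences are pervasive across the transcriptome, not a
#' property of one gene class.
#'
#' @param n_genes total genes.
#' @param n_individuals individuals, divisible by 4.
#' @param n_composition,n_circadian,n_handling,n_individual_genes,n_treatment
#'   planted class sizes; the remainder is null.
#' @param n_cell_types cell types driving composition genes (a background
#'   compartment is added internally).
#' @param sigma_e residual noise SD (log2 units).
#' @param sigma_m individual-effect SD for the individual class.
#' @param sigma_m_null baseline individual SD for null genes.
#' @param amplitude circadian amplitude (log2 units).
#' @param phase_sd_h SD of the per-individual circadian phase (hours).
#' @param period_h circadian period (hours).
#' @param handling_slope handling-stress slope (log2 units per biopsy step).
#' @param composition_spread half-separation of a composition gene's log2
#'   level between its own cell type and the rest.
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   around the individual's mean composition (larger = steadier biopsies).
#' @param dirichlet_mean_alpha symmetric Dirichlet parameter for the
#'   per-individual mean composition (1 = maximally spread between mice).
#' @param treatment_effect peak treated-vs-untreated effect (log2 units).
#' @param mu_mean,mu_sd distribution of baseline expression.
#' @param rng_seed integer seed; the generator is bit-reproducible given it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_individuals = 16L,
                              n_composition = 150L, n_circadian = 50L,
                              n_handling = 60L, n_individual_genes = 100L,
                              n_treatment = 100L, n_cell_types = 2L,
                              sigma_e = 0.2, sigma_m = 0.8,
                              sigma_m_null = 0.1, amplitude = 1.5,
                              phase_sd_h = 1.0, period_h = 24,
                              handling_slope = 0.13,
                              composition_spread = 2.0,
                              dirichlet_concentration = 5,
                              dirichlet_mean_alpha = 1.0,
                              treatment_effect = 1.0,
                              mu_mean = 8, mu_sd = 1.5, rng_seed = 1L) {
  cfg <- as.list(environment())
  n_classed <- n_composition + n_circadian + n_handling + n_individual_genes + n_treatment
  if (n_classed > n_genes) stop("class counts (", n_classed, ") exceed n_genes (", n_genes, ")")
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  if (dirichlet_concentration <= 0 || dirichlet_mean_alpha <= 0) {
    stop("Dirichlet parameters must be > 0")
  }
  if (n_individuals %% 4L != 0L || n_individuals < 4L) {
    stop("n_individuals must be a positive multiple of 4 (one per design group)")
  }
  structure(cfg, class = "simulation_config")
}

#' Build the repeated-measures design
#'
#' Splits `n_individuals` evenly over the four design groups and lays out the
#' per-individual biopsy series (6 early / 5 late time points).
#'
#' @param config a [simulation_config()].
#' @return validated sample table (`biopsy_order` unset).
#' @export
build_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_per <- config$n_individuals / 4L
  groups <- data.frame(
    group = c("high", "none_early", "low", "none_late"),
    series = c("early", "early", "late", "late"),
    dose = c("high", "none", "low", "none"),
    stringsAsFactors = FALSE
  )
  recs <- list()
  ind <- 0L
  for (gi in seq_len(nrow(groups))) {
    times <- if (groups$series[gi] == "early") EARLY_TIMES else LATE_TIMES
    for (k in seq_len(n_per)) {
      ind <- ind + 1L
      iid <- sprintf("M%02d", ind)
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sprintf("%s_t%s", iid, fmt_time(times)),
        individual_id = iid,
        series = groups$series[gi],
        recovery_time_h = times,
        dose = groups$dose[gi],
        treated = groups$dose[gi] != "none",
        group = groups$group[gi],
        biopsy_order = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  validate_sample_table(out)
  out
}

# Effective biopsy-stress exposure per sample: sequence position within the
# individual, with the late series restarting at 7.5 h (t0 and t7.5 both
# count as a first biopsy for the stress response).
effective_biopsy_step <- function(samples) {
  step <- integer(nrow(samples))
  early <- samples$series == "early"
  step[early] <- match(samples$recovery_time_h[early], EARLY_TIMES)
  step[!early] <- c(1L, 1L, 2L, 3L, 4L)[match(samples$recovery_time_h[!early], LATE_TIMES)]
  step
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate an expression matrix with planted confounders
#'
#' Generates a log2 expression matrix over `design` with the gene classes of
#' `config` planted, plus the ground truth needed for recovery testing.
#' Per-gene noise is drawn from a counter-based substream keyed on the gene
#' index, so changing a class count never reshuffles other genes' noise.
#'
#' @param config a [simulation_config()].
#' @param design sample table from [build_design()] (or compatible).
#' @return list with elements `matrix` (genes x samples), `truth` (class
#'   `ground_truth`: `classes` named by gene, `params` per-gene parameter
#'   table, `phase_h` per-individual circadian phase, `cell_fractions`
#'   (cell types + background) x samples, `config`).
#' @export
simulate_experiment <- function(config, design = build_design(config)) {
  stopifnot(inherits(config, "simulation_config"))
  validate_sample_table(design)
  n_genes <- config$n_genes
  n_s <- nrow(design)
  inds <- unique(design$individual_id)
  n_i <- length(inds)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))

  classes <- rep("null", n_genes)
  counts <- c(composition = config$n_composition, circadian = config$n_circadian,
              handling = config$n_handling, individual = config$n_individual_genes,
              treatment = config$n_treatment)
  if (sum(counts) > n_genes) stop("class counts exceed n_genes")
  at <- 0L
  for (cl in names(counts)) {
    if (counts[[cl]] > 0L) classes[at + seq_len(counts[[cl]])] <- cl
    at <- at + counts[[cl]]
  }
  names(classes) <- gene_ids

  n_ct <- config$n_cell_types
  ## design-level randomness: phases, per-individual mean composition,
  ## per-sample cell fractions
  design_draw <- with_seed(substream_seed(config$rng_seed, 0L), {
    phase <- stats::rnorm(n_i, 0, config$phase_sd_h)
    names(phase) <- inds
    p_mean <- vapply(seq_len(n_i),
                     function(i) rdirichlet1(rep(config$dirichlet_mean_alpha, n_ct + 1L)),
                     numeric(n_ct + 1L))
    colnames(p_mean) <- inds
    fr <- vapply(seq_len(n_s), function(s) {
      pm <- p_mean[, design$individual_id[s]]
      rdirichlet1(config$dirichlet_concentration * pm + 1e-8)
    }, numeric(n_ct + 1L))
    colnames(fr) <- design$sample_id
    rownames(fr) <- c(sprintf("cell_type_%d", seq_len(n_ct)), "background")
    list(phase = phase, fractions = fr)
  })
  phase <- design_draw$phase
  fractions <- design_draw$fractions

  b_step <- effective_biopsy_step(design)
  t_h <- design$recovery_time_h
  ramp <- ifelse(design$series == "early", t_h / max(EARLY_TIMES),
                 t_h / max(LATE_TIMES))
  dose_scale <- c(none = 0, low = 0.5, high = 1)[design$dose]
  ind_index <- match(design$individual_id, inds)

  mat <- matrix(0, n_genes, n_s, dimnames = list(gene_ids, design$sample_id))
  params <- data.frame(gene_id = gene_ids, class = classes,
                       mu = NA_real_, cell_type = NA_integer_,
                       amplitude = NA_real_, slope = NA_real_,
                       sigma_m = NA_real_, delta = NA_real_,
                       stringsAsFactors = FALSE, row.names = NULL)

  for (g in seq_len(n_genes)) {
    cl <- classes[g]
    res <- with_seed(substream_seed(config$rng_seed, g), {
      mu <- stats::rnorm(1, config$mu_mean, config$mu_sd)
      ## every gene carries a per-individual baseline offset: mouse-to-mouse
      ## differences are pervasive, not confined to one gene class
      m_sd <- if (cl == "individual") config$sigma_m else config$sigma_m_null
      m <- if (m_sd > 0) stats::rnorm(n_i, 0, m_sd) else numeric(n_i)
      eps <- if (config$sigma_e > 0) stats::rnorm(n_s, 0, config$sigma_e) else numeric(n_s)
      base <- if (m_sd > 0) m[ind_index] else 0
      ct <- NA_integer_
      v <- switch(
        cl,
        composition = {
          ct <- ((g - 1L) %% n_ct) + 1L
          a <- rep(mu - config$composition_spread, n_ct + 1L)
          a[ct] <- mu + config$composition_spread
          log2(as.vector(crossprod(fractions, 2^a))) + base
        },
        circadian = mu + base + config$amplitude *
          sin(2 * pi * (t_h + phase[ind_index]) / config$period_h),
        handling = mu + base + config$handling_slope * (b_step - 1),
        individual = mu + base,
        treatment = mu + base +
          config$treatment_effect * ramp * dose_scale * design$treated,
        mu + base  # null
      )
      list(values = v + eps, mu = mu, m_sd = m_sd, cell_type = ct)
    })
    mat[g, ] <- res$values
    params$mu[g] <- res$mu
    params$cell_type[g] <- res$cell_type
    if (cl == "circadian") params$amplitude[g] <- config$amplitude
    if (cl == "handling") params$slope[g] <- config$handling_slope
    if (cl == "treatment") params$delta[g] <- config$treatment_effect
    if (cl %in% c("null", "individual", "treatment")) params$sigma_m[g] <- res$m_sd
  }

  validate_expression_matrix(mat)
  truth <- structure(list(classes = classes, params = params, phase_h = phase,
                          cell_fractions = fractions, config = config),
                     class = "ground_truth")
  list(matrix = mat, truth = truth)
}

#' Ground-truth gene sets by planted class
#'
#' @param truth `ground_truth` object from [simulate_experiment()].
#' @param classes which planted classes to return.
#' @return named list of [gene_set()]s (provenance `truth`).
#' @export
truth_gene_sets <- function(truth,
                            classes = c("composition", "circadian", "handling",
                                        "individual", "treatment", "null")) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- lapply(classes, function(cl) {
    gene_set(paste0("truth_", cl), names(truth$classes)[truth$classes == cl],
             provenance = "truth", empty_ok = TRUE,
             description = paste("planted", cl, "genes"))
  })
  names(out) <- classes
  out
}

#' Marker seed genes for the composition screen
#'
#' Returns, per cell type, the first `n_seeds` planted composition genes of
#' that type -- the synthetic analogue of known cell-type marker genes
#' (hemoglobins, CD3 chains, ...) used to seed cluster extraction.
#'
#' @param truth `ground_truth` object.
#' @param n_seeds seeds per cell type (default 8: a small marker panel).
#' @return named list of character vectors.
#' @export
composition_marker_seeds <- function(truth, n_seeds = 8L) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$params[truth$params$class == "composition", ]
  if (nrow(p) == 0L) return(list())
  sp <- split(p$gene_id, p$cell_type)
  out <- lapply(sp, function(g) utils::head(g, n_seeds))
  names(out) <- paste0("cell_type_", names(sp))
  out
}
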