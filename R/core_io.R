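## Domain types and file I/O.
##
## An expression matrix is a plain numeric matrix (genes x samples, log2
## units) with unique, non-empty dimnames; a sample table is a data.frame
## with one row per sample.  Validators enforce the domain invariants so the
## rest of the package can assume them.

EARLY_TIMES <- c(0, 1, 2, 3, 4, 5)
LATE_TIMES <- c(0, 7.5, 9, 10.5, 12)

# "7.5" -> "7p5": time labels safe for IDs, formatted element-wise.
fmt_time <- function(t) sub("\\.", "p", vapply(t, format, character(1)))

#' Validate an expression matrix
#'
#' Checks that `x` is a numeric matrix with unique gene (row) and sample
#' (column) IDs and only finite values.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have gene row names and sample column names")
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample IDs and the gene
#' ID in the first column.  Decimal separator is `.`; no quoting.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples, row/column order as in the file.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2L) stop("expression file has no data rows: ", path)
  if (length(unique(nf)) != 1L) {
    stop(sprintf("ragged rows in '%s': row %d has %d fields, expected %d",
                 path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene-ID column plus sample columns")
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), sample '%s'",
                 vals[bad[1L], bad[2L]], gene_ids[bad[1L]], bad[1L],
                 sample_ids[bad[2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix, genes x samples.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Enforces the design-domain invariants: unique sample IDs; `series` in
#' `early`/`late`; early recovery times in \{0..5\} h and late times in
#' \{0, 7.5, 9, 10.5, 12\} h; `dose` in `none`/`low`/`high`; each individual
#' in exactly one series and one dose arm; `biopsy_order`, when set, in 1..6.
#'
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `series`, `recovery_time_h`, `dose`, `treated` and optionally
#'   `biopsy_order`.
#' @return `samples`, invisibly, if valid.
#' @export
validate_sample_table <- function(samples) {
  req <- c("sample_id", "individual_id", "series", "recovery_time_h", "dose", "treated")
  miss <- setdiff(req, colnames(samples))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) == 0L) stop("no records in sample table")
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (!all(samples$series %in% c("early", "late"))) {
    stop("series must be 'early' or 'late'")
  }
  if (!all(samples$dose %in% c("none", "low", "high"))) {
    stop("dose must be 'none', 'low' or 'high'")
  }
  if (!is.logical(samples$treated)) stop("treated must be logical")
  bad <- samples$series == "early" & !samples$recovery_time_h %in% EARLY_TIMES
  if (any(bad)) {
    stop("early-series recovery time(s) outside {0..5} h for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "))
  }
  bad <- samples$series == "late" & !samples$recovery_time_h %in% LATE_TIMES
  if (any(bad)) {
    stop("late-series recovery time(s) outside {0,7.5,9,10.5,12} h for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "))
  }
  per_ind <- split(samples, samples$individual_id)
  for (tab in per_ind) {
    if (length(unique(tab$series)) > 1L) {
      stop("individual '", tab$individual_id[1L], "' appears in more than one series")
    }
    if (length(unique(tab$dose)) > 1L) {
      stop("individual '", tab$individual_id[1L], "' appears in more than one dose arm")
    }
  }
  if ("biopsy_order" %in% colnames(samples)) {
    bo <- samples$biopsy_order
    if (!all(is.na(bo) | (bo %in% 1:6))) stop("biopsy_order must be in 1..6 when set")
  }
  invisible(samples)
}

#' Read a sample metadata table from TSV
#'
#' Required columns: `sample_id`, `individual_id`, `series`,
#' `recovery_time_h`, `dose`, `treated`.  Any extra columns (e.g. a genotype
#' column) are carried along but ignored by all computations.
#' `biopsy_order` is left unset; assign it with [relabel_biopsy_order()].
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in sample table: ", path)
  if ("treated" %in% colnames(df)) {
    df$treated <- df$treated %in% c("TRUE", "True", "true", "1", TRUE)
  }
  if ("recovery_time_h" %in% colnames(df)) {
    df$recovery_time_h <- as.numeric(df$recovery_time_h)
  }
  if (!"biopsy_order" %in% colnames(df)) df$biopsy_order <- NA_integer_
  validate_sample_table(df)
  df
}

#' Write a sample table to TSV
#' @param samples validated sample table.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' A gene set is a named collection of gene IDs with a provenance label
#' recording which screen produced it (`SC` sample composition, `TD` time of
#' day, `HS` handling stress, `IM` individual, `DEG` differential expression,
#' `truth` planted ground truth, `other`).
#'
#' @param name set name.
#' @param genes character vector of gene IDs (de-duplicated, order kept).
#' @param provenance one of `SC`, `TD`, `HS`, `IM`, `DEG`, `truth`, `other`.
#' @param description free-text description.
#' @param empty_ok allow an empty set.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, provenance = "other", description = "",
                     empty_ok = FALSE) {
  provenance <- match.arg(provenance, c("SC", "TD", "HS", "IM", "DEG", "truth", "other"))
  genes <- unique(as.character(genes))
  if (!length(genes) && !empty_ok) {
    stop("gene set '", name, "' is empty (pass empty_ok = TRUE to allow)")
  }
  structure(list(name = name, provenance = provenance, genes = genes,
                 description = description, empty_ok = empty_ok),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s] %d gene(s)\n", x$name, x$provenance,
              length(x$genes)))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then one gene per field, all
#' tab-separated, UTF-8, newline-terminated.
#'
#' @param sets list of [gene_set()] objects (a single set is accepted).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    if (!length(s$genes) && !isTRUE(s$empty_ok)) {
      stop("gene set '", s$name, "' is empty and not flagged empty-allowed")
    }
    desc <- if (nzchar(s$description)) s$description else s$provenance
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read gene sets from GMT format
#'
#' @param path file path.
#' @param provenance provenance label to stamp on the sets read.
#' @return list of [gene_set()] objects, in file order.
#' @export
read_gene_sets <- function(path, provenance = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", substr(ln, 1, 60))
    gene_set(f[1L], f[-(1:2)], provenance = provenance, description = f[2L],
             empty_ok = TRUE)
  })
}

#' Default pipeline configuration
#'
#' Holds the screen thresholds: `top_n_variance` genes kept in the variance
#' screen; `fc_threshold_log2` for the per-individual fold-change range;
#' `handling_sd_threshold` for the low-SD filter on biopsy DEGs;
#' `individual_coef_threshold` for the |individual coefficient| rule;
#' `q_threshold` for FDR significance; `n_permutations` and `rng_seed` for the
#' permutation test; `variance_tail_quantile` (or explicit
#' `variance_tail_k_early`/`_late`) for the low-variance tail; coherence flag
#' thresholds `coherence_within` / `coherence_between`.
#'
#' @param ... overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    top_n_variance = 5000L,
    fc_threshold_log2 = 1.0,
    handling_sd_threshold = 0.32,
    individual_coef_threshold = 0.5,
    individual_coef_inclusive = FALSE,
    q_threshold = 0.05,
    n_permutations = 300L,
    rng_seed = 1L,
    variance_tail_k_early = NULL,
    variance_tail_k_late = NULL,
    variance_tail_quantile = 0.75,
    coherence_within = 0.8,
    coherence_between = 0.3,
    late_biopsy_scheme = "restart"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("top_n_variance", "fc_threshold_log2", "handling_sd_threshold",
           "individual_coef_threshold", "q_threshold", "n_permutations")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop("config field '", f, "' must be non-negative")
  }
  if (cfg$fc_threshold_log2 <= 0 || cfg$handling_sd_threshold <= 0 ||
      cfg$individual_coef_threshold <= 0) {
    stop("thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds flat key/value pairs mirroring [pipeline_config()].
#'
#' @param path YAML file path.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
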