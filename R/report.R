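## Overlap accounting between DEG sets and confounder sets, hypergeometric
## over-representation, DEG count tables, and ground-truth recovery metrics.

.as_genes <- function(s) if (inherits(s, "gene_set")) s$genes else unique(as.character(s))

#' Overlap table between DEG sets and confounder sets
#'
#' One row per contrast, one column per confounder set plus an `All` column
#' for their union; cells are the percentage of the contrast's DEGs present
#' in the set (exact values; see [format_overlap_table()] for the rounded
#' display with the `-` convention for empty DEG rows).
#'
#' @param deg_sets named list of DEG [gene_set()]s (per contrast).
#' @param confounder_sets list of confounder [gene_set()]s.
#' @return list of class `overlap_table`: `percent` (contrasts x sets,
#'   exact), `deg_counts`, `set_sizes`.
#' @export
overlap_table <- function(deg_sets, confounder_sets) {
  set_names <- vapply(confounder_sets, function(s) s$name, character(1))
  union_all <- unique(unlist(lapply(confounder_sets, .as_genes)))
  pct <- matrix(NA_real_, length(deg_sets), length(confounder_sets) + 1L,
                dimnames = list(names(deg_sets), c(set_names, "All")))
  counts <- integer(length(deg_sets))
  for (i in seq_along(deg_sets)) {
    dg <- .as_genes(deg_sets[[i]])
    counts[i] <- length(dg)
    if (!length(dg)) next
    for (j in seq_along(confounder_sets)) {
      pct[i, j] <- 100 * length(intersect(dg, .as_genes(confounder_sets[[j]]))) / length(dg)
    }
    pct[i, length(confounder_sets) + 1L] <- 100 * length(intersect(dg, union_all)) / length(dg)
  }
  structure(list(percent = pct, deg_counts = stats::setNames(counts, names(deg_sets)),
                 set_sizes = stats::setNames(
                   vapply(confounder_sets, function(s) length(.as_genes(s)), integer(1)),
                   set_names)),
            class = "overlap_table")
}

#' Render an overlap table for display
#'
#' Percentages rounded half-up to integers; rows with zero DEGs shown as
#' `-`.
#'
#' @param x an `overlap_table`.
#' @return character matrix with a leading DEG-count column.
#' @export
format_overlap_table <- function(x) {
  stopifnot(inherits(x, "overlap_table"))
  out <- cbind(`#DEG` = as.character(x$deg_counts),
               apply(x$percent, 2L, function(col) {
                 ifelse(is.na(col), "-", as.character(round_half_up(col)))
               }))
  rownames(out) <- rownames(x$percent)
  out
}

#' @export
print.overlap_table <- function(x, ...) {
  print(format_overlap_table(x), quote = FALSE)
  invisible(x)
}

#' Hypergeometric over-representation probability
#'
#' Upper-tail probability `P(X >= k)` of the overlap `k` between a DEG set
#' (draw of size `n`) and a confounder set (`K` successes) against a
#' background of `background_size` genes; exact, computed in log space via
#' the hypergeometric distribution.
#'
#' @param deg DEG [gene_set()] or gene ID vector.
#' @param set confounder [gene_set()] or gene ID vector.
#' @param background_size number of genes on the array/background.
#' @return upper-tail probability (numeric scalar).
#' @export
hypergeometric_ora <- function(deg, set, background_size) {
  dg <- .as_genes(deg)
  sg <- .as_genes(set)
  n <- length(dg); K <- length(sg)
  if (n > background_size || K > background_size) {
    stop("set sizes exceed the background")
  }
  k <- length(intersect(dg, sg))
  if (k > min(n, K)) stop("internal error: overlap exceeds min(|deg|, |set|)")
  if (k == 0L) return(1)
  stats::phyper(k - 1L, K, background_size - K, n, lower.tail = FALSE)
}

#' DEG count table for paired scans with and without the individual term
#'
#' @param scan_with,scan_without `contrast_scan` objects over identical
#'   contrasts (with / without the individual random term).
#' @return data.frame: contrast, `n_with`, `n_without`.
#' @export
deg_count_table <- function(scan_with, scan_without) {
  stopifnot(inherits(scan_with, "contrast_scan"), inherits(scan_without, "contrast_scan"))
  if (!identical(names(scan_with$deg_sets), names(scan_without$deg_sets))) {
    stop("the two scans cover different contrasts")
  }
  data.frame(
    contrast = names(scan_with$deg_sets),
    n_with = vapply(scan_with$deg_sets, function(s) length(s$genes), integer(1)),
    n_without = vapply(scan_without$deg_sets, function(s) length(s$genes), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Recovery metrics of called gene sets against planted ground truth
#'
#' @param called named list: planted class -> called [gene_set()] (or gene
#'   vector).  Classes without a called set get recall 0 and precision `NA`.
#' @param truth `ground_truth` from [simulate_experiment()].
#' @return data.frame: class, n_truth, n_called, n_hit, precision, recall,
#'   f1.
#' @export
recovery_metrics <- function(called, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  known <- unique(truth$classes)
  bad <- setdiff(names(called), known)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  classes <- setdiff(known, "null")
  rows <- lapply(classes, function(cl) {
    truth_genes <- names(truth$classes)[truth$classes == cl]
    cg <- if (cl %in% names(called)) .as_genes(called[[cl]]) else character(0)
    hit <- length(intersect(cg, truth_genes))
    prec <- if (length(cg)) hit / length(cg) else NA_real_
    rec <- if (length(truth_genes)) hit / length(truth_genes) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) 2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = cl, n_truth = length(truth_genes), n_called = length(cg),
               n_hit = hit, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' False-positive rate of a called set among planted null genes
#'
#' @param called [gene_set()] or gene vector.
#' @param truth `ground_truth`.
#' @return fraction of null genes present in `called`.
#' @export
null_call_rate <- function(called, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  nulls <- names(truth$classes)[truth$classes == "null"]
  if (!length(nulls)) return(NA_real_)
  length(intersect(.as_genes(called), nulls)) / length(nulls)
}
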