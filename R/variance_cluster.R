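## Variance screening, Ward clustering with deterministic leaf ordering,
## seeded cluster extraction, and PCA gene-subset discovery.

#' Rank genes by standard deviation over a sample subset
#'
#' SD uses denominator n-1 and is computed over exactly the given samples.
#' Ranking ties are broken by gene ID (lexicographic), so rank 1 is the most
#' variable gene and the ranking is bit-reproducible.
#'
#' @param matrix expression matrix (genes x samples).
#' @param samples sample IDs to compute over (>= 2).
#' @param n size of the top cut.
#' @return list of class `variance_ranking`: `table` (gene_id, sd, rank, in
#'   file order), `top` (top-n gene IDs by rank), `samples`, `n`.
#' @export
top_variable_genes <- function(matrix, samples = colnames(matrix), n) {
  validate_expression_matrix(matrix)
  missing <- setdiff(samples, colnames(matrix))
  if (length(missing)) stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(samples) < 2L) stop("need at least 2 samples for an SD")
  if (n < 1L || n > nrow(matrix)) {
    stop("n must be between 1 and the number of genes (", nrow(matrix), ")")
  }
  sds <- row_sds(matrix[, samples, drop = FALSE])
  ord <- order(-sds, rownames(matrix))
  rank <- integer(length(sds))
  rank[ord] <- seq_along(ord)
  tab <- data.frame(gene_id = rownames(matrix), sd = sds, rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, top = tab$gene_id[ord][seq_len(n)],
                 samples = samples, n = n),
            class = "variance_ranking")
}

#' @export
print.variance_ranking <- function(x, ...) {
  cat(sprintf("<variance_ranking> %d genes over %d samples; top cut n = %d\n",
              nrow(x$table), length(x$samples), x$n))
  invisible(x)
}

# Deterministic leaf order: at every internal node the child whose member
# genes have the smaller mean (unscaled) expression comes first.
.order_by_child_mean <- function(merge, gene_means) {
  n <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  order_of <- vector("list", nrow(merge))
  node_members <- function(k) if (k < 0) -k else members[[k]]
  node_order <- function(k) if (k < 0) -k else order_of[[k]]
  for (i in seq_len(nrow(merge))) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    ma <- node_members(a); mb <- node_members(b)
    members[[i]] <- c(ma, mb)
    if (mean(gene_means[ma]) <= mean(gene_means[mb])) {
      order_of[[i]] <- c(node_order(a), node_order(b))
    } else {
      order_of[[i]] <- c(node_order(b), node_order(a))
    }
  }
  order_of[[nrow(merge)]]
}

#' Ward clustering of gene profiles
#'
#' Genes are row-scaled (mean 0, SD 1: the comparison is between profile
#' shapes), then clustered by Ward's minimum-variance method on Euclidean
#' distances.  Merge heights are reported as the increase in within-cluster
#' sum of squares (delta-ESS).  Leaf order is deterministic: at every node
#' the child with the smaller mean expression (average of its genes' raw
#' means) is placed first.
#'
#' @param matrix expression matrix.
#' @param genes genes to cluster (>= 2); must exist in `matrix`.
#' @param samples sample IDs to cluster over (default all).
#' @param scale row-scale profiles before clustering (default); turn off to
#'   cluster raw values.
#' @return list of class `gene_dendrogram`: `hclust` (heights in delta-ESS
#'   units), `labels`, `order` (leaf order as gene IDs), `heights`.
#' @export
ward_cluster <- function(matrix, genes, samples = colnames(matrix), scale = TRUE) {
  validate_expression_matrix(matrix)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < 2L) stop("need at least 2 genes to cluster")
  x <- matrix[genes, samples, drop = FALSE]
  if (scale) {
    xs <- scale_rows(x)
    if (length(attr(xs, "zero_sd"))) {
      warning(length(attr(xs, "zero_sd")), " constant gene profile(s) scaled to zero")
    }
  } else {
    xs <- x
  }
  hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
  hc$height <- hc$height^2 / 2  # ward.D2 reports sqrt(2 * delta-ESS)
  leaf_idx <- .order_by_child_mean(hc$merge, rowMeans(x))
  hc$order <- leaf_idx
  structure(list(hclust = hc, labels = hc$labels,
                 order = hc$labels[leaf_idx], heights = hc$height),
            class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("<gene_dendrogram> %d genes, %d merges (Ward, delta-ESS heights)\n",
              length(x$labels), length(x$heights)))
  invisible(x)
}

#' Extract the smallest cluster containing a set of seed genes
#'
#' Returns the member set of the lowest dendrogram node containing all
#' seeds (for a single seed: the smallest non-leaf node containing it).
#' If that node is larger than `max_size` it is still returned, flagged
#' over-size via the `oversize` attribute.
#'
#' @param dendro `gene_dendrogram` from [ward_cluster()].
#' @param seeds seed gene IDs; all must be leaves of the tree.
#' @param max_size size above which the result is flagged over-size.
#' @param name,provenance passed to [gene_set()].
#' @return [gene_set()] with attribute `oversize` (logical).
#' @export
extract_seeded_cluster <- function(dendro, seeds, max_size = Inf,
                                   name = "seeded_cluster", provenance = "SC") {
  stopifnot(inherits(dendro, "gene_dendrogram"))
  labels <- dendro$labels
  missing <- setdiff(seeds, labels)
  if (length(missing)) stop("seed(s) not in tree: ", paste(missing, collapse = ", "))
  merge <- dendro$hclust$merge
  members <- vector("list", nrow(merge))
  node_members <- function(k) if (k < 0) labels[-k] else members[[k]]
  best <- NULL
  for (i in seq_len(nrow(merge))) {
    members[[i]] <- c(node_members(merge[i, 1L]), node_members(merge[i, 2L]))
    if (all(seeds %in% members[[i]])) { best <- members[[i]]; break }
  }
  if (is.null(best)) best <- labels  # forced root (defensive; last merge is root)
  out <- gene_set(name, best, provenance = provenance,
                  description = paste0("lowest Ward node containing seeds: ",
                                       paste(seeds, collapse = ",")))
  attr(out, "oversize") <- length(best) > max_size
  out
}

#' PCA-based gene subset discovery
#'
#' PCA with genes as observations and samples as variables; each sample
#' column is centred over the genes analysed.  Component signs are fixed by
#' forcing the largest-magnitude loading of each component positive, so
#' scores are reproducible.  Subsets are cut out of the (PC1, PC2) score
#' plane by explicit threshold clauses, replacing manual gating on the plot.
#'
#' @param matrix expression matrix.
#' @param genes genes to analyse (>= 3).
#' @param rule list of clauses; each clause is a list with `name` and any of
#'   `pc1_min`, `pc1_max`, `pc2_min`, `pc2_max` (defaults -Inf/Inf).
#' @param samples sample IDs to use (default all).
#' @return list with `sets` (one [gene_set()] per clause, provenance `SC`),
#'   `scores` (genes x 2), `var_explained` (per component, all PCs).
#' @export
pca_gene_subsets <- function(matrix, genes, rule, samples = colnames(matrix)) {
  validate_expression_matrix(matrix)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < 3L) stop("need at least 3 genes for PCA")
  x <- matrix[genes, samples, drop = FALSE]
  if (all(row_sds(t(x)) == 0) || all(row_sds(x) == 0)) {
    stop("no principal structure: all gene profiles identical")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(min(2L, ncol(pc$rotation)))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  if (ncol(pc$x) < 2L) stop("no principal structure: rank < 2")
  scores <- pc$x[, 1:2, drop = FALSE]
  sets <- lapply(rule, function(cl) {
    keep <- scores[, 1L] >= (cl$pc1_min %||% -Inf) &
            scores[, 1L] <= (cl$pc1_max %||% Inf) &
            scores[, 2L] >= (cl$pc2_min %||% -Inf) &
            scores[, 2L] <= (cl$pc2_max %||% Inf)
    gene_set(cl$name %||% "pca_subset", rownames(scores)[keep],
             provenance = "SC", empty_ok = TRUE,
             description = "PCA score-threshold subset")
  })
  list(sets = sets, scores = scores,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
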