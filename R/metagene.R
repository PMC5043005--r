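## Metagene scores: one scalar per gene set and sample group, the mean scaled
## expression of the set's genes. Used to compare culture systems and disease
## models on a common axis.

#' Metagene scores of gene sets across sample groups
#'
#' Per gene, expression is scaled (see `scaling`), replicates within each
#' group are averaged first, and the group means are then averaged across the
#' set's genes. Dispersion is the SD across genes of those per-gene group
#' means.
#'
#' @param x an `expr_matrix`.
#' @param sets a [gene_set_collection()] (the universe is ignored here); set
#'   members absent from the matrix are dropped and counted, a set with no
#'   present member is an error.
#' @param groups named list of character vectors of sample IDs, or NULL to
#'   use every (condition, day) combination present (named
#'   `"<condition>|<day>"`).
#' @param scaling `"reference_anchored"`: per gene
#'   `(value - mean_ref) / SD_ref` using the reference-group samples, so the
#'   reference group scores 0 and scores read as deviation from fresh cells;
#'   `"global_z"`: per-gene z-score across all samples.
#' @param reference_condition condition label anchoring the
#'   `reference_anchored` mode (default `"FH"`).
#' @param sd_floor variance guard for constant genes.
#' @return data.frame: set, group, score, n_genes, n_missing, dispersion.
#' @export
metagene_scores <- function(x, sets, groups = NULL,
                            scaling = c("reference_anchored", "global_z"),
                            reference_condition = "FH", sd_floor = 1e-8) {
  stopifnot(inherits(x, "expr_matrix"))
  scaling <- match.arg(scaling)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.null(groups)) {
    ann <- x$samples
    key <- paste(ann$condition, ann$day, sep = "|")
    groups <- split(ann$sample_id, key)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")

  m <- x$values
  if (scaling == "reference_anchored") {
    ref_ids <- samples_where(x, condition = reference_condition)
    if (length(ref_ids) < 2)
      stop("reference_anchored scaling needs >= 2 reference samples")
    mu <- rowMeans(m[, ref_ids, drop = FALSE])
    sdv <- pmax(apply(m[, ref_ids, drop = FALSE], 1, stats::sd), sd_floor)
  } else {
    mu <- rowMeans(m)
    sdv <- pmax(apply(m, 1, stats::sd), sd_floor)
  }
  scaled <- (m - mu) / sdv

  rows <- list()
  for (set_name in names(sets)) {
    members <- intersect(sets[[set_name]], rownames(m))
    n_missing <- length(sets[[set_name]]) - length(members)
    if (!length(members))
      stop("set '", set_name, "' has no members present in the matrix")
    for (grp in names(groups)) {
      ids <- groups[[grp]]
      if (!length(ids)) next
      gene_means <- rowMeans(scaled[members, ids, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, group = grp,
        score = mean(gene_means),
        n_genes = length(members),
        n_missing = n_missing,
        dispersion = if (length(members) > 1) stats::sd(gene_means)
                     else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top deregulated genes of a cluster at an anchor contrast
#'
#' Selects the `k` cluster genes with largest |log2FC| in the given DEG
#' table (by default the day-1 confluent-monolayer contrast), the gene set
#' feeding a cluster metagene.
#'
#' @param deg a `deg_table` for the anchor contrast.
#' @param cluster_genes character vector of the cluster's gene IDs.
#' @param k number of genes (default 10).
#' @return Character vector of at most `k` gene IDs, strongest first; all
#'   cluster genes (with a warning) when fewer than `k` are present.
#' @export
top_cluster_metagene <- function(deg, cluster_genes, k = 10) {
  stopifnot(inherits(deg, "deg_table"))
  if (k < 1) stop("k must be >= 1")
  tab <- deg$table[deg$table$gene %in% cluster_genes, , drop = FALSE]
  if (nrow(tab) < length(cluster_genes))
    warning(length(cluster_genes) - nrow(tab),
            " cluster genes missing from the DEG table", call. = FALSE)
  if (nrow(tab) < k)
    warning(sprintf("cluster has only %d genes (k = %d)", nrow(tab), k),
            call. = FALSE)
  tab <- tab[order(-abs(tab$log2fc), tab$gene), , drop = FALSE]
  utils::head(tab$gene, k)
}

#' Culture/disease sample groups of an annotated matrix
#'
#' Convenience grouping used by the metagene CLI: one group per culture
#' (condition, day) and one per disease condition, plus the reference.
#'
#' @param x an `expr_matrix`.
#' @return Named list of sample-ID vectors.
#' @export
standard_groups <- function(x) {
  ann <- x$samples
  key <- ifelse(ann$model_type == "in_vivo", ann$condition,
                paste(ann$condition, ann$day, sep = "|"))
  split(ann$sample_id, key)
}
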