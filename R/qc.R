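## Sample-level quality control: high-variance gene selection, gene-centered
## PCA, and outlier flagging by replicate correlation and PCA distance.

#' Select the k genes with highest variance
#'
#' Variance is computed per gene across all samples of `x`. Ties are broken
#' by input (row) order, so a constant matrix returns the first `k` genes.
#'
#' @param x an `expr_matrix`.
#' @param k number of genes to keep (`k <= nrow`).
#' @return Character vector of `k` gene IDs, ordered by decreasing variance.
#' @export
select_high_variance_genes <- function(x, k) {
  stopifnot(inherits(x, "expr_matrix"))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(x$values)) stop("k exceeds the number of genes")
  v <- apply(x$values, 1, stats::var)
  ord <- order(-v)                      # order() is stable: ties keep input order
  rownames(x$values)[ord[seq_len(k)]]
}

#' Gene-centered principal component analysis of samples
#'
#' Rows (genes) are mean-centered, no variance scaling; samples are the
#' observations. Component signs follow the convention that the loading with
#' the largest absolute value is positive, making orientations reproducible.
#'
#' @param x an `expr_matrix`.
#' @param genes gene IDs to use (typically from
#'   [select_high_variance_genes()]); NULL uses all genes.
#' @param n_components number of components to return.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings` (genes x components) and `variance_fraction` (per component,
#'   non-increasing, sums to <= 1).
#' @export
pca_expression <- function(x, genes = NULL, n_components = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2) stop("PCA needs at least two samples")
  if (n_components > min(dim(m)))
    stop("n_components exceeds matrix rank bound")
  centered <- m - rowMeans(m)
  ## samples as rows for the SVD; prcomp would center per column (per gene
  ## across samples is what we want, hence the manual row centering above)
  sv <- svd(t(centered), nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2
  dimnames(scores) <- list(colnames(m),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(rownames(m),
                             paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ev[seq_len(n_components)] / sum(ev)),
            class = "pca_result")
}

#' Flag outlier samples within replicate groups
#'
#' A sample is flagged when, within its annotation group
#' (condition x day x species), either (a) its mean Pearson correlation to
#' the other group members falls more than `z_threshold` SDs below the
#' leave-one-out group mean of that statistic, or (b) its distance from the
#' leave-one-out group centroid in the top-2 PCA plane is more than
#' `z_threshold` SDs above the expected within-group distance. Both criteria
#' are leave-one-out because with typical replicate groups (n = 3-4) a
#' z-score that includes the candidate itself is bounded by
#' (n-1)/sqrt(n) < 2 and could never fire. Groups with fewer than 3 samples
#' are skipped with a warning.
#'
#' Two calibration details keep the false-flag rate low on clean data: the
#' correlation gap must exceed `min_cor_gap` (an absolute drop in mean
#' replicate correlation, guarding against noise-level z inflation when the
#' 2-3 reference values happen to be very tight), and the PCA distances are
#' standardized with the chi distribution appropriate for a 2-D Euclidean
#' norm — per-sample distances are corrected for the leave-one-out
#' inflation sqrt(n/(n-1)), the noise scale is estimated robustly from the
#' pooled dataset median (replicate noise assumed homoscedastic across
#' groups), and `z_threshold` is mapped to its normal upper-tail probability
#' and applied as the exact chi-squared(2) quantile, so "3 SDs" keeps its
#' usual per-sample false-positive meaning on a distance scale.
#'
#' @param x an `expr_matrix`.
#' @param z_threshold z-score cutoff (default 3).
#' @param top_genes number of high-variance genes feeding the PCA criterion.
#' @param min_cor_gap minimal absolute drop in mean replicate correlation for
#'   the correlation criterion to fire.
#' @return Character vector of flagged sample IDs (possibly empty).
#' @export
flag_outlier_samples <- function(x, z_threshold = 3, top_genes = 1000,
                                 min_cor_gap = 0.01) {
  stopifnot(inherits(x, "expr_matrix"))
  ann <- x$samples
  grp <- interaction(ann$condition, ann$day, ann$species, drop = TRUE)
  k <- min(top_genes, nrow(x$values))
  pc <- pca_expression(x, select_high_variance_genes(x, k), n_components = 2)
  stats_rows <- list()
  for (g in levels(grp)) {
    ids <- ann$sample_id[grp == g]
    n <- length(ids)
    if (n < 3) {
      warning("group ", g, " has fewer than 3 samples; skipped", call. = FALSE)
      next
    }
    sub <- x$values[, ids, drop = FALSE]
    cm <- suppressWarnings(stats::cor(sub))
    cm[!is.finite(cm)] <- 1           # constant replicates correlate perfectly
    mean_cor <- (colSums(cm) - 1) / (n - 1)
    sc <- pc$scores[ids, , drop = FALSE]
    for (i in seq_len(n)) {
      others <- mean_cor[-i]
      rest <- sc[-i, , drop = FALSE]
      centroid <- colMeans(rest)
      stats_rows[[ids[i]]] <- data.frame(
        sample_id = ids[i],
        cor_gap = mean(others) - mean_cor[i],
        cor_sd = stats::sd(others),
        # leave-one-out distance, corrected for its sqrt(n/(n-1)) inflation
        d = sqrt(sum((sc[i, ] - centroid)^2)) / sqrt(n / (n - 1)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(stats_rows)) return(character(0))
  st <- do.call(rbind, stats_rows)
  cor_hit <- st$cor_gap > min_cor_gap &
    ifelse(st$cor_sd > 1e-12, st$cor_gap / st$cor_sd > z_threshold, TRUE)
  ## chi(2) calibration: for a 2-D Gaussian with component SD sigma the
  ## distance has median sigma * sqrt(qchisq(0.5, 2)) = 1.177 sigma; the z
  ## cutoff is translated to the matching chi-squared quantile
  sigma <- stats::median(st$d) / 1.177
  d_cut <- sigma * sqrt(stats::qchisq(stats::pnorm(z_threshold), df = 2))
  pca_hit <- if (sigma > 1e-12) st$d > d_cut else st$d > 1e-8
  st$sample_id[cor_hit | pca_hit]
}
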