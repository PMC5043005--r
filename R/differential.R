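## Differential expression against the fresh-hepatocyte reference.
## Per-gene Welch two-sample t test on log2 values, Benjamini-Hochberg FDR
## within each contrast, and a two-part significance gate: adjusted p < alpha
## AND fold change of at least `fc_threshold` (|log2FC| >= log2(threshold)).

#' Define a contrast against the reference group
#'
#' @param condition condition label of the test group.
#' @param day cultivation day of the test group; NA matches any day (used for
#'   disease conditions that carry a nominal day).
#' @param reference reference condition label (default `"FH"`, the freshly
#'   isolated hepatocytes at day 0).
#' @return A `contrast_spec` list with a printable `label`.
#' @export
contrast_spec <- function(condition, day = NA, reference = "FH") {
  if (condition == reference) stop("condition must differ from the reference")
  structure(list(condition = condition, day = day, reference = reference,
                 label = sprintf("%s vs %s day %s", condition, reference,
                                 format(day))),
            class = "contrast_spec")
}

## Vectorized Welch t test on a genes x samples matrix split into two groups.
welch_rows <- function(m1, m2, var_floor = 1e-8) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- pmax(rowSums((m1 - mu1)^2) / (n1 - 1), var_floor)
  v2 <- pmax(rowSums((m2 - mu2)^2) / (n2 - 1), var_floor)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(log2fc = mu1 - mu2, t = tstat, df = df, p = p)
}

#' Call differentially expressed genes for one contrast
#'
#' Per gene: Welch two-sample t test of the condition group against the
#' reference group on log2 values (variance floor 1e-8 guards zero-variance
#' groups), Benjamini-Hochberg adjustment across all genes of the contrast,
#' then the gate: `call = "up"` iff `p_adj < alpha` and
#' `log2fc >= log2(fc_threshold)`; `"down"` symmetric; `"none"` otherwise.
#'
#' @param x an `expr_matrix`.
#' @param contrast a [contrast_spec()].
#' @param alpha FDR level (default 0.05).
#' @param fc_threshold fold-change gate on the natural scale (default 2,
#'   i.e. |log2FC| >= 1). Set `strict = TRUE` for a strict inequality.
#' @param strict if TRUE the fold-change gate is `>` instead of `>=`.
#' @return A `deg_table`: list with `table` (data.frame: gene, contrast,
#'   log2fc, p_raw, p_adj, call) and the `contrast`.
#' @export
compute_deg <- function(x, contrast, alpha = 0.05, fc_threshold = 2,
                        strict = FALSE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(contrast, "contrast_spec"))
  test_ids <- samples_where(x, condition = contrast$condition,
                            day = if (is.na(contrast$day)) NULL
                                  else contrast$day)
  ref_ids <- samples_where(x, condition = contrast$reference)
  if (length(test_ids) < 2 || length(ref_ids) < 2)
    stop("need >= 2 replicates per group (", contrast$label, ": ",
         length(test_ids), " vs ", length(ref_ids), ")")
  w <- welch_rows(x$values[, test_ids, drop = FALSE],
                  x$values[, ref_ids, drop = FALSE])
  p_adj <- stats::p.adjust(w$p, method = "BH")
  lfc_gate <- log2(fc_threshold)
  pass <- if (strict) abs(w$log2fc) > lfc_gate else abs(w$log2fc) >= lfc_gate
  call <- ifelse(p_adj < alpha & pass,
                 ifelse(w$log2fc > 0, "up", "down"), "none")
  structure(list(
    table = data.frame(gene = rownames(x$values),
                       contrast = contrast$label,
                       log2fc = unname(w$log2fc),
                       p_raw = unname(w$p),
                       p_adj = unname(p_adj),
                       call = unname(call),
                       stringsAsFactors = FALSE),
    contrast = contrast), class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  n <- table(factor(x$table$call, levels = c("up", "down", "none")))
  cat(sprintf("deg_table [%s]: %d genes, %d up, %d down\n",
              x$contrast$label, nrow(x$table), n[["up"]], n[["down"]]))
  invisible(x)
}

#' Compute DEG tables for every condition x day against the reference
#'
#' @param x an `expr_matrix`.
#' @param conditions conditions to test; default every non-reference
#'   condition present (culture and in-vivo/disease).
#' @param reference reference condition label.
#' @param ... passed to [compute_deg()].
#' @return Named list of `deg_table`s, one per condition x day, named by the
#'   contrast label.
#' @export
deg_by_day <- function(x, conditions = NULL, reference = "FH", ...) {
  ann <- x$samples
  if (is.null(conditions))
    conditions <- setdiff(unique(ann$condition[ann$model_type !=
                                                 "reference"]), reference)
  out <- list()
  for (cond in conditions) {
    days <- sort(unique(ann$day[ann$condition == cond]))
    for (d in days) {
      ct <- contrast_spec(cond, d, reference)
      out[[ct$label]] <- compute_deg(x, ct, ...)
    }
  }
  out
}

#' Count DEGs per contrast
#'
#' @param degs list of `deg_table`s sharing the same reference.
#' @return data.frame: contrast, condition, day, up, down, total.
#' @export
count_degs_per_day <- function(degs) {
  if (inherits(degs, "deg_table")) degs <- list(degs)
  refs <- unique(vapply(degs, function(d) d$contrast$reference, character(1)))
  if (length(refs) > 1)
    stop("contrasts do not share a reference: ", paste(refs, collapse = ", "))
  rows <- lapply(degs, function(d) {
    data.frame(contrast = d$contrast$label,
               condition = d$contrast$condition,
               day = d$contrast$day,
               up = sum(d$table$call == "up"),
               down = sum(d$table$call == "down"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$total <- out$up + out$down
  rownames(out) <- NULL
  out
}

#' Top-ranked deregulated genes of one contrast
#'
#' Genes called in the requested direction, ranked by decreasing |log2FC|,
#' ties broken by gene ID. Returns all qualifying genes (with a warning) when
#' fewer than `k` qualify.
#'
#' @param deg a `deg_table`.
#' @param k number of genes requested.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of at most `k` gene IDs, strongest first.
#' @export
top_ranked_genes <- function(deg, k, direction = c("up", "down")) {
  stopifnot(inherits(deg, "deg_table"))
  direction <- match.arg(direction)
  if (k < 1) stop("k must be >= 1")
  tab <- deg$table[deg$table$call == direction, , drop = FALSE]
  tab <- tab[order(-abs(tab$log2fc), tab$gene), , drop = FALSE]
  if (nrow(tab) < k)
    warning(sprintf("only %d genes called %s (k = %d)", nrow(tab), direction,
                    k), call. = FALSE)
  utils::head(tab$gene, k)
}

#' Overlap statistics between two ranked gene lists
#'
#' List `b` is optionally translated to list-`a` ID space through an
#' orthologue map before intersecting; unmapped genes are dropped and
#' counted.
#'
#' @param a,b character vectors of gene IDs (non-empty).
#' @param ortholog_map optional data.frame with columns `gene_a`, `gene_b`;
#'   `b` entries are translated `gene_b -> gene_a`.
#' @return List: `intersection` (character), `n_intersection`, `jaccard`,
#'   `n_unmapped` (entries of `b` lost in translation).
#' @export
ranking_overlap <- function(a, b, ortholog_map = NULL) {
  if (!length(a) || !length(b)) stop("gene lists must be non-empty")
  n_unmapped <- 0L
  if (!is.null(ortholog_map)) {
    idx <- match(b, ortholog_map$gene_b)
    n_unmapped <- sum(is.na(idx))
    b <- ortholog_map$gene_a[idx[!is.na(idx)]]
  }
  inter <- intersect(a, b)
  uni <- union(a, b)
  list(intersection = inter,
       n_intersection = length(inter),
       jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_,
       n_unmapped = n_unmapped)
}
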