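## Concordance between two deregulation profiles (e.g. culture day 1 vs a
## disease model): Spearman correlation of fold changes, sign-coincidence
## odds ratios over shared DEGs, their time course over cultivation days,
## and the cross-species quadrant analysis on orthologue pairs.

## Align two DEG tables on a shared gene space, optionally translating
## table b's genes to a's ID space through an orthologue map.
align_deg_pair <- function(deg_a, deg_b, ortholog_map = NULL) {
  ta <- deg_a$table
  tb <- deg_b$table
  if (!is.null(ortholog_map)) {
    idx <- match(tb$gene, ortholog_map$gene_b)
    tb <- tb[!is.na(idx), , drop = FALSE]
    tb$gene <- ortholog_map$gene_a[idx[!is.na(idx)]]
  }
  shared <- intersect(ta$gene, tb$gene)
  if (!length(shared)) stop("no shared genes between the two DEG tables")
  list(a = ta[match(shared, ta$gene), , drop = FALSE],
       b = tb[match(shared, tb$gene), , drop = FALSE])
}

#' Spearman correlation of fold changes between two comparisons
#'
#' @param deg_a,deg_b `deg_table`s on a shared gene space (after optional
#'   orthologue translation of `deg_b`).
#' @param gene_policy gene set entering the correlation: `"union_deg"` (DEG
#'   in either table), `"intersection_deg"` (DEG in both), or `"all"`.
#' @param ortholog_map optional data.frame `gene_a`, `gene_b` translating
#'   `deg_b` genes.
#' @return List: `rho` (Spearman, midranks on ties), `p` (large-sample
#'   approximation), `n` (genes used), `gene_policy`.
#' @export
foldchange_correlation <- function(deg_a, deg_b,
                                   gene_policy = c("union_deg",
                                                   "intersection_deg", "all"),
                                   ortholog_map = NULL) {
  gene_policy <- match.arg(gene_policy)
  al <- align_deg_pair(deg_a, deg_b, ortholog_map)
  keep <- switch(gene_policy,
    union_deg = al$a$call != "none" | al$b$call != "none",
    intersection_deg = al$a$call != "none" & al$b$call != "none",
    all = rep(TRUE, nrow(al$a)))
  n <- sum(keep)
  if (n < 3) stop("fewer than 3 genes selected for the correlation")
  ct <- suppressWarnings(
    stats::cor.test(al$a$log2fc[keep], al$b$log2fc[keep],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       gene_policy = gene_policy)
}

#' Sign-coincidence odds ratio between two DEG tables
#'
#' Over genes called up or down in BOTH comparisons (the shared-DEG
#' universe; `universe = "all"` instead dichotomizes every gene by fold
#' change sign), counts the 2x2 table of call agreement and reports the odds
#' ratio (Haldane-Anscombe 0.5 correction when a cell is zero) with the
#' two-sided Fisher exact p.
#'
#' @param deg_a,deg_b `deg_table`s on a shared gene space.
#' @param ortholog_map optional orthologue translation for `deg_b`.
#' @param universe `"shared_deg"` (default) or `"all"`.
#' @return A `coincidence_table`: list with `counts` (named n_uu, n_ud,
#'   n_du, n_dd), `odds_ratio`, `log_or_se`, `p`, `n`, `universe_policy`,
#'   `corrected`.
#' @export
coincidence_odds_ratio <- function(deg_a, deg_b, ortholog_map = NULL,
                                   universe = c("shared_deg", "all")) {
  universe <- match.arg(universe)
  al <- align_deg_pair(deg_a, deg_b, ortholog_map)
  if (universe == "shared_deg") {
    keep <- al$a$call != "none" & al$b$call != "none"
    up_a <- al$a$call[keep] == "up"
    up_b <- al$b$call[keep] == "up"
  } else {
    keep <- rep(TRUE, nrow(al$a))
    up_a <- al$a$log2fc >= 0
    up_b <- al$b$log2fc >= 0
  }
  n <- sum(keep)
  if (n < 1) stop("no genes qualify for the coincidence table")
  n_uu <- sum(up_a & up_b);  n_ud <- sum(up_a & !up_b)
  n_du <- sum(!up_a & up_b); n_dd <- sum(!up_a & !up_b)
  or <- odds_ratio_2x2(n_uu, n_ud, n_du, n_dd)
  structure(list(counts = c(n_uu = n_uu, n_ud = n_ud, n_du = n_du,
                            n_dd = n_dd),
                 odds_ratio = or$odds_ratio,
                 log_or_se = or$log_or_se,
                 p = fisher_exact_p(n_uu, n_ud, n_du, n_dd),
                 n = n, universe_policy = universe,
                 corrected = or$corrected),
            class = "coincidence_table")
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat(sprintf("coincidence_table (%s, n = %d): OR = %.3g, p = %.3g\n",
              x$universe_policy, x$n, x$odds_ratio, x$p))
  print(x$counts)
  invisible(x)
}

#' Coincidence odds ratios across cultivation days
#'
#' Applies [coincidence_odds_ratio()] of each per-day culture DEG table
#' against one disease DEG table; per-day failures (e.g. no qualifying
#' genes) become gaps with a warning rather than aborting the series.
#'
#' @param degs_by_day named list of culture `deg_table`s (>= 2 days).
#' @param disease a disease `deg_table`.
#' @param ... passed to [coincidence_odds_ratio()].
#' @return data.frame: day, condition, n, n_uu, n_ud, n_du, n_dd,
#'   odds_ratio, log_or, p (NA rows mark gaps), ordered by day.
#' @export
odds_ratio_timecourse <- function(degs_by_day, disease, ...) {
  days <- vapply(degs_by_day, function(d) d$contrast$day, numeric(1))
  if (length(unique(days)) < 2)
    stop("need culture contrasts on >= 2 days")
  rows <- lapply(seq_along(degs_by_day), function(i) {
    d <- degs_by_day[[i]]
    base <- data.frame(day = d$contrast$day, condition = d$contrast$condition,
                       n = NA_integer_, n_uu = NA_integer_,
                       n_ud = NA_integer_, n_du = NA_integer_,
                       n_dd = NA_integer_, odds_ratio = NA_real_,
                       log_or = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
    ct <- tryCatch(coincidence_odds_ratio(d, disease, ...),
                   error = function(e) {
                     warning("day ", d$contrast$day, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (!is.null(ct)) {
      base$n <- ct$n
      base[c("n_uu", "n_ud", "n_du", "n_dd")] <- as.list(ct$counts)
      base$odds_ratio <- ct$odds_ratio
      base$log_or <- log(ct$odds_ratio)
      base$p <- ct$p
    }
    base
  })
  out <- do.call(rbind, rows)
  out[order(out$day), ]
}

#' Pair orthologous genes between two species' DEG tables
#'
#' Keeps only one-to-one map entries (genes appearing more than once on
#' either side are dropped and counted) that resolve in both tables.
#'
#' @param deg_a species-A `deg_table`.
#' @param deg_b species-B `deg_table`.
#' @param map data.frame with columns `gene_a`, `gene_b` (e.g. from
#'   [read_ortholog_tsv()]).
#' @return An `ortholog_pairs` data.frame: gene_a, gene_b, log2fc_a,
#'   log2fc_b, call_a, call_b; attributes `n_many_to_many` and `n_unmatched`
#'   count dropped entries.
#' @export
map_orthologs <- function(deg_a, deg_b, map) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  dup <- duplicated(map$gene_a) | duplicated(map$gene_a, fromLast = TRUE) |
         duplicated(map$gene_b) | duplicated(map$gene_b, fromLast = TRUE)
  n_many <- sum(dup)
  map <- map[!dup, , drop = FALSE]
  ia <- match(map$gene_a, deg_a$table$gene)
  ib <- match(map$gene_b, deg_b$table$gene)
  ok <- !is.na(ia) & !is.na(ib)
  n_unmatched <- sum(!ok)
  if (!any(ok)) stop("no orthologue pairs resolve against both DEG tables")
  out <- data.frame(gene_a = map$gene_a[ok], gene_b = map$gene_b[ok],
                    log2fc_a = deg_a$table$log2fc[ia[ok]],
                    log2fc_b = deg_b$table$log2fc[ib[ok]],
                    call_a = deg_a$table$call[ia[ok]],
                    call_b = deg_b$table$call[ib[ok]],
                    stringsAsFactors = FALSE)
  attr(out, "n_many_to_many") <- n_many
  attr(out, "n_unmatched") <- n_unmatched
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Assign orthologue pairs to cross-species quadrants
#'
#' A pair gets a quadrant label only when |log2FC| >= log2(`fc_threshold`)
#' in BOTH species: Q1 both up, Q3 both down, Q2 A down & B up, Q4 A up & B
#' down; everything else is `unassigned`. Labels partition all pairs.
#'
#' @param pairs an `ortholog_pairs` data.frame (columns log2fc_a, log2fc_b).
#' @param fc_threshold fold-change gate on the natural scale (default 2).
#' @return `pairs` with an added factor column `quadrant` with levels Q1,
#'   Q2, Q3, Q4, unassigned.
#' @export
assign_quadrants <- function(pairs, fc_threshold = 2) {
  thr <- log2(fc_threshold)
  a <- pairs$log2fc_a
  b <- pairs$log2fc_b
  q <- rep("unassigned", nrow(pairs))
  both <- abs(a) >= thr & abs(b) >= thr
  q[both & a > 0 & b > 0] <- "Q1"
  q[both & a < 0 & b > 0] <- "Q2"
  q[both & a < 0 & b < 0] <- "Q3"
  q[both & a > 0 & b < 0] <- "Q4"
  pairs$quadrant <- factor(q, levels = c("Q1", "Q2", "Q3", "Q4",
                                         "unassigned"))
  pairs
}

#' Motif overrepresentation per quadrant
#'
#' Hypergeometric overrepresentation of each motif set (species-A IDs) in
#' each quadrant, universe = all pairs (assigned and unassigned); BH
#' adjustment across quadrant x set. Empty quadrants are skipped with a
#' message-level note in the result.
#'
#' @param assigned output of [assign_quadrants()].
#' @param motif_sets a [gene_set_collection()] on species-A gene IDs; its
#'   universe is intersected with the paired genes.
#' @return data.frame: quadrant, set, set_size, overlap, expected,
#'   odds_ratio, p_raw, p_adj.
#' @export
quadrant_enrichment <- function(assigned, motif_sets) {
  stopifnot("quadrant" %in% names(assigned),
            inherits(motif_sets, "gene_set_collection"))
  universe <- intersect(motif_sets$universe, assigned$gene_a)
  sets <- lapply(motif_sets$sets, intersect, y = universe)
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(sets)) stop("no motif-set members among the paired genes")
  coll <- gene_set_collection(sets, universe)
  rows <- list()
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    query <- intersect(assigned$gene_a[assigned$quadrant == q], universe)
    if (!length(query)) next                       # empty quadrant: skipped
    enr <- overrepresentation(query, coll)
    enr$quadrant <- q
    rows[[q]] <- enr
  }
  if (!length(rows)) stop("all quadrants are empty")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)                # BH across quadrant x set
  rownames(out) <- NULL
  out[, c("quadrant", "set", "set_size", "overlap", "expected", "odds_ratio",
          "p_raw", "p_adj")]
}

#' Quadrant metagenes from the top deregulated orthologue pairs
#'
#' Per quadrant, the `k` pairs with the best combined deregulation (smallest
#' sum of the two per-species ranks of |log2FC|) define a gene set in each
#' species; metagene scores are then computed in both species' expression
#' matrices across the requested groups.
#'
#' @param assigned output of [assign_quadrants()].
#' @param x_a,x_b species A / B `expr_matrix` objects.
#' @param k pairs per quadrant (default 10; whole quadrant if smaller).
#' @param groups_a,groups_b group definitions passed to [metagene_scores()]
#'   (NULL = all condition x day groups).
#' @param scaling passed to [metagene_scores()].
#' @return List per non-empty quadrant: `genes_a`, `genes_b`, `scores_a`,
#'   `scores_b`.
#' @export
quadrant_metagenes <- function(assigned, x_a, x_b, k = 10,
                               groups_a = NULL, groups_b = NULL,
                               scaling = "reference_anchored") {
  stopifnot("quadrant" %in% names(assigned))
  out <- list()
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    sub <- assigned[assigned$quadrant == q, , drop = FALSE]
    if (!nrow(sub)) next
    rank_sum <- rank(-abs(sub$log2fc_a), ties.method = "average") +
                rank(-abs(sub$log2fc_b), ties.method = "average")
    sub <- sub[order(rank_sum, sub$gene_a), , drop = FALSE]
    top <- utils::head(sub, k)
    sets_a <- stats::setNames(list(top$gene_a), paste0(q, "_top"))
    sets_b <- stats::setNames(list(top$gene_b), paste0(q, "_top"))
    out[[q]] <- list(
      genes_a = top$gene_a,
      genes_b = top$gene_b,
      scores_a = metagene_scores(x_a, sets_a, groups = groups_a,
                                 scaling = scaling),
      scores_b = metagene_scores(x_b, sets_b, groups = groups_b,
                                 scaling = scaling))
  }
  out
}
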