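## Fuzzy c-means clustering of time-dependent fold-change profiles, cluster
## count selection, hypergeometric gene-set overrepresentation, and motif
## assignment of clusters.

#' Build z-scaled fold-change profiles for clustering
#'
#' Concatenates each gene's log2 fold changes over (condition x day) from a
#' list of DEG tables, then z-scales per gene (mean 0, SD 1 across the
#' profile entries). With `include_reference = TRUE` (default) the day-0
#' anchor — a fold change of exactly 0 against the reference — is prepended
#' to every condition's sub-profile, so that a gene deregulated to the same
#' level on every sampled day still has a well-defined (step-like) shape
#' instead of a constant profile. Constant profiles cannot be scaled and are
#' excluded.
#'
#' @param degs named list of `deg_table`s covering >= 2 timepoints.
#' @param gene_filter `"any-contrast-DEG"` keeps genes called up or down in
#'   at least one contrast; `"all"` keeps every gene.
#' @param include_reference prepend the day-0 zero per condition.
#' @return A `gene_profiles` object: list with `profiles` (genes x entries
#'   matrix, rows scaled), `excluded` (gene IDs dropped as constant), and
#'   `columns` (profile entry labels).
#' @export
build_profiles <- function(degs, gene_filter = c("any-contrast-DEG", "all"),
                           include_reference = TRUE) {
  gene_filter <- match.arg(gene_filter)
  if (!length(degs)) stop("no DEG tables supplied")
  days <- unique(vapply(degs, function(d) d$contrast$day, numeric(1)))
  if (length(days) < 2) stop("profiles need contrasts over >= 2 timepoints")
  conds <- vapply(degs, function(d) d$contrast$condition, character(1))
  dayv <- vapply(degs, function(d) d$contrast$day, numeric(1))
  degs <- degs[order(conds, dayv)]
  conds <- conds[order(conds, dayv)]
  genes <- degs[[1]]$table$gene
  fc <- vapply(degs, function(d) {
    if (!identical(d$table$gene, genes)) stop("DEG tables disagree on genes")
    d$table$log2fc
  }, numeric(length(genes)))
  rownames(fc) <- genes
  colnames(fc) <- vapply(degs, function(d) d$contrast$label, character(1))
  if (include_reference) {
    blocks <- lapply(unique(conds), function(cc) {
      anchor <- matrix(0, length(genes), 1,
                       dimnames = list(genes, paste(cc, "day 0")))
      cbind(anchor, fc[, conds == cc, drop = FALSE])
    })
    fc <- do.call(cbind, blocks)
  }
  if (gene_filter == "any-contrast-DEG") {
    called <- Reduce(`|`, lapply(degs, function(d) d$table$call != "none"))
    fc <- fc[called, , drop = FALSE]
  }
  sds <- apply(fc, 1, stats::sd)
  excluded <- rownames(fc)[sds == 0]
  fc <- fc[sds > 0, , drop = FALSE]
  if (!nrow(fc)) stop("no non-constant profiles left")
  scaled <- (fc - rowMeans(fc)) / apply(fc, 1, stats::sd)
  structure(list(profiles = scaled, excluded = excluded,
                 columns = colnames(fc)),
            class = "gene_profiles")
}

## One FCM run from a given center initialization. Standard alternating
## updates: u_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1)), v_j = sum_i u^m x / sum u^m.
fcm_run <- function(x, centers, m, tol, max_iter) {
  n <- nrow(x)
  c <- nrow(centers)
  expo <- 2 / (m - 1)
  obj_trace <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 1e-16)
    ## u_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1)), computed via ratios to the
    ## row minimum so small fuzzifiers (large exponents) cannot overflow
    dmin <- d2[cbind(seq_len(n), max.col(-d2))]
    w <- (dmin / d2)^(expo / 2)
    u <- w / rowSums(w)
    um <- u^m
    obj <- sum(um * d2)
    obj_trace <- c(obj_trace, obj)
    centers_new <- (t(um) %*% x) / colSums(um)
    if (it > 1 && abs(obj_trace[it - 1] - obj) <=
        tol * max(1, abs(obj_trace[it - 1]))) {
      centers <- centers_new
      converged <- TRUE
      break
    }
    centers <- centers_new
  }
  list(u = u, centers = centers, objective = obj_trace,
       converged = converged)
}

#' Fuzzy c-means clustering of gene profiles
#'
#' Standard FCM with Euclidean distance on the z-scaled profiles: soft
#' memberships controlled by the fuzzifier `m`, multiple random restarts,
#' the best run selected by final objective. Deterministic given `seed`.
#'
#' @param profiles a `gene_profiles` object (or a numeric matrix of scaled
#'   profiles).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1); m -> 1 approaches hard k-means.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap per restart; non-convergence is reported in
#'   the `converged` flag with a warning.
#' @param n_restarts number of random center initializations.
#' @param seed integer seed.
#' @param membership_min membership cutoff for the `core` flag.
#' @return A `fuzzy_clustering`: list with `centers` (c x profile length),
#'   `membership` (genes x c, rows sum to 1), `hard_label` (named integer),
#'   `core` (named logical, max membership >= `membership_min`),
#'   `objective` (trace of the winning run), `converged`, `c`, `m`.
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, tol = 1e-9, max_iter = 200,
                         n_restarts = 10, seed = 1, membership_min = 0.5) {
  x <- if (inherits(profiles, "gene_profiles")) profiles$profiles
       else as.matrix(profiles)
  if (c < 2) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (nrow(x) < c) stop("need at least c profiles")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- x[sample.int(nrow(x), c), , drop = FALSE]
    run <- fcm_run(x, init, m, tol, max_iter)
    if (is.null(best) ||
        utils::tail(run$objective, 1) < utils::tail(best$objective, 1))
      best <- run
  }
  if (!best$converged)
    warning("fuzzy c-means did not converge within max_iter", call. = FALSE)
  u <- best$u
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(c)))
  hard <- apply(u, 1, which.max)
  structure(list(centers = best$centers, membership = u,
                 hard_label = hard,
                 core = apply(u, 1, max) >= membership_min,
                 objective = best$objective, converged = best$converged,
                 c = c, m = m),
            class = "fuzzy_clustering")
}

#' Choose the cluster count by internal quality indices
#'
#' Runs [fuzzy_cmeans()] for every candidate `c` and reports the partition
#' coefficient (higher = crisper) and the Xie-Beni index (compactness over
#' separation; lower = better). The chosen `c` minimizes Xie-Beni.
#'
#' @param profiles a `gene_profiles` or scaled matrix.
#' @param c_range candidate cluster counts.
#' @param m fuzzifier.
#' @param seed integer seed.
#' @param ... passed to [fuzzy_cmeans()].
#' @return List: `c` (chosen), `scores` (data.frame c, partition_coefficient,
#'   xie_beni), `clusterings` (per candidate, named by c).
#' @export
select_cluster_count <- function(profiles, c_range, m = 2, seed = 1, ...) {
  x <- if (inherits(profiles, "gene_profiles")) profiles$profiles
       else as.matrix(profiles)
  if (any(c_range < 2) || any(c_range >= nrow(x)))
    stop("c_range must lie in [2, n_profiles)")
  rows <- list(); fits <- list()
  for (cc in c_range) {
    fit <- fuzzy_cmeans(x, cc, m = m, seed = seed, ...)
    u <- fit$membership
    d2 <- outer(rowSums(x^2), rep(1, cc)) - 2 * x %*% t(fit$centers) +
      outer(rep(1, nrow(x)), rowSums(fit$centers^2))
    j <- sum((u^m) * pmax(d2, 0))
    sep <- min(stats::dist(fit$centers)^2)
    rows[[as.character(cc)]] <- data.frame(
      c = cc,
      partition_coefficient = mean(rowSums(u^2)),
      xie_beni = j / (nrow(x) * sep))
    fits[[as.character(cc)]] <- fit
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  chosen <- scores$c[which.min(scores$xie_beni)]
  list(c = chosen, scores = scores, clusterings = fits)
}

#' Gene-set overrepresentation by the hypergeometric test
#'
#' One-sided hypergeometric tail p per set ([hypergeom_tail_p()]),
#' Benjamini-Hochberg adjustment across sets, and the 2x2 odds ratio with
#' Haldane-Anscombe correction when any cell is zero.
#'
#' @param query character vector of gene IDs (subset of the universe).
#' @param sets a [gene_set_collection()].
#' @return data.frame: set, set_size, overlap, expected, odds_ratio, p_raw,
#'   p_adj, ordered by p_raw.
#' @export
overrepresentation <- function(query, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(query)
  if (!length(query)) stop("empty query")
  universe <- sets$universe
  if (!length(universe)) stop("empty universe")
  stray <- setdiff(query, universe)
  if (length(stray))
    stop("query genes outside the universe (e.g. ", stray[1], ")")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- sets$sets[[nm]]
    k <- length(members)
    ov <- length(intersect(query, members))
    or <- odds_ratio_2x2(ov, n_q - ov, k - ov, n_u - n_q - k + ov)
    data.frame(set = nm, set_size = k, overlap = ov,
               expected = n_q * k / n_u,
               odds_ratio = or$odds_ratio,
               p_raw = hypergeom_tail_p(ov, n_q, k, n_u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out[order(out$p_raw), ]
}

#' Assign biological motif labels to clusters from enrichment results
#'
#' Each cluster is labelled by the motif whose rule sets reach the smallest
#' adjusted p in that cluster's enrichment table; ties are broken by larger
#' odds ratio; clusters where no rule set passes `alpha` stay unlabelled
#' (NA).
#'
#' @param clustering a `fuzzy_clustering`.
#' @param enrichments named list (one element per cluster, names matching
#'   `colnames(clustering$membership)`) of [overrepresentation()] tables.
#' @param motif_rules named list: motif name -> character vector of gene-set
#'   names that diagnose it.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return Named character vector cluster -> motif (NA when unlabelled).
#' @export
assign_motifs <- function(clustering, enrichments, motif_rules,
                          alpha = 0.05) {
  stopifnot(inherits(clustering, "fuzzy_clustering"))
  clusters <- colnames(clustering$membership)
  out <- stats::setNames(rep(NA_character_, length(clusters)), clusters)
  if (!length(motif_rules)) return(out)
  for (cl in clusters) {
    enr <- enrichments[[cl]]
    if (is.null(enr)) next
    best_p <- Inf; best_or <- -Inf; best_motif <- NA_character_
    for (motif in names(motif_rules)) {
      sub <- enr[enr$set %in% motif_rules[[motif]], , drop = FALSE]
      if (!nrow(sub)) next
      i <- order(sub$p_adj, -sub$odds_ratio)[1]
      if (sub$p_adj[i] < best_p ||
          (sub$p_adj[i] == best_p && sub$odds_ratio[i] > best_or)) {
        best_p <- sub$p_adj[i]; best_or <- sub$odds_ratio[i]
        best_motif <- motif
      }
    }
    if (is.finite(best_p) && best_p < alpha) out[cl] <- best_motif
  }
  out
}

#' Split metabolism clusters by sandwich-culture rescue
#'
#' Post-hoc rule separating "rescued" from "unrescued" downregulated genes:
#' a gene is rescued when its mean |log2FC| across days in the sandwich
#' condition falls below `ratio` times that in the confluent-monolayer
#' condition. The default ratio 0.75 is the midpoint between a fully
#' attenuated (50%) and an unattenuated (100%) sandwich response, so genes
#' attenuated by half do not sit on the decision boundary.
#'
#' @param degs named list of `deg_table`s (as from [deg_by_day()]).
#' @param genes gene IDs to classify.
#' @param sandwich,monolayer condition labels.
#' @param ratio attenuation threshold (default 0.75).
#' @return Named logical vector: TRUE = rescued.
#' @export
rescued_by_sandwich <- function(degs, genes, sandwich = "S",
                                monolayer = "M_C", ratio = 0.75) {
  conds <- vapply(degs, function(d) d$contrast$condition, character(1))
  mean_abs_fc <- function(cond) {
    tabs <- degs[conds == cond]
    if (!length(tabs)) stop("no contrasts for condition ", cond)
    fc <- vapply(tabs, function(d) {
      d$table$log2fc[match(genes, d$table$gene)]
    }, numeric(length(genes)))
    rowMeans(abs(matrix(fc, nrow = length(genes))))
  }
  s <- mean_abs_fc(sandwich)
  m <- mean_abs_fc(monolayer)
  stats::setNames(s < ratio * m, genes)
}
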