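# Shared fixtures and independent oracles, all built in code.

# Small hand-made expression matrix: `values` genes x samples, annotations
# derived from sample IDs of the form "<cond>_d<day>_r<rep>".
tiny_expr <- function(values) {
  ids <- colnames(values)
  parts <- strsplit(ids, "_d|_r")
  ann <- data.frame(
    sample_id = ids,
    condition = vapply(parts, `[`, "", 1),
    day = as.numeric(vapply(parts, `[`, "", 2)),
    replicate = as.integer(vapply(parts, `[`, "", 3)),
    species = "A",
    model_type = ifelse(vapply(parts, `[`, "", 1) == "FH", "reference",
                        "culture"),
    stringsAsFactors = FALSE)
  expression_matrix(values, ann)
}

# Deterministic random matrix with gene/sample names.
rand_expr <- function(n_genes, ids, seed = 1, sd = 1, mean = 8) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * length(ids), mean, sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  tiny_expr(m)
}

# Config used by several module tests: one condition, clean motif set.
clean_config <- function(seed, noise_sd = 0.3, effect = 2, n_rep = 3,
                         motifs = c(metabolism_down_unrescued = 60,
                                    inflammation_transient = 60,
                                    inflammation_persistent = 60,
                                    cellcycle = 60),
                         n_genes = 400, conditions = "M_C",
                         timepoints = c(0, 1, 2, 3, 5, 7), ...) {
  simulation_config(n_genes = n_genes, motif_sizes = motifs,
                    n_replicates = n_rep, timepoints = timepoints,
                    conditions = conditions, disease_conditions = numeric(0),
                    noise_sd = noise_sd, effect_size_log2 = effect,
                    seed = seed, ...)
}

# Adjusted Rand index (permutation-invariant clustering agreement), the
# standard contingency-table closed form. Independent of the package.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
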