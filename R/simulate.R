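## Synthetic hepatocyte time-course generator. Plants gene modules ("motifs")
## with the dynamics seen in cultivated hepatocytes: loss of mature liver
## functions (monotone down, partially rescued by sandwich culture),
## transient and persistent inflammation (up), delayed cell-cycle induction,
## and a cholesterol module induced in one species only. Every downstream
## stage of the pipeline is validated against the planted truth.

MOTIF_NAMES <- c("metabolism_down_rescued", "metabolism_down_unrescued",
                 "inflammation_transient", "inflammation_persistent",
                 "cellcycle", "cholesterol_speciesA_only", "background")

#' Configuration for the synthetic time-course generator
#'
#' @param n_genes total number of genes per species.
#' @param motif_sizes named integer vector of planted module sizes. Valid
#'   names: `metabolism_down_rescued`, `metabolism_down_unrescued`,
#'   `inflammation_transient`, `inflammation_persistent`, `cellcycle`,
#'   `cholesterol_speciesA_only`. Genes not covered are `background`.
#' @param n_replicates replicates per culture condition x day group and for
#'   the reference group.
#' @param timepoints ordered cultivation days; day 0 is the freshly isolated
#'   hepatocyte (FH) reference group and must be first.
#' @param conditions culture-condition labels. `"S"` (sandwich) attenuates the
#'   `metabolism_down_rescued` effect by 50%.
#' @param disease_conditions named numeric vector: disease label ->
#'   target correlation (in [-1, 1]) between the disease fold changes and the
#'   day-1 culture fold changes of the anchor condition.
#' @param n_replicates_disease replicates per disease condition.
#' @param noise_sd residual SD on the log2 scale.
#' @param effect_size_log2 named numeric vector of peak |log2 fold change|
#'   per motif; a single unnamed number applies to all motifs.
#' @param ortholog_discordant_fraction fraction of mapped effect-gene pairs
#'   whose species-B effect sign is flipped (planted Q2/Q4 genes).
#' @param anchor_condition culture condition whose day-1 fold changes anchor
#'   the disease correlation structure.
#' @param seed integer seed; all randomness is derived from it.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              motif_sizes = c(metabolism_down_rescued = 200,
                                              metabolism_down_unrescued = 200,
                                              inflammation_transient = 150,
                                              inflammation_persistent = 150,
                                              cellcycle = 60,
                                              cholesterol_speciesA_only = 40),
                              n_replicates = 3,
                              timepoints = c(0, 1, 2, 3, 5, 7),
                              conditions = c("M_C", "M_S", "S"),
                              disease_conditions = c(disease = 0.6),
                              n_replicates_disease = 3,
                              noise_sd = 0.3,
                              effect_size_log2 = 2,
                              ortholog_discordant_fraction = 0,
                              anchor_condition = "M_C",
                              seed = 1L) {
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (timepoints[1] != 0)
    stop("first timepoint must be 0 (the fresh-cell reference)")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  bad <- setdiff(names(motif_sizes), setdiff(MOTIF_NAMES, "background"))
  if (length(bad)) stop("unknown motif names: ", paste(bad, collapse = ", "))
  if (any(motif_sizes < 0)) stop("motif sizes must be non-negative")
  if (sum(motif_sizes) > n_genes)
    stop("motif sizes sum exceeds n_genes")
  if (length(disease_conditions) && any(abs(disease_conditions) > 1))
    stop("|rho_target| must be <= 1")
  if (ortholog_discordant_fraction < 0 || ortholog_discordant_fraction > 1)
    stop("ortholog_discordant_fraction must be in [0, 1]")
  if (n_replicates < 1) stop("n_replicates must be positive")
  eff <- effect_size_log2
  if (is.null(names(eff))) {
    if (length(eff) != 1) stop("unnamed effect_size_log2 must be scalar")
    eff <- stats::setNames(rep(eff, length(motif_sizes)), names(motif_sizes))
  } else {
    bad <- setdiff(names(eff), names(motif_sizes))
    if (length(bad)) stop("effect sizes for unknown motifs: ",
                          paste(bad, collapse = ", "))
    full <- stats::setNames(rep(2, length(motif_sizes)), names(motif_sizes))
    full[names(eff)] <- eff
    eff <- full
  }
  structure(list(n_genes = as.integer(n_genes),
                 motif_sizes = motif_sizes,
                 n_replicates = as.integer(n_replicates),
                 timepoints = timepoints,
                 conditions = conditions,
                 disease_conditions = disease_conditions,
                 n_replicates_disease = as.integer(n_replicates_disease),
                 noise_sd = noise_sd,
                 effect_size_log2 = eff,
                 ortholog_discordant_fraction = ortholog_discordant_fraction,
                 anchor_condition = anchor_condition,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Mean log2 fold-change trajectory of one motif at day t (t = 0 -> 0).
## `effect` is the peak |log2FC|; `condition` matters only for the
## sandwich-rescued metabolism module (50% attenuation in "S").
motif_trajectory <- function(motif, t, effect, condition) {
  peak_shape <- function(t, peak, a = 2) {
    u <- t / peak
    u^a * exp(a * (1 - u))
  }
  ## time constants are fast (tau = 0.4 d for the saturating modules) because
  ## the bulk of the culture-induced deregulation happens within the first
  ## 24 h; the day-by-day DEG count therefore peaks at day 1
  switch(motif,
    metabolism_down_rescued = {
      att <- if (condition == "S") 0.5 else 1
      -effect * att * (1 - exp(-t / 0.4))
    },
    metabolism_down_unrescued = -effect * (1 - exp(-t / 0.4)),
    inflammation_transient = effect * peak_shape(t, peak = 1, a = 3),
    inflammation_persistent = effect * (1 - exp(-t / 0.4)),
    cellcycle = effect * peak_shape(t, peak = 2.5),
    cholesterol_speciesA_only = effect * (1 - exp(-t / 0.4)),
    background = rep(0, length(t)),
    stop("unknown motif: ", motif)
  )
}

## Deterministic per-species seed derived from the config seed (kept < 2^31).
derive_seed <- function(seed, tag) {
  (seed * 1009L + tag * 7919L) %% 2147483647L
}

#' Simulate a culture time course with planted motif structure
#'
#' Generates log2 expression for a fresh-hepatocyte reference group (day 0)
#' and every culture condition x day combination. Per-gene values are the
#' gene's baseline plus its motif trajectory plus Gaussian noise
#' (`noise_sd`, log2 scale). Output is deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param species species label (`"A"` or `"B"`). The
#'   `cholesterol_speciesA_only` motif has zero effect outside species A;
#'   gene IDs and sample IDs are prefixed by species.
#' @param flip_genes optional character vector of gene IDs (species-local
#'   numbering, e.g. `"gB0007"`) whose motif effect sign is flipped; used by
#'   [simulate_species_pair()] to plant discordant orthologues.
#'
#' @return A `synthetic_dataset`: list with `expression` (an `expr_matrix`),
#'   `truth` (named character vector gene -> motif), `true_fc` (genes x
#'   (condition x day) matrix of true log2 fold changes), `flipped` (logical
#'   per gene), `config`, `species`. `ortholog_map` and `true_disease_fc` are
#'   filled in by [build_ortholog_map()] / [simulate_disease_conditions()].
#' @export
simulate_timecourse <- function(config, species = "A", flip_genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, match(species, LETTERS)))
  ng <- config$n_genes
  genes <- sprintf("g%s%04d", species, seq_len(ng))

  truth <- rep("background", ng)
  idx <- 1L
  for (nm in names(config$motif_sizes)) {
    k <- config$motif_sizes[[nm]]
    if (k > 0) truth[idx:(idx + k - 1L)] <- nm
    idx <- idx + k
  }
  names(truth) <- genes

  flipped <- stats::setNames(genes %in% flip_genes, genes)
  baseline <- stats::rnorm(ng, mean = 8, sd = 2)

  tps <- config$timepoints
  culture_days <- tps[tps > 0]

  ## true log2FC per gene for every (condition, day) group
  groups <- expand.grid(condition = config$conditions, day = culture_days,
                        stringsAsFactors = FALSE)
  true_fc <- matrix(0, ng, nrow(groups),
                    dimnames = list(genes,
                                    paste(groups$condition, groups$day,
                                          sep = "|")))
  for (j in seq_len(nrow(groups))) {
    for (nm in unique(truth)) {
      rows <- which(truth == nm)
      eff <- if (nm == "background") 0 else config$effect_size_log2[[nm]]
      if (nm == "cholesterol_speciesA_only" && species != "A") eff <- 0
      fc <- motif_trajectory(nm, groups$day[j], eff, groups$condition[j])
      true_fc[rows, j] <- fc
    }
  }
  true_fc[flipped, ] <- -true_fc[flipped, , drop = FALSE]

  ## samples: reference (FH) + one group per condition x culture day
  nrep <- config$n_replicates
  ann <- data.frame(
    sample_id = sprintf("%s_FH_r%d", species, seq_len(nrep)),
    condition = "FH", day = 0, replicate = seq_len(nrep),
    species = species, model_type = "reference",
    stringsAsFactors = FALSE)
  vals <- baseline + matrix(stats::rnorm(ng * nrep, 0, config$noise_sd),
                            ng, nrep)
  for (j in seq_len(nrow(groups))) {
    ids <- sprintf("%s_%s_d%g_r%d", species, groups$condition[j],
                   groups$day[j], seq_len(nrep))
    ann <- rbind(ann, data.frame(
      sample_id = ids, condition = groups$condition[j], day = groups$day[j],
      replicate = seq_len(nrep), species = species, model_type = "culture",
      stringsAsFactors = FALSE))
    block <- baseline + true_fc[, j] +
      matrix(stats::rnorm(ng * nrep, 0, config$noise_sd), ng, nrep)
    vals <- cbind(vals, block)
  }
  colnames(vals) <- ann$sample_id
  rownames(vals) <- genes

  structure(list(expression = expression_matrix(vals, ann),
                 truth = truth,
                 true_fc = true_fc,
                 baseline = stats::setNames(baseline, genes),
                 flipped = flipped,
                 ortholog_map = NULL,
                 true_disease_fc = NULL,
                 species = species,
                 config = config),
            class = "synthetic_dataset")
}

#' Add disease conditions with controlled concordance
#'
#' For each configured disease condition with target correlation
#' `rho_target`, draws per-gene true disease log2 fold changes from a
#' bivariate-normal construction around the day-1 fold changes of the anchor
#' culture condition, so that the gene-level correlation equals `rho_target`
#' in expectation, then simulates replicate samples (`model_type "in_vivo"`,
#' annotated day 1) around those effects.
#'
#' @param ds a `synthetic_dataset` from [simulate_timecourse()].
#' @param config the same [simulation_config()]; its `disease_conditions`
#'   entry drives this step.
#' @return `ds` with disease samples appended to `$expression` and
#'   `$true_disease_fc` (genes x disease matrix) filled in.
#' @export
simulate_disease_conditions <- function(ds, config = ds$config) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!length(config$disease_conditions)) return(ds)
  if (any(abs(config$disease_conditions) > 1))
    stop("|rho_target| must be <= 1")
  set.seed(derive_seed(config$seed, 97L + match(ds$species, LETTERS)))

  anchor_col <- paste(config$anchor_condition, 1, sep = "|")
  if (!anchor_col %in% colnames(ds$true_fc))
    stop("anchor condition/day not simulated: ", anchor_col)
  f1 <- ds$true_fc[, anchor_col]
  s <- stats::sd(f1)
  if (s == 0) s <- 1          # degenerate no-effect world: pure noise target
  z <- f1 / s

  ng <- length(f1)
  genes <- names(f1)
  nrep <- config$n_replicates_disease
  true_dfc <- matrix(0, ng, length(config$disease_conditions),
                     dimnames = list(genes, names(config$disease_conditions)))
  vals <- NULL
  ann <- NULL
  for (d in names(config$disease_conditions)) {
    rho <- config$disease_conditions[[d]]
    if (abs(rho) == 1 && config$noise_sd == 0) {
      g <- rho * z * s       # exactly proportional in the noiseless limit
    } else {
      g <- (rho * z + sqrt(1 - rho^2) * stats::rnorm(ng)) * s
    }
    true_dfc[, d] <- g
    ids <- sprintf("%s_%s_r%d", ds$species, d, seq_len(nrep))
    block <- ds$baseline + g +
      matrix(stats::rnorm(ng * nrep, 0, config$noise_sd), ng, nrep)
    colnames(block) <- ids
    vals <- cbind(vals, block)
    ann <- rbind(ann, data.frame(
      sample_id = ids, condition = d, day = 1, replicate = seq_len(nrep),
      species = ds$species, model_type = "in_vivo", stringsAsFactors = FALSE))
  }
  rownames(vals) <- genes
  ds$expression <- expression_matrix(cbind(ds$expression$values, vals),
                                     rbind(ds$expression$samples, ann))
  ds$true_disease_fc <- true_dfc
  ds
}

#' Simulate a two-species pair with a planted orthologue map
#'
#' Species A and B share motif assignments gene-by-gene (gene `gA000i`
#' corresponds to `gB000i`); a fraction `ortholog_discordant_fraction` of
#' effect genes (sampled independently per gene) have their species-B effect
#' sign flipped, planting discordant (Q2/Q4) orthologue pairs.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `a` and `b` (each a `synthetic_dataset`,
#'   species B carrying the flips) where `a$ortholog_map` is filled in by
#'   [build_ortholog_map()].
#' @export
simulate_species_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  a <- simulate_timecourse(config, species = "A")
  set.seed(derive_seed(config$seed, 41L))
  effect_genes <- names(a$truth)[a$truth != "background"]
  flip_a <- effect_genes[
    stats::runif(length(effect_genes)) < config$ortholog_discordant_fraction]
  flip_b <- sub("^gA", "gB", flip_a)
  b <- simulate_timecourse(config, species = "B", flip_genes = flip_b)
  a <- build_ortholog_map(a, b, config)
  list(a = a, b = b)
}

#' Attach the one-to-one orthologue map between two simulated species
#'
#' The map pairs gene `gA000i` with `gB000i`. Idempotent: re-applying it to a
#' dataset that already carries a map leaves the labels unchanged.
#'
#' @param ds_a species-A `synthetic_dataset`.
#' @param ds_b species-B `synthetic_dataset` (must have the same gene count).
#' @param config the shared [simulation_config()].
#' @return `ds_a` with `$ortholog_map`: data.frame `gene_a`, `gene_b`,
#'   `discordant` (logical, TRUE where the B effect sign was flipped).
#' @export
build_ortholog_map <- function(ds_a, ds_b, config = ds_a$config) {
  stopifnot(inherits(ds_a, "synthetic_dataset"),
            inherits(ds_b, "synthetic_dataset"))
  if (length(ds_a$truth) != length(ds_b$truth))
    stop("species gene counts differ")
  map <- data.frame(gene_a = names(ds_a$truth),
                    gene_b = names(ds_b$truth),
                    discordant = unname(ds_b$flipped),
                    stringsAsFactors = FALSE)
  ds_a$ortholog_map <- map
  ds_a
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits `expression.tsv`, `annotations.tsv`, `truth.tsv`, plus
#' `ortholog_map.tsv` when present, and the config as `config.json`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(ds$expression,
                       file.path(dir, "expression.tsv"),
                       file.path(dir, "annotations.tsv"))
  utils::write.table(data.frame(gene = names(ds$truth), motif = ds$truth),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ds$ortholog_map))
    write_ortholog_tsv(ds$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  cfg <- ds$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
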