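# Minimal deg_table constructor for arithmetic-level tests.
fake_deg <- function(genes, log2fc, call = NULL, condition = "M_C", day = 1) {
  if (is.null(call)) call <- ifelse(abs(log2fc) >= 1, ifelse(log2fc > 0,
                                                             "up", "down"),
                                    "none")
  structure(list(table = data.frame(gene = genes,
                                    contrast = sprintf("%s vs FH day %s",
                                                       condition, day),
                                    log2fc = log2fc, p_raw = 0.001,
                                    p_adj = 0.01, call = call,
                                    stringsAsFactors = FALSE),
                 contrast = contrast_spec(condition, day)),
            class = "deg_table")
}

test_that("fold-change correlation hits the degenerate limits", {
  set.seed(61)
  g <- sprintf("g%03d", 1:100)
  fc <- rnorm(100, 0, 2)
  a <- fake_deg(g, fc)
  expect_equal(foldchange_correlation(a, a)$rho, 1)
  b <- fake_deg(g, -fc)
  expect_equal(foldchange_correlation(a, b)$rho, -1)
  # invariance under strictly monotone transform of one vector
  bmono <- fake_deg(g, fc^3 + 2 * fc)
  expect_equal(foldchange_correlation(a, bmono, gene_policy = "all")$rho, 1)
  expect_error(foldchange_correlation(fake_deg(g[1:3], c(0, 0, 0)),
                                      fake_deg(g[1:3], c(0, 0, 0))),
               "fewer than 3")
})

test_that("synthetic disease at rho 0.6 lands near the target", {
  rhos <- vapply(1:5, function(s) {
    cfg <- clean_config(seed = 60 + s, n_genes = 1200,
                        motifs = c(metabolism_down_unrescued = 200,
                                   inflammation_persistent = 200),
                        timepoints = c(0, 1))
    cfg$disease_conditions <- c(dz = 0.6)
    ds <- simulate_disease_conditions(simulate_timecourse(cfg), cfg)
    deg_c <- compute_deg(ds$expression, contrast_spec("M_C", 1))
    deg_d <- compute_deg(ds$expression, contrast_spec("dz", 1))
    foldchange_correlation(deg_c, deg_d)$rho
  }, numeric(1))
  expect_true(all(rhos > 0.45 & rhos < 0.75))
  expect_lt(abs(mean(rhos) - 0.6), 0.1)
})

test_that("coincidence odds ratio reproduces the arithmetic identity", {
  # table (10, 2, 3, 15): OR = (10*15)/(2*3) = 25
  calls_a <- c(rep("up", 12), rep("down", 18))
  calls_b <- c(rep("up", 10), rep("down", 2), rep("up", 3), rep("down", 15))
  g <- sprintf("g%02d", 1:30)
  a <- fake_deg(g, ifelse(calls_a == "up", 2, -2), call = calls_a)
  b <- fake_deg(g, ifelse(calls_b == "up", 2, -2), call = calls_b)
  ct <- coincidence_odds_ratio(a, b)
  expect_equal(unname(ct$counts), c(10, 2, 3, 15))
  expect_equal(ct$odds_ratio, 25)
  expect_false(ct$corrected)
  # Fisher p matches the exhaustive hypergeometric enumeration oracle
  expect_equal(ct$p, fisher.test(matrix(c(10, 3, 2, 15), 2))$p.value,
               tolerance = 1e-10)
  # transpose symmetry of the OR
  ct_t <- coincidence_odds_ratio(b, a)
  expect_equal(ct_t$odds_ratio, ct$odds_ratio)
  # zero cell: Haldane-Anscombe correction keeps the OR finite
  calls_b2 <- c(rep("up", 12), rep("down", 18))
  b2 <- fake_deg(g, ifelse(calls_b2 == "up", 2, -2), call = calls_b2)
  ct2 <- coincidence_odds_ratio(a, b2)
  expect_true(ct2$corrected && is.finite(ct2$odds_ratio))
  # genes called none in either table are excluded
  b3 <- b
  b3$table$call[1] <- "none"
  expect_equal(coincidence_odds_ratio(a, b3)$n, 29)
})

test_that("package Fisher p matches fisher.test over random small tables", {
  set.seed(62)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(10:30, 1), rep(0.25, 4)))
    p_pkg <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    p_ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("independent random signs give log-OR near zero", {
  set.seed(63)
  reps <- replicate(40, {
    g <- sprintf("g%04d", 1:400)
    ca <- sample(c("up", "down"), 400, TRUE)
    cb <- sample(c("up", "down"), 400, TRUE)
    ct <- coincidence_odds_ratio(
      fake_deg(g, ifelse(ca == "up", 2, -2), call = ca),
      fake_deg(g, ifelse(cb == "up", 2, -2), call = cb))
    c(log(ct$odds_ratio), ct$log_or_se)
  })
  # delta-method oracle: log OR is within 3 SE of 0 for almost all draws
  expect_gt(mean(abs(reps[1, ]) <= 3 * reps[2, ]), 0.9)
})

test_that("odds-ratio time course peaks where the disease matches", {
  cfg <- clean_config(seed = 65, n_genes = 600,
                      motifs = c(metabolism_down_unrescued = 150,
                                 inflammation_transient = 150))
  ds <- simulate_timecourse(cfg)
  degs <- deg_by_day(ds$expression)
  # disease constructed to equal the day-1 culture signature exactly
  disease <- compute_deg(ds$expression, contrast_spec("M_C", 1))
  series <- odds_ratio_timecourse(degs, disease)
  expect_equal(series$day, sort(series$day))
  expect_equal(series$odds_ratio[series$day == 1],
               max(series$odds_ratio, na.rm = TRUE))
  expect_error(odds_ratio_timecourse(degs[1], disease), ">= 2 days")
})

test_that("orthologue mapping keeps one-to-one pairs only", {
  g_a <- sprintf("a%02d", 1:20)
  g_b <- sprintf("b%02d", 1:20)
  a <- fake_deg(g_a, seq(-2, 2, length.out = 20))
  b <- fake_deg(g_b, seq(2, -2, length.out = 20))
  map <- data.frame(gene_a = g_a, gene_b = g_b)
  pairs <- map_orthologs(a, b, map)
  expect_equal(nrow(pairs), 20)
  expect_equal(attr(pairs, "n_many_to_many"), 0)
  # identity map on the same gene space pairs every gene
  pairs_id <- map_orthologs(a, a, data.frame(gene_a = g_a, gene_b = g_a))
  expect_equal(nrow(pairs_id), 20)
  # duplicated A-gene entries are dropped entirely
  map_dup <- rbind(map, data.frame(gene_a = "a01", gene_b = "b99"))
  pairs_dup <- map_orthologs(a, b, map_dup)
  expect_false("a01" %in% pairs_dup$gene_a)
  expect_equal(attr(pairs_dup, "n_many_to_many"), 2)
  # unmatched genes are counted
  map_ghost <- rbind(map, data.frame(gene_a = "aXX", gene_b = "bXX"))
  expect_equal(attr(map_orthologs(a, b, map_ghost), "n_unmatched"), 1)
  expect_error(map_orthologs(a, b, data.frame(gene_a = "zz", gene_b = "yy")),
               "resolve")
})

test_that("quadrant labels follow the definition and partition all pairs", {
  pairs <- data.frame(
    gene_a = sprintf("a%d", 1:6), gene_b = sprintf("b%d", 1:6),
    log2fc_a = c(1.58, -1.2, 1.2, 0.5, -1.5, 1.0),
    log2fc_b = c(1.32, -2.0, -1.2, 3.0, 1.7, 0.2))
  q <- assign_quadrants(pairs)
  expect_equal(as.character(q$quadrant),
               c("Q1", "Q3", "Q4", "unassigned", "Q2", "unassigned"))
  expect_equal(sum(table(q$quadrant)), nrow(pairs))
})

test_that("planted discordant genes land in Q2/Q4 with motif enrichment", {
  cfg <- clean_config(seed = 71, n_genes = 800,
                      motifs = c(metabolism_down_unrescued = 150,
                                 inflammation_persistent = 150),
                      timepoints = c(0, 1))
  cfg$ortholog_discordant_fraction <- 0.1
  pair <- simulate_species_pair(cfg)
  deg_a <- compute_deg(pair$a$expression, contrast_spec("M_C", 1))
  deg_b <- compute_deg(pair$b$expression, contrast_spec("M_C", 1))
  pairs <- map_orthologs(deg_a, deg_b, pair$a$ortholog_map)
  q <- assign_quadrants(pairs)
  lab <- setNames(as.character(q$quadrant), q$gene_a)
  truth <- pair$a$truth
  disc <- pair$a$ortholog_map$gene_a[pair$a$ortholog_map$discordant]
  # discordant metabolism genes: A down, B up -> Q2; discordant
  # inflammation: A up, B down -> Q4
  disc_met <- intersect(disc, names(truth)[truth ==
                                             "metabolism_down_unrescued"])
  disc_inf <- intersect(disc, names(truth)[truth ==
                                             "inflammation_persistent"])
  expect_gt(mean(lab[disc_met] == "Q2"), 0.9)
  expect_gt(mean(lab[disc_inf] == "Q4"), 0.9)
  # concordant effect genes land in Q1/Q3
  conc_met <- setdiff(names(truth)[truth == "metabolism_down_unrescued"],
                      disc)
  expect_gt(mean(lab[conc_met] == "Q3"), 0.9)
  # motif enrichment per quadrant
  coll <- gene_set_collection(
    list(metabolism = names(truth)[truth == "metabolism_down_unrescued"],
         inflammation = names(truth)[truth == "inflammation_persistent"]),
    names(truth))
  enr <- quadrant_enrichment(q, coll)
  expect_lt(enr$p_adj[enr$quadrant == "Q2" & enr$set == "metabolism"], 0.05)
  expect_lt(enr$p_adj[enr$quadrant == "Q4" & enr$set == "inflammation"],
            0.05)
  expect_lt(enr$p_adj[enr$quadrant == "Q3" & enr$set == "metabolism"], 0.05)
  expect_lt(enr$p_adj[enr$quadrant == "Q1" & enr$set == "inflammation"],
            0.05)
})

test_that("quadrant metagenes select by rank sum and score correctly", {
  cfg <- clean_config(seed = 73, n_genes = 400,
                      motifs = c(inflammation_persistent = 100),
                      timepoints = c(0, 1))
  pair <- simulate_species_pair(cfg)
  deg_a <- compute_deg(pair$a$expression, contrast_spec("M_C", 1))
  deg_b <- compute_deg(pair$b$expression, contrast_spec("M_C", 1))
  pairs <- map_orthologs(deg_a, deg_b, pair$a$ortholog_map)
  q <- assign_quadrants(pairs)
  mg <- quadrant_metagenes(q, pair$a$expression, pair$b$expression, k = 10)
  expect_true("Q1" %in% names(mg))
  # brute-force rank-sum oracle for the selection
  sub <- q[q$quadrant == "Q1", ]
  rs <- rank(-abs(sub$log2fc_a)) + rank(-abs(sub$log2fc_b))
  oracle <- sub$gene_a[order(rs, sub$gene_a)][1:10]
  expect_equal(mg$Q1$genes_a, oracle)
  # Q1 metagene is positive in both species' day-1 culture groups
  sa <- mg$Q1$scores_a
  sb <- mg$Q1$scores_b
  expect_gt(sa$score[sa$group == "M_C|1"], 0)
  expect_gt(sb$score[sb$group == "M_C|1"], 0)
  # k larger than the quadrant uses the whole quadrant
  mg_all <- quadrant_metagenes(q, pair$a$expression, pair$b$expression,
                               k = 10000)
  expect_equal(sort(mg_all$Q1$genes_a), sort(sub$gene_a))
})

test_that("deg tables survive the TSV round trip for concordance input", {
  cfg <- clean_config(seed = 74, n_genes = 80,
                      motifs = c(cellcycle = 20), timepoints = c(0, 1, 2))
  ds <- simulate_timecourse(cfg)
  deg <- compute_deg(ds$expression, contrast_spec("M_C", 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_deg_tsv(deg, path)
  back <- read_deg_tsv(path)
  expect_equal(back$table$log2fc, deg$table$log2fc, tolerance = 1e-10)
  expect_equal(back$table$call, deg$table$call)
  expect_equal(back$contrast$condition, "M_C")
  expect_equal(back$contrast$day, 1)
})
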