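test_that("generators are deterministic given the seed", {
  st1 <- small_study(seed = 3)
  st2 <- small_study(seed = 3)
  expect_identical(st1$interactions, st2$interactions)
  expect_identical(st1$profiles[[2]]$values, st2$profiles[[2]]$values)
  expect_identical(unclass(st1$gene_sets), unclass(st2$gene_sets))
  expect_identical(st1$features, st2$features)
  st3 <- small_study(seed = 4)
  expect_false(identical(st1$interactions$pairs, st3$interactions$pairs))
})

test_that("planted pairs share at least 3 miRNAs by construction", {
  gi <- generate_interactions(synthetic_config(
    seed = 2, n_genes = 60, n_mirnas = 50, targets_per_gene = 8,
    n_planted_pairs = 2, n_planted_cliques = 1, clique_size = 4))
  targets <- split(gi$interactions$pairs$mirna, gi$interactions$pairs$gene)
  pl <- gi$truth$planted_edges
  shared <- vapply(seq_len(nrow(pl)), function(i) {
    length(intersect(targets[[pl$gene_a[i]]], targets[[pl$gene_b[i]]]))
  }, integer(1))
  expect_true(all(shared >= 3))
})

test_that("non-planted pairs share miRNAs at the random-assignment rate", {
  cfg <- synthetic_config(seed = 9, n_genes = 200, n_mirnas = 100,
                          targets_per_gene = 10, n_planted_pairs = 0,
                          n_planted_cliques = 0)
  gi <- generate_interactions(cfg)
  targets <- split(gi$interactions$pairs$mirna, gi$interactions$pairs$gene)
  genes <- names(targets)
  set.seed(1)
  idx <- cbind(sample(length(genes), 1000, replace = TRUE),
               sample(length(genes), 1000, replace = TRUE))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  shared <- vapply(seq_len(nrow(idx)), function(i) {
    length(intersect(targets[[idx[i, 1]]], targets[[idx[i, 2]]]))
  }, integer(1))
  # hypergeometric expectation t * n / m with matching standard error
  t <- cfg$targets_per_gene; m <- cfg$n_mirnas
  expected <- t * t / m
  v <- t * (t / m) * ((m - t) / m) * ((m - t) / (m - 1))
  se <- sqrt(v / length(shared))
  expect_lt(abs(mean(shared) - expected), 3 * se)
})

test_that("planted-pair correlations converge to the configured rho", {
  cfg <- synthetic_config(seed = 21, n_genes = 80, n_mirnas = 60,
                          n_samples = 1000, targets_per_gene = 9,
                          n_planted_pairs = 20, n_planted_cliques = 0,
                          rho = 0.8)
  gi <- generate_interactions(cfg)
  pr <- generate_expression(cfg, gi$truth, 1)
  pl <- gi$truth$planted_pairs
  r <- vapply(seq_len(nrow(pl)), function(i) {
    cor(pr$values[pl$gene_a[i], ], pr$values[pl$gene_b[i], ])
  }, numeric(1))
  expect_true(all(abs(r - 0.8) < 0.05))
  # Fisher-z band at n = 200
  cfg2 <- synthetic_config(seed = 22, n_genes = 80, n_mirnas = 60,
                           n_samples = 200, targets_per_gene = 9,
                           n_planted_pairs = 20, n_planted_cliques = 0,
                           rho = 0.8)
  gi2 <- generate_interactions(cfg2)
  pr2 <- generate_expression(cfg2, gi2$truth, 1)
  pl2 <- gi2$truth$planted_pairs
  r2 <- vapply(seq_len(nrow(pl2)), function(i) {
    cor(pr2$values[pl2$gene_a[i], ], pr2$values[pl2$gene_b[i], ])
  }, numeric(1))
  se <- (1 - 0.8^2) / sqrt(200)
  # per-pair 3-SE band holds for the vast majority; the mean is tighter
  expect_gte(mean(abs(r2 - 0.8) < 3 * se), 0.9)
  expect_lt(abs(mean(r2) - 0.8), 3 * se / sqrt(length(r2)) + 0.01)
})

test_that("non-planted genes are uncorrelated noise", {
  cfg <- synthetic_config(seed = 31, n_genes = 100, n_mirnas = 60,
                          n_samples = 200, targets_per_gene = 9,
                          n_planted_pairs = 5, n_planted_cliques = 0)
  gi <- generate_interactions(cfg)
  pr <- generate_expression(cfg, gi$truth, 1)
  free <- setdiff(rownames(pr$values),
                  c(unlist(gi$truth$planted_groups), "DICER1"))
  cm <- cor(t(pr$values[free[1:40], ]))
  offdiag <- cm[upper.tri(cm)]
  # null correlation at n = 200: |r| < 0.25 except with probability << 1%
  expect_gt(mean(abs(offdiag) < 0.25), 0.99)
})

test_that("Dicer-low samples show stronger planted co-expression", {
  cfg <- synthetic_config(seed = 41, n_genes = 200, n_mirnas = 80,
                          n_samples = 100, targets_per_gene = 9,
                          n_planted_pairs = 50, n_planted_cliques = 0,
                          dicer_effect = 0.5)
  gi <- generate_interactions(cfg)
  pr <- generate_expression(cfg, gi$truth, 1)
  res <- dicer_stratified_coexpression(pr, gi$truth$planted_edges, "DICER1")
  expect_gt(res$mean_r_low, res$mean_r_high)
})

test_that("pathway and feature generators have the configured shape", {
  st <- small_study(seed = 5)
  expect_length(st$gene_sets, 8L)
  expect_true(all(lengths(st$gene_sets) == 30L))
  planted <- unique(unlist(st$truth$planted_groups))
  in_pw <- planted %in% unlist(st$gene_sets)
  expect_true(all(in_pw))  # pathway_planted_fraction = 1
  expect_setequal(names(st$features),
                  c("gene", "transcript_length", "exon_count",
                    "conservation_score"))
  expect_true(all(st$features$transcript_length > 0))
  expect_true(all(st$features$exon_count >= 1))
})

test_that("a full study wires profiles, diseases and truth together", {
  st <- small_study(seed = 6, n_profiles = 7, n_diseases = 4)
  expect_length(st$profiles, 7L)
  diseases <- vapply(st$profiles, `[[`, character(1), "disease")
  expect_length(unique(diseases), 4L)
  expect_equal(nrow(st$truth$activity), nrow(st$truth$planted_edges))
  expect_true(all(vapply(st$profiles, function(p) "DICER1" %in% p$genes,
                         logical(1))))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(targets_per_gene = 500, n_mirnas = 100),
               "exceed")
  expect_error(synthetic_config(n_genes = 20, n_planted_pairs = 50),
               "not enough genes")
  expect_error(synthetic_config(rho = 1.2), "rho")
  expect_error(synthetic_config(targets_per_gene = 2), ">= 3")
})

test_that("a written study re-reads through the standard readers", {
  st <- small_study(seed = 8, n_profiles = 3, n_diseases = 2)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  tab <- read_interactions(file.path(dir, "interactions.tsv"))
  expect_equal(tab$m, st$interactions$m)
  expect_equal(nrow(tab$pairs), nrow(st$interactions$pairs))
  manifest <- yaml::read_yaml(file.path(dir, "profiles.yaml"))$profiles
  pr <- read_expression(file.path(dir, manifest[[1]]$path),
                        profile_id = manifest[[1]]$profile_id)
  expect_equal(dim(pr$values), dim(st$profiles[[1]]$values))
  expect_equal(pr$values, st$profiles[[1]]$values, tolerance = 1e-5)
  sets <- read_gene_sets(file.path(dir, "pathways.gmt"))
  expect_identical(unclass(sets), unclass(st$gene_sets))
})
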