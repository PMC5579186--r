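#' Configuration for a synthetic ceRNA study
#'
#' Defines the generative conditions for a multi-profile study with planted
#' ceRNA structure: a bipartite miRNA-target table in which planted gene
#' pairs are guaranteed a block of shared miRNAs, expression profiles in
#' which those pairs are positively co-expressed through a shared latent
#' factor, pathway gene sets overlapping the planted network, and a
#' Dicer-proxy gene whose level attenuates planted-pair correlation.
#'
#' Defaults mirror a desk-scale multi-disease microarray compendium: 21
#' profiles over 8 disease labels, 386 miRNAs, 2,000 genes with ~30 targets
#' each, 100 samples per profile, planted correlation 0.8, and 16 pathway
#' sets of 62 genes.
#'
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param n_mirnas,n_genes,n_samples,n_profiles study dimensions.
#' @param n_diseases number of disease labels assigned round-robin.
#' @param targets_per_gene miRNAs targeting each gene (>= 3).
#' @param n_planted_pairs number of planted ceRNA pairs (disjoint genes).
#' @param n_planted_cliques,clique_size planted ceRNA cliques: groups of
#'   `clique_size` genes sharing one latent factor and one miRNA block, so
#'   all within-group pairs become ceRNA edges (the raw material for
#'   module discovery).
#' @param rho population correlation of planted pairs, in (0, 1).
#' @param noise_sd expression noise standard deviation.
#' @param dicer_effect correlation attenuation in the Dicer-high sample
#'   group: effective correlation there is `rho * (1 - dicer_effect)`.
#' @param n_pathways,pathway_size pathway collection dimensions.
#' @param pathway_planted_fraction fraction of planted genes placed into at
#'   least one pathway.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_mirnas = 386, n_genes = 2000,
                             n_samples = 100, n_profiles = 21, n_diseases = 8,
                             targets_per_gene = 30, n_planted_pairs = 150,
                             n_planted_cliques = 1, clique_size = 12,
                             rho = 0.8, noise_sd = 1, dicer_effect = 0,
                             n_pathways = 16, pathway_size = 62,
                             pathway_planted_fraction = 1) {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_profiles = as.integer(n_profiles),
              n_diseases = as.integer(n_diseases),
              targets_per_gene = as.integer(targets_per_gene),
              n_planted_pairs = as.integer(n_planted_pairs),
              n_planted_cliques = as.integer(n_planted_cliques),
              clique_size = as.integer(clique_size),
              rho = rho, noise_sd = noise_sd, dicer_effect = dicer_effect,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              pathway_planted_fraction = pathway_planted_fraction)
  if (cfg$targets_per_gene < 3) stop("targets_per_gene must be >= 3")
  if (cfg$targets_per_gene > cfg$n_mirnas) {
    stop("targets_per_gene cannot exceed n_mirnas")
  }
  if (cfg$n_planted_cliques > 0 && cfg$clique_size < 3) {
    stop("clique_size must be >= 3")
  }
  n_planted_genes <- 2L * cfg$n_planted_pairs +
    cfg$n_planted_cliques * cfg$clique_size
  if (n_planted_genes > cfg$n_genes) {
    stop("not enough genes for the requested planted structure")
  }
  if (cfg$rho <= 0 || cfg$rho >= 1) stop("rho must lie in (0, 1)")
  if (cfg$dicer_effect < 0 || cfg$rho * (1 - cfg$dicer_effect) < 0) {
    stop("dicer_effect must be in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  structure(cfg, class = "synthetic_config")
}

# evaluate code under a temporary RNG seed, restoring the caller's stream;
# each generator uses seed + a fixed stage offset so adding a generator
# never perturbs earlier outputs
with_stage_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

synthetic_gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))
synthetic_mirna_ids <- function(cfg) sprintf("mir%04d", seq_len(cfg$n_mirnas))

canonical_pairs <- function(a, b) {
  out <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

# all unordered pairs within a member vector, canonical order
group_edges <- function(members) {
  cmb <- utils::combn(sort(members), 2)
  canonical_pairs(cmb[1, ], cmb[2, ])
}

#' Generate a miRNA-target table with planted shared-target structure
#'
#' Planted groups (pairs, and optionally larger cliques) receive a shared
#' block of miRNAs first (two thirds of `targets_per_gene`, at least 3),
#' then independent remainders; all other genes draw their targets
#' uniformly. Every within-group pair therefore shares at least 3 miRNAs.
#' Deterministic given the seed.
#'
#' @param cfg a [synthetic_config].
#' @return list with `interactions` (an `interaction_table`) and `truth`:
#'   `planted_pairs` (the disjoint two-gene groups), `planted_cliques`
#'   (list of member vectors), `planted_groups` (all groups),
#'   `planted_edges` (every within-group pair), `dicer_gene_id`,
#'   `shared_block`.
#' @export
generate_interactions <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_gene_ids(cfg)
  mirnas <- synthetic_mirna_ids(cfg)
  shared_block <- max(3L, as.integer(round(2 * cfg$targets_per_gene / 3)))
  n_clique_genes <- cfg$n_planted_cliques * cfg$clique_size
  with_stage_seed(cfg$seed + 1L, {
    planted_genes <- sample(genes, 2L * cfg$n_planted_pairs + n_clique_genes)
    pair_genes <- planted_genes[seq_len(2L * cfg$n_planted_pairs)]
    groups <- lapply(seq_len(cfg$n_planted_pairs), function(i) {
      pair_genes[c(2L * i - 1L, 2L * i)]
    })
    cliques <- list()
    if (cfg$n_planted_cliques > 0) {
      clique_genes <- planted_genes[2L * cfg$n_planted_pairs +
                                      seq_len(n_clique_genes)]
      cliques <- split(clique_genes,
                       rep(seq_len(cfg$n_planted_cliques),
                           each = cfg$clique_size))
      cliques <- lapply(unname(cliques), sort)
      groups <- c(groups, cliques)
    }
    target_sets <- vector("list", cfg$n_genes)
    names(target_sets) <- genes
    for (grp in groups) {
      shared <- sample(mirnas, shared_block)
      rest <- setdiff(mirnas, shared)
      extra <- cfg$targets_per_gene - shared_block
      for (g in grp) target_sets[[g]] <- c(shared, sample(rest, extra))
    }
    for (g in setdiff(genes, planted_genes)) {
      target_sets[[g]] <- sample(mirnas, cfg$targets_per_gene)
    }
    pairs <- data.frame(
      mirna = unlist(target_sets, use.names = FALSE),
      gene = rep(genes, times = lengths(target_sets)),
      stringsAsFactors = FALSE
    )
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
    planted <- if (cfg$n_planted_pairs > 0) {
      do.call(rbind, lapply(groups[seq_len(cfg$n_planted_pairs)], group_edges))
    } else {
      empty
    }
    planted <- planted[order(planted$gene_a, planted$gene_b), ]
    rownames(planted) <- NULL
    all_edges <- if (length(groups)) {
      do.call(rbind, lapply(groups, group_edges))
    } else {
      empty
    }
    all_edges <- all_edges[order(all_edges$gene_a, all_edges$gene_b), ]
    rownames(all_edges) <- NULL
    truth <- list(planted_pairs = planted, planted_cliques = cliques,
                  planted_groups = groups, planted_edges = all_edges,
                  dicer_gene_id = "DICER1", shared_block = shared_block)
    list(interactions = interaction_table(pairs), truth = truth)
  })
}

#' Generate one expression profile with planted co-expression
#'
#' Each planted pair draws both genes from a shared latent factor,
#' \eqn{x = \sqrt{\rho_{\mathrm{eff}}} z + \sqrt{1 - \rho_{\mathrm{eff}}}\,
#' \epsilon}, so their population correlation is exactly
#' \eqn{\rho_{\mathrm{eff}}}. Samples belong to a Dicer-low or Dicer-high
#' group (bimodal Dicer-proxy expression); in the high group
#' \eqn{\rho_{\mathrm{eff}} = \rho (1 - \mathrm{dicer\_effect})}. All other
#' genes are independent Gaussian noise. Values are on a log2-like scale
#' (baseline 7).
#'
#' @param cfg a [synthetic_config].
#' @param truth truth list from [generate_interactions].
#' @param profile_index which profile (1-based); determines the RNG stream.
#' @param disease,platform metadata attached to the profile.
#' @return an [expression_profile] including the Dicer-proxy gene row.
#' @export
generate_expression <- function(cfg, truth, profile_index, disease = "",
                                platform = "synthetic") {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_gene_ids(cfg)
  ns <- cfg$n_samples
  with_stage_seed(cfg$seed + 1000L + profile_index, {
    group <- rep_len(c(0L, 1L), ns)  # 0 = Dicer-low, 1 = Dicer-high
    rho_eff <- cfg$rho * (1 - cfg$dicer_effect * group)
    vals <- matrix(stats::rnorm(cfg$n_genes * ns, sd = cfg$noise_sd),
                   nrow = cfg$n_genes, dimnames = list(genes, NULL))
    for (grp in truth$planted_groups) {
      z <- stats::rnorm(ns)
      for (g in grp) {
        vals[g, ] <- cfg$noise_sd *
          (sqrt(rho_eff) * z + sqrt(1 - rho_eff) * stats::rnorm(ns))
      }
    }
    dicer <- 5 + 4 * group + stats::rnorm(ns, sd = 0.2)
    vals <- rbind(vals + 7, DICER1 = dicer)
    colnames(vals) <- sprintf("S%03d", seq_len(ns))
    expression_profile(vals, profile_id = sprintf("profile%02d", profile_index),
                       disease = disease, platform = platform)
  })
}

#' Generate pathway gene sets overlapping the planted network
#'
#' A configurable fraction of planted genes is placed into pathways; for
#' each placed planted pair, both genes land in the same pathway with
#' probability 1/2 (future within-pathway pairs) and in two different
#' pathways otherwise (between-pathway pairs). Remaining slots are filled
#' with other genes so every set has exactly `pathway_size` members.
#'
#' @param cfg a [synthetic_config].
#' @param truth truth list from [generate_interactions].
#' @return a `gene_set_collection` of `n_pathways` sets.
#' @export
generate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_gene_ids(cfg)
  pw_names <- sprintf("pathway%02d", seq_len(cfg$n_pathways))
  with_stage_seed(cfg$seed + 2L, {
    sets <- stats::setNames(vector("list", cfg$n_pathways), pw_names)
    for (nm in pw_names) sets[[nm]] <- character(0)
    pl <- truth$planted_pairs
    use <- stats::runif(nrow(pl)) < cfg$pathway_planted_fraction
    for (i in which(use)) {
      if (stats::runif(1) < 0.5) {
        pw <- sample(pw_names, 1)
        sets[[pw]] <- union(sets[[pw]], c(pl$gene_a[i], pl$gene_b[i]))
      } else {
        pw <- sample(pw_names, 2)
        sets[[pw[1]]] <- union(sets[[pw[1]]], pl$gene_a[i])
        sets[[pw[2]]] <- union(sets[[pw[2]]], pl$gene_b[i])
      }
    }
    # each planted clique lands whole in one pathway so module discovery
    # among pathway-mapped genes can recover it
    for (cl in truth$planted_cliques) {
      pw <- sample(pw_names, 1)
      sets[[pw]] <- union(sets[[pw]], cl)
    }
    planted_genes <- unique(unlist(truth$planted_groups))
    filler <- setdiff(genes, planted_genes)
    for (nm in pw_names) {
      need <- cfg$pathway_size - length(sets[[nm]])
      if (need > 0) {
        sets[[nm]] <- c(sets[[nm]], sample(setdiff(filler, sets[[nm]]), need))
      } else if (need < 0) {
        sets[[nm]] <- sets[[nm]][seq_len(cfg$pathway_size)]
      }
    }
    gene_set_collection(sets)
  })
}

#' Generate a transcript feature table
#'
#' Lengths are log-normal, exon counts shifted Poisson, conservation scores
#' uniform; genes participating in planted ceRNA pairs are drawn longer,
#' with more exons and higher conservation, reflecting the tendency of
#' cross-talk transcripts to carry more miRNA response elements.
#'
#' @param cfg a [synthetic_config].
#' @param truth truth list from [generate_interactions].
#' @return data.frame `gene`, `transcript_length`, `exon_count`,
#'   `conservation_score`.
#' @export
generate_transcript_features <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- synthetic_gene_ids(cfg)
  planted <- genes %in% unique(unlist(truth$planted_groups))
  with_stage_seed(cfg$seed + 3L, {
    len <- round(stats::rlnorm(cfg$n_genes, meanlog = log(1500), sdlog = 0.5))
    len[planted] <- round(len[planted] * 1.6)
    ex <- 1L + stats::rpois(cfg$n_genes, 5)
    ex[planted] <- ex[planted] + stats::rpois(sum(planted), 3)
    cons <- stats::runif(cfg$n_genes, 0, 0.8)
    cons[planted] <- pmin(1, cons[planted] + 0.15)
    data.frame(gene = genes, transcript_length = pmax(len, 100L),
               exon_count = ex, conservation_score = cons,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study
#'
#' Wires all generators under one seed: interaction table, `n_profiles`
#' expression profiles with disease labels assigned round-robin over
#' `n_diseases`, pathway sets, transcript features and the ground truth.
#' Planted pairs are active in every profile.
#'
#' @param cfg a [synthetic_config].
#' @return list with `interactions`, `profiles` (list of
#'   [expression_profile]), `gene_sets`, `features`, `truth`, `config`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gi <- generate_interactions(cfg)
  truth <- gi$truth
  diseases <- sprintf("disease%02d", rep_len(seq_len(cfg$n_diseases),
                                             cfg$n_profiles))
  truth$profile_diseases <- diseases
  truth$activity <- matrix(TRUE, nrow = nrow(truth$planted_edges),
                           ncol = cfg$n_profiles)
  profiles <- lapply(seq_len(cfg$n_profiles), function(i) {
    generate_expression(cfg, truth, i, disease = diseases[i])
  })
  gene_sets <- generate_pathways(cfg, truth)
  features <- generate_transcript_features(cfg, truth)
  list(interactions = gi$interactions, profiles = profiles,
       gene_sets = gene_sets, features = features, truth = truth, config = cfg)
}

#' Write a synthetic study to a fixture directory
#'
#' Emits the interaction TSV, one expression TSV per profile, the pathway
#' GMT, the transcript feature TSV, a planted-pair truth TSV and a profile
#' manifest (YAML) so the study can be re-read through the standard readers.
#'
#' @param study output of [generate_study].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(study$interactions$pairs,
                     file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- lapply(study$profiles, function(p) {
    f <- paste0(p$profile_id, ".tsv")
    tab <- data.frame(gene = rownames(p$values), p$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(path = f, profile_id = p$profile_id, disease = p$disease,
         platform = p$platform, log2 = TRUE)
  })
  yaml::write_yaml(list(profiles = manifest), file.path(dir, "profiles.yaml"))
  write_gene_sets(study$gene_sets, file.path(dir, "pathways.gmt"))
  utils::write.table(study$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$planted_pairs,
                     file.path(dir, "planted_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
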