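#' Pipeline run configuration
#'
#' Collects every threshold of the analysis in one validated object. Either
#' `simulate` (a [synthetic_config]) or `inputs` (paths to an interaction
#' TSV, a profile manifest, a GMT file and optionally a feature TSV) must
#' be supplied.
#'
#' @param seed integer seed for all stochastic steps.
#' @param out_dir report directory.
#' @param simulate optional [synthetic_config] (or list of its arguments).
#' @param inputs optional list with elements `interactions`, `profiles`
#'   (list of `path`/`profile_id`/`disease`/`platform`/`log2` entries),
#'   `gene_sets`, `features`, `dicer_gene`.
#' @param min_shared minimum shared miRNA count for a candidate pair.
#' @param alpha_holm Holm-adjusted cut-off for the hypergeometric test.
#' @param alpha_p Pearson p-value cut-off.
#' @param top_frac hub fraction.
#' @param simpson_threshold neighbor-overlap threshold for common hubs.
#' @param core_min minimum occurrence count for a core edge.
#' @param community_min,community_max retained modularity community sizes.
#' @param k clique percolation parameter.
#' @param n_permutations permutations for similarity p-values (0 = none).
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = "cerna_report", simulate = NULL,
                       inputs = NULL, min_shared = 3, alpha_holm = 0.01,
                       alpha_p = 0.01, top_frac = 0.10,
                       simpson_threshold = 0.8, core_min = 16,
                       community_min = 4, community_max = 299, k = 3,
                       n_permutations = 0) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("run_config needs either simulation settings or input paths")
  }
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config")) {
    simulate <- do.call(synthetic_config, simulate)
  }
  stopifnot(min_shared >= 1, alpha_holm > 0, alpha_holm <= 1, alpha_p >= 0,
            alpha_p <= 1, top_frac > 0, top_frac <= 1, simpson_threshold >= 0,
            simpson_threshold <= 1, core_min >= 1, community_min >= 1,
            community_max >= community_min, k >= 3, n_permutations >= 0)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, simulate = simulate,
         inputs = inputs, min_shared = min_shared, alpha_holm = alpha_holm,
         alpha_p = alpha_p, top_frac = top_frac,
         simpson_threshold = simpson_threshold, core_min = as.integer(core_min),
         community_min = as.integer(community_min),
         community_max = as.integer(community_max), k = as.integer(k),
         n_permutations = as.integer(n_permutations)),
    class = "run_config"
  )
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- config$seed
    study <- generate_study(do.call(synthetic_config, unclass(cfg)))
    study$dicer_gene <- study$truth$dicer_gene_id
    return(study)
  }
  inp <- config$inputs
  interactions <- read_interactions(inp$interactions,
                                    header = isTRUE(inp$header))
  profiles <- lapply(inp$profiles, function(pr) {
    read_expression(pr$path, profile_id = pr$profile_id,
                    disease = pr$disease,
                    platform = if (is.null(pr$platform)) "" else pr$platform,
                    log2_transform = !isTRUE(pr$log2))
  })
  gene_sets <- read_gene_sets(inp$gene_sets)
  features <- if (!is.null(inp$features)) {
    read_transcript_features(inp$features)
  }
  list(interactions = interactions, profiles = profiles,
       gene_sets = gene_sets, features = features, truth = NULL,
       dicer_gene = inp$dicer_gene)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end ceRNA analysis
#'
#' Orchestrates the full study: acquire inputs (simulated or read from
#' disk), enumerate candidate pairs, build one ceRNA network per profile,
#' merge by disease and globally, characterize topology, compute the
#' Simpson similarity matrix and conserved core, classify hubs, discover
#' common modules by clique percolation, classify pathway cross-talk pairs
#' and compare transcript features. Every stage writes its table under the
#' report directory; a machine-readable `summary.json` collects all counts.
#' Deterministic given the seed.
#'
#' @param config a [run_config].
#' @return the summary list, invisibly; side effect: the report directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  summary <- list(seed = config$seed)

  data <- run_stage("inputs", load_pipeline_inputs(config))
  if (!is.null(data$truth)) {
    utils::write.table(data$truth$planted_pairs,
                       file.path(out, "planted_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary$n_profiles <- length(data$profiles)
  summary$n_mirnas <- data$interactions$m
  summary$n_genes_interactions <- length(unique(data$interactions$pairs$gene))

  cand <- run_stage("candidates", candidate_pairs(
    data$interactions, min_shared = config$min_shared,
    alpha_holm = config$alpha_holm))
  utils::write.table(cand, file.path(out, "candidate_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$n_pairs_min_shared <- nrow(cand)
  summary$n_candidate_pairs <- sum(cand$candidate)

  nets <- run_stage("profile_networks", lapply(data$profiles, function(pr) {
    nw <- build_profile_network(pr, cand, alpha_p = config$alpha_p)
    write_network(nw, file.path(out, "networks",
                                paste0("profile-", pr$profile_id, ".tsv")))
    nw
  }))
  names(nets) <- vapply(data$profiles, `[[`, character(1), "profile_id")
  summary$profile_edge_counts <- stats::setNames(
    vapply(nets, function(nw) nrow(nw$edges), integer(1)), names(nets))

  diseases <- vapply(data$profiles, `[[`, character(1), "disease")
  dnets <- run_stage("disease_networks", merge_by_disease(nets, diseases))
  for (nm in names(dnets)) {
    write_network(dnets[[nm]], file.path(out, "networks",
                                         paste0("disease-", nm, ".tsv")))
  }
  global <- run_stage("global_network",
                      merge_networks(nets, "global", level = "global"))
  write_network(global, file.path(out, "networks", "global.tsv"))
  summary$n_disease_networks <- length(dnets)
  summary$n_global_edges <- nrow(global$edges)
  summary$n_global_nodes <- length(global$nodes)

  topo <- run_stage("topology", lapply(nets, function(nw) {
    fit <- tryCatch(fit_power_law(as.numeric(network_degrees(nw))),
                    error = function(e) NULL)
    comm <- detect_communities(nw, min_size = config$community_min,
                               max_size = config$community_max,
                               seed = config$seed)
    list(alpha = if (is.null(fit)) NA_real_ else fit$alpha,
         ks = if (is.null(fit)) NA_real_ else fit$ks_distance,
         n_communities = length(comm$communities))
  }))
  topo_tab <- data.frame(
    profile = names(topo),
    powerlaw_alpha = vapply(topo, `[[`, numeric(1), "alpha"),
    powerlaw_ks = vapply(topo, `[[`, numeric(1), "ks"),
    n_communities = vapply(topo, `[[`, integer(1), "n_communities")
  )
  utils::write.table(topo_tab, file.path(out, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$mean_powerlaw_alpha <- mean(topo_tab$powerlaw_alpha, na.rm = TRUE)

  nonempty <- Filter(function(nw) nrow(nw$edges) > 0, nets)
  if (length(nonempty) >= 2) {
    simres <- run_stage("similarity", network_similarity_matrix(
      nets, n_permutations = config$n_permutations,
      universe = edge_keys(cand), seed = config$seed))
    utils::write.table(simres$sim, file.path(out, "similarity.tsv"),
                       sep = "\t", quote = FALSE)
    summary$mean_offdiag_simpson <- mean(simres$sim[upper.tri(simres$sim)])
  }

  occ <- run_stage("edge_counts", edge_profile_counts(nets))
  utils::write.table(occ$counts, file.path(out, "edge_profile_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(nets) >= config$core_min) {
    core <- run_stage("core", extract_core_network(nets, config$core_min))
    write_network(core, file.path(out, "networks", "core.tsv"))
    summary$n_core_edges <- nrow(core$edges)
    summary$n_core_nodes <- length(core$nodes)
  } else {
    core <- NULL
    summary$n_core_edges <- NA_integer_
  }

  hubs <- run_stage("hubs", classify_hubs(
    dnets, top_frac = config$top_frac,
    simpson_threshold = config$simpson_threshold))
  utils::write.table(hubs, file.path(out, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$n_common_hubs <- sum(hubs$category == "common")
  summary$n_differential_hubs <- sum(hubs$category == "differential")
  summary$n_specific_hubs <- sum(hubs$category == "specific")

  common_hub_genes <- hubs$gene[hubs$category == "common"]
  mods <- run_stage("modules", common_modules(
    global, data$gene_sets, common_hub_genes, k = config$k,
    disease_networks = dnets))
  mod_tab <- if (length(mods$modules)) {
    data.frame(module = rep(seq_along(mods$modules),
                            lengths(mods$modules)),
               gene = unlist(mods$modules), stringsAsFactors = FALSE)
  } else {
    data.frame(module = integer(), gene = character())
  }
  utils::write.table(mod_tab, file.path(out, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$n_common_modules <- length(mods$modules)

  pw_net <- run_stage("pathway_pairs", pathway_subnetwork(global,
                                                          data$gene_sets))
  cls <- run_stage("pair_classes", classify_pairs(global$edges,
                                                  data$gene_sets))
  utils::write.table(cls, file.path(out, "pair_pathway_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_pathway_pairs <- nrow(pw_net$edges)
  summary$n_cpwp <- sum(cls$class == "CPWP")
  summary$n_cpbp <- sum(cls$class == "CPBP")

  if (!is.null(data$features) && nrow(pw_net$edges)) {
    pw_genes <- pw_net$nodes
    other <- setdiff(unique(data$interactions$pairs$gene), pw_genes)
    if (length(other)) {
      feat <- run_stage("features", compare_transcript_features(
        pw_genes, other, data$features))
      utils::write.table(feat, file.path(out, "transcript_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$feature_p_length <-
        feat$p_value[feat$feature == "transcript_length"]
    }
  }

  if (!is.null(data$dicer_gene)) {
    dic <- lapply(seq_along(nets), function(i) {
      nw <- nets[[i]]
      if (nrow(nw$edges) < 5) return(NULL)
      tryCatch(dicer_stratified_coexpression(data$profiles[[i]], nw$edges,
                                             data$dicer_gene),
               error = function(e) NULL)
    })
    ok <- !vapply(dic, is.null, logical(1))
    if (any(ok)) {
      summary$dicer_mean_r_low <- mean(vapply(dic[ok], `[[`, numeric(1),
                                              "mean_r_low"))
      summary$dicer_mean_r_high <- mean(vapply(dic[ok], `[[`, numeric(1),
                                               "mean_r_high"))
    }
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
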