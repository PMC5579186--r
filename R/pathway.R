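#' Restrict a network to pathway-annotated edges
#'
#' Keeps exactly the edges whose both endpoints belong to the union of the
#' pathway gene sets. Idempotent.
#'
#' @param network a `cerna_network`.
#' @param gene_sets a `gene_set_collection` (or named list of gene vectors).
#' @return the pathway-mapped `cerna_network`.
#' @export
pathway_subnetwork <- function(network, gene_sets) {
  stopifnot(inherits(network, "cerna_network"))
  pw_genes <- unique(unlist(gene_sets))
  if (!length(pw_genes)) stop("gene sets must be non-empty")
  e <- network$edges
  keep <- e$gene_a %in% pw_genes & e$gene_b %in% pw_genes
  cerna_network(e[keep, , drop = FALSE],
                network_id = paste0(network$network_id, "_pathway"),
                level = network$level)
}

#' Overlapping communities by k-clique percolation
#'
#' Enumerates all k-cliques of the network, joins two cliques when they
#' share k-1 nodes, and returns one community per connected component of
#' that clique-adjacency graph (the CFinder construction). Communities may
#' overlap; every community has at least k members.
#'
#' @param network a `cerna_network` or an undirected igraph graph.
#' @param k clique size (>= 3).
#' @return list of character vectors (sorted member gene ids), ordered by
#'   decreasing size.
#' @export
clique_percolation <- function(network, k = 3) {
  if (k < 3) stop("k must be >= 3")
  g <- if (inherits(network, "cerna_network")) as_igraph(network) else network
  if (igraph::vcount(g) == 0L) return(list())
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl)) return(list())
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(g)))
  members <- lapply(cl, function(x) vnames[as.integer(x)])
  nc <- length(members)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(nc), each = k),
    j = match(unlist(members), vnames),
    x = 1, dims = c(nc, length(vnames))
  )
  shared <- Matrix::tcrossprod(inc)
  trip <- Matrix::summary(shared)
  adj <- trip[trip$i < trip$j & trip$x == k - 1, , drop = FALSE]
  cg <- igraph::graph_from_edgelist(cbind(adj$i, adj$j), directed = FALSE)
  cg <- igraph::add_vertices(cg, nc - igraph::vcount(cg))
  comp <- igraph::components(cg)$membership
  comms <- lapply(split(seq_len(nc), comp), function(ii) {
    sort(unique(unlist(members[ii])))
  })
  comms <- unname(comms)
  comms[order(-lengths(comms), vapply(comms, `[`, character(1), 1))]
}

#' Common modules among pathway-mapped common hubs
#'
#' Restricts the pathway-mapped global network to edges whose both
#' endpoints are common hubs, then finds overlapping modules by k-clique
#' percolation. When disease-level networks are supplied, each module's
#' internal edges are annotated with the number of diseases in which they
#' occur.
#'
#' @param global_network the merged global `cerna_network`.
#' @param gene_sets pathway `gene_set_collection`.
#' @param common_hubs character vector of common hub gene ids.
#' @param k clique percolation parameter.
#' @param disease_networks optional list of disease-level networks for the
#'   per-edge disease counts.
#' @return list with `modules` (as [clique_percolation]) and `edge_tables`
#'   (per module, a data.frame of its internal edges with `n_diseases`, or
#'   NULL when no disease networks are given).
#' @export
common_modules <- function(global_network, gene_sets, common_hubs, k = 3,
                           disease_networks = NULL) {
  sub <- pathway_subnetwork(global_network, gene_sets)
  e <- sub$edges
  e <- e[e$gene_a %in% common_hubs & e$gene_b %in% common_hubs, , drop = FALSE]
  hub_net <- cerna_network(e, network_id = "common_hub_subnetwork",
                           level = "global")
  modules <- clique_percolation(hub_net, k = k)
  edge_tables <- NULL
  if (!is.null(disease_networks) && length(modules)) {
    occ <- edge_profile_counts(disease_networks)$counts
    occ_keys <- edge_keys(occ)
    edge_tables <- lapply(modules, function(mem) {
      me <- hub_net$edges
      me <- me[me$gene_a %in% mem & me$gene_b %in% mem, , drop = FALSE]
      me$n_diseases <- occ$count[match(edge_keys(me), occ_keys)]
      me$n_diseases[is.na(me$n_diseases)] <- 0L
      me
    })
  }
  list(modules = modules, edge_tables = edge_tables)
}

#' Classify gene pairs by pathway membership
#'
#' A pair is a within-pathway cross-talk (CPWP) when some pathway contains
#' both genes; a between-pathway cross-talk (CPBP) when both genes are
#' pathway-annotated but no single pathway holds both; and unclassified
#' when at most one gene is annotated.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param gene_sets pathway `gene_set_collection`.
#' @return `pairs` with `class` (`"CPWP"`, `"CPBP"`, `"unclassified"`) and
#'   `witness` (comma-separated pathways containing both genes, for CPWP)
#'   appended.
#' @export
classify_pairs <- function(pairs, gene_sets) {
  set_names <- names(gene_sets)
  gene2set <- list()
  for (nm in set_names) {
    for (g in gene_sets[[nm]]) gene2set[[g]] <- c(gene2set[[g]], nm)
  }
  cls <- character(nrow(pairs))
  wit <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sa <- gene2set[[pairs$gene_a[i]]]
    sb <- gene2set[[pairs$gene_b[i]]]
    if (is.null(sa) || is.null(sb)) {
      cls[i] <- "unclassified"; wit[i] <- ""
    } else {
      both <- intersect(sa, sb)
      if (length(both)) {
        cls[i] <- "CPWP"; wit[i] <- paste(sort(both), collapse = ",")
      } else {
        cls[i] <- "CPBP"; wit[i] <- ""
      }
    }
  }
  pairs$class <- cls
  pairs$witness <- wit
  pairs
}

#' Normalized degree of pathway genes in a network
#'
#' Degree of each pathway gene present in the network, divided by the
#' maximum degree of that network, giving a `[0, 1]` value comparable
#' across networks of different density.
#'
#' @param network a `cerna_network`.
#' @param gene_sets pathway `gene_set_collection`.
#' @return data.frame `pathway`, `gene`, `degree`, `normalized_degree`
#'   (genes absent from the network are omitted).
#' @export
normalized_pathway_degree <- function(network, gene_sets) {
  deg <- network_degrees(network)
  if (!length(deg)) {
    return(data.frame(pathway = character(), gene = character(),
                      degree = integer(), normalized_degree = numeric()))
  }
  mx <- max(deg)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], names(deg))
    if (!length(gs)) return(NULL)
    data.frame(pathway = nm, gene = gs, degree = as.integer(deg[gs]),
               normalized_degree = as.numeric(deg[gs]) / mx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), gene = character(),
                      degree = integer(), normalized_degree = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric test `P(overlap >= observed)` of a query gene
#' list against each gene set, relative to a gene universe, with BH
#' correction across sets.
#'
#' @param query_genes character vector (must lie within `universe`).
#' @param gene_sets pathway `gene_set_collection`.
#' @param universe character vector of background genes.
#' @return data.frame `pathway`, `set_size`, `overlap`, `p`, `q_bh`.
#' @export
geneset_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(query_genes, set_u))
    p <- hypergeom_pvalue(length(universe), length(set_u),
                          length(query_genes), ov)
    data.frame(pathway = nm, set_size = length(set_u), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Compare transcript features between gene groups
#'
#' One-sided Mann-Whitney U test per feature (group A greater than group
#' B) on transcript length, exon count and conservation score. Genes
#' missing from the feature table are excluded with a message.
#'
#' @param genes_a,genes_b character vectors (e.g. pathway-associated ceRNA
#'   genes vs all other genes).
#' @param features feature table as from [read_transcript_features].
#' @return data.frame `feature`, `median_a`, `median_b`, `p_value`.
#' @export
compare_transcript_features <- function(genes_a, genes_b, features) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  miss <- sum(!c(genes_a, genes_b) %in% features$gene)
  if (miss) message(miss, " genes excluded: no transcript features")
  fa <- features[features$gene %in% genes_a, , drop = FALSE]
  fb <- features[features$gene %in% genes_b, , drop = FALSE]
  if (!nrow(fa) || !nrow(fb)) stop("both groups need genes with features")
  feats <- c("transcript_length", "exon_count", "conservation_score")
  rows <- lapply(feats, function(f) {
    wt <- suppressWarnings(stats::wilcox.test(fa[[f]], fb[[f]],
                                              alternative = "greater"))
    data.frame(feature = f, median_a = stats::median(fa[[f]]),
               median_b = stats::median(fb[[f]]), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
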