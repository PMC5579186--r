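#' Merge ceRNA networks
#'
#' Takes the union of node and edge sets; for an edge present in several
#' input networks the retained statistics come from the constituent with
#' the smallest Pearson p-value (its strongest supporting profile).
#'
#' @param networks list of `cerna_network`s.
#' @param network_id id for the merged network.
#' @param level level tag (`"disease"` or `"global"`).
#' @return a merged `cerna_network`.
#' @export
merge_networks <- function(networks, network_id = "merged", level = "disease") {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "cerna_network")))
  edges <- do.call(rbind, lapply(networks, function(nw) nw$edges))
  if (is.null(edges) || nrow(edges) == 0L) {
    return(cerna_network(NULL, network_id = network_id, level = level))
  }
  ord <- order(edge_keys(edges), edges$p, na.last = TRUE)
  edges <- edges[ord, ]
  edges <- edges[!duplicated(edge_keys(edges)), ]
  cerna_network(edges, network_id = network_id, level = level)
}

#' Group profile networks by disease and merge
#'
#' @param networks list of profile-level `cerna_network`s.
#' @param diseases character vector of disease labels, parallel to
#'   `networks`.
#' @return named list of disease-level `cerna_network`s.
#' @export
merge_by_disease <- function(networks, diseases) {
  stopifnot(length(networks) == length(diseases))
  idx <- split(seq_along(networks), diseases)
  lapply(idx, function(ii) {
    merge_networks(networks[ii], network_id = diseases[ii[1]],
                   level = "disease")
  })
}

#' Simpson (overlap) index of two sets
#'
#' \eqn{|A \cap B| / \min(|A|, |B|)}; 0 when either set is empty. Robust to
#' unequal set sizes, which makes it the similarity of choice when
#' comparing networks of very different density.
#'
#' @param set_a,set_b vectors treated as sets.
#' @return a number in `[0, 1]`.
#' @export
simpson_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) return(0)
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Pairwise Simpson similarity of network edge sets
#'
#' Computes the Simpson index over edge sets for every pair of networks.
#' Optional significance: each network's edge count is resampled uniformly
#' from a shared candidate universe `n_permutations` times and the
#' empirical p-value is `(1 + #{perm >= observed}) / (1 + n_permutations)`.
#'
#' @param networks named list of >= 2 `cerna_network`s.
#' @param n_permutations number of permutations (0 = no p-values).
#' @param universe character vector of candidate edge keys (for example
#'   `paste(gene_a, gene_b, sep = "\t")` over the candidate pairs);
#'   required when `n_permutations > 0`.
#' @param seed RNG seed for the permutations.
#' @return list with `sim` (symmetric matrix, unit diagonal for non-empty
#'   networks) and `p` (matrix or NULL).
#' @export
network_similarity_matrix <- function(networks, n_permutations = 0,
                                      universe = NULL, seed = NULL) {
  stopifnot(length(networks) >= 2)
  ids <- names(networks)
  if (is.null(ids)) ids <- vapply(networks, `[[`, character(1), "network_id")
  keysets <- lapply(networks, function(nw) edge_keys(nw$edges))
  k <- length(networks)
  sim <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    sim[i, i] <- if (length(keysets[[i]])) 1 else 0
    for (j in seq_len(k)[-seq_len(i)]) {
      sim[i, j] <- sim[j, i] <- simpson_index(keysets[[i]], keysets[[j]])
    }
  }
  pmat <- NULL
  if (n_permutations > 0) {
    if (is.null(universe)) stop("permutation p-values need a candidate universe")
    universe <- unique(universe)
    pmat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    perm_one <- function(ni, nj, obs) {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        sa <- sample(universe, min(ni, length(universe)))
        sb <- sample(universe, min(nj, length(universe)))
        if (simpson_index(sa, sb) >= obs) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_permutations)
    }
    run <- function() {
      for (i in seq_len(k)) {
        for (j in seq_len(k)[-seq_len(i)]) {
          pmat[i, j] <<- pmat[j, i] <<- perm_one(length(keysets[[i]]),
                                                 length(keysets[[j]]),
                                                 sim[i, j])
        }
      }
    }
    if (is.null(seed)) run() else with_stage_seed(seed, run())
  }
  list(sim = sim, p = pmat)
}

#' Occurrence count of each edge across networks
#'
#' @param networks list of `cerna_network`s.
#' @return list with `counts` (data.frame `gene_a`, `gene_b`, `count`) and
#'   `histogram` (named table: number of edges per occurrence count).
#' @export
edge_profile_counts <- function(networks) {
  keys <- unlist(lapply(networks, function(nw) edge_keys(nw$edges)),
                 use.names = FALSE)
  if (!length(keys)) {
    return(list(counts = data.frame(gene_a = character(),
                                    gene_b = character(), count = integer()),
                histogram = table(integer(0))))
  }
  tab <- table(keys)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  counts <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1),
    gene_b = vapply(parts, `[`, character(1), 2),
    count = as.integer(tab), stringsAsFactors = FALSE
  )
  counts <- counts[order(-counts$count, counts$gene_a, counts$gene_b), ]
  rownames(counts) <- NULL
  list(counts = counts, histogram = table(counts$count))
}

#' Extract the conserved core ceRNA network
#'
#' Keeps edges occurring in at least `min_profiles` of the supplied
#' networks (the default 16 encodes a "more than 15 networks" rule); edge
#' statistics come from the merged network's best supporting profile.
#'
#' @param networks list of `cerna_network`s.
#' @param min_profiles minimum occurrence count for a core edge.
#' @return a `cerna_network` at global level (id `"core"`).
#' @export
extract_core_network <- function(networks, min_profiles = 16) {
  if (min_profiles > length(networks)) {
    stop("min_profiles exceeds the number of supplied networks")
  }
  occ <- edge_profile_counts(networks)$counts
  keep <- occ[occ$count >= min_profiles, c("gene_a", "gene_b")]
  merged <- merge_networks(networks, network_id = "core", level = "global")
  edges <- merged$edges[edge_keys(merged$edges) %in% edge_keys(keep), ,
                        drop = FALSE]
  cerna_network(edges, network_id = "core", level = "global")
}

#' Identify hub genes of a network
#'
#' Hubs are the top `top_frac` of nodes by degree: with `k =
#' ceiling(top_frac * n_nodes)`, every node whose degree reaches the k-th
#' largest degree is a hub, so ties at the threshold are always included
#' and the hub set is deterministic.
#'
#' @param network a `cerna_network`.
#' @param top_frac fraction of nodes taken as hubs (default 0.10).
#' @return character vector of hub gene ids.
#' @export
identify_hubs <- function(network, top_frac = 0.10) {
  deg <- network_degrees(network)
  if (!length(deg)) return(character(0))
  k <- max(1L, ceiling(top_frac * length(deg)))
  thresh <- sort(as.numeric(deg), decreasing = TRUE)[k]
  sort(names(deg)[deg >= thresh])
}

#' Classify hubs as common, differential or specific
#'
#' A hub appearing in exactly one network is *specific*. For a hub of
#' several networks, the Simpson index of its neighbor sets is computed for
#' every pair of networks in which it is a hub: if any pairwise index
#' exceeds `simpson_threshold` the hub is *common* (neighbors conserved),
#' otherwise *differential* (neighbors rewired). The three categories
#' partition the hub universe.
#'
#' @param networks named list of (typically disease-level) `cerna_network`s.
#' @param top_frac hub fraction passed to [identify_hubs].
#' @param simpson_threshold neighbor-overlap threshold (default 0.8,
#'   strict inequality).
#' @return data.frame with `gene`, `n_networks`, `hub_networks`
#'   (comma-separated ids), `max_simpson`, `category`.
#' @export
classify_hubs <- function(networks, top_frac = 0.10, simpson_threshold = 0.8) {
  ids <- names(networks)
  if (is.null(ids)) {
    ids <- vapply(networks, `[[`, character(1), "network_id")
    names(networks) <- ids
  }
  hub_sets <- lapply(networks, identify_hubs, top_frac = top_frac)
  all_hubs <- sort(unique(unlist(hub_sets)))
  if (!length(all_hubs)) {
    return(data.frame(gene = character(), n_networks = integer(),
                      hub_networks = character(), max_simpson = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(all_hubs, function(g) {
    in_nets <- ids[vapply(hub_sets, function(h) g %in% h, logical(1))]
    if (length(in_nets) == 1L) {
      return(data.frame(gene = g, n_networks = 1L,
                        hub_networks = in_nets, max_simpson = NA_real_,
                        category = "specific", stringsAsFactors = FALSE))
    }
    nbrs <- lapply(in_nets, function(id) network_neighbors(networks[[id]], g))
    cmb <- utils::combn(length(in_nets), 2)
    sims <- apply(cmb, 2, function(ij) simpson_index(nbrs[[ij[1]]],
                                                     nbrs[[ij[2]]]))
    mx <- max(sims)
    data.frame(gene = g, n_networks = length(in_nets),
               hub_networks = paste(in_nets, collapse = ","),
               max_simpson = mx,
               category = if (mx > simpson_threshold) "common" else "differential",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
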