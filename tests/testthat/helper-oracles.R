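# Independent oracles and shared fixtures for the test suite.

# draw n integers from a discrete power law with exponent alpha and lower
# cut-off xmin (continuity-corrected inverse-CDF sampler)
rdiscrete_powerlaw <- function(n, alpha, xmin = 1) {
  floor((xmin - 0.5) * stats::runif(n)^(-1 / (alpha - 1)) + 0.5)
}

# Monte-Carlo estimate of P(shared >= r): draw n of m items, t of which are
# marked, and count how often the overlap reaches r
mc_hypergeom_tail <- function(m, t, n, r, reps = 1e4) {
  hits <- vapply(seq_len(reps), function(i) {
    sum(sample.int(m, n) <= t) >= r
  }, logical(1))
  mean(hits)
}

# brute-force k-clique percolation: enumerate k-cliques by combn, join
# cliques sharing k-1 nodes, flood-fill components
bruteforce_clique_percolation <- function(edges, k) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  has_edge <- function(a, b) {
    any((edges$gene_a == a & edges$gene_b == b) |
          (edges$gene_a == b & edges$gene_b == a))
  }
  if (length(nodes) < k) return(list())
  cliques <- list()
  cmb <- utils::combn(nodes, k)
  for (j in seq_len(ncol(cmb))) {
    mem <- cmb[, j]
    prs <- utils::combn(mem, 2)
    if (all(vapply(seq_len(ncol(prs)),
                   function(q) has_edge(prs[1, q], prs[2, q]), logical(1)))) {
      cliques[[length(cliques) + 1]] <- mem
    }
  }
  nc <- length(cliques)
  if (!nc) return(list())
  comp <- seq_len(nc)
  repeat {
    changed <- FALSE
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        if (comp[i] != comp[j] &&
            length(intersect(cliques[[i]], cliques[[j]])) == k - 1) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comms <- lapply(split(seq_len(nc), comp), function(ii) {
    sort(unique(unlist(cliques[ii])))
  })
  unname(comms)
}

# canonical sortable representation of a community list, for set equality
community_fingerprint <- function(comms) {
  sort(vapply(comms, function(x) paste(sort(x), collapse = ","), character(1)))
}

# small synthetic study used across tests (fast: ~1 s)
small_study <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 300, n_mirnas = 120, n_samples = 60,
         n_profiles = 6, n_diseases = 3, targets_per_gene = 12,
         n_planted_pairs = 40, pathway_size = 30, n_pathways = 8),
    list(...)
  )
  generate_study(do.call(synthetic_config, args))
}

# canonical edge keys of a network or pair table
keys_of <- function(x) {
  e <- if (inherits(x, "cerna_network")) x$edges else x
  paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b), sep = "\t")
}

# build a cerna_network from compact edge vectors
net_from <- function(a, b, r = 0.5, p = 1e-4, n_shared = 3, id = "net") {
  cerna_network(data.frame(gene_a = a, gene_b = b, r = r, p = p,
                           q = p, n_shared = n_shared,
                           stringsAsFactors = FALSE), network_id = id)
}
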