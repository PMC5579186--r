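#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood exponent for the discrete power law using the
#' continuity-corrected estimator
#' \deqn{\hat\alpha = 1 + N \Big/ \sum_i \ln\frac{d_i}{x_{\min} - 1/2},}
#' with the lower cut-off `xmin` chosen to minimize the Kolmogorov-Smirnov
#' distance between the empirical tail CCDF and the fitted CCDF
#' \eqn{((x - 1/2)/(x_{\min} - 1/2))^{1-\alpha}}.
#'
#' @param degrees positive integer degree sequence (>= 10 distinct values).
#' @param min_tail smallest tail size considered when scanning `xmin`.
#' @param xmin optional fixed lower cut-off; when given, no scan is done.
#' @return list with `alpha`, `xmin`, `ks_distance`, `n_tail`.
#' @export
fit_power_law <- function(degrees, min_tail = 10, xmin = NULL) {
  degrees <- degrees[is.finite(degrees) & degrees > 0]
  if (length(unique(degrees)) < 2) stop("cannot fit: degenerate degree sequence")
  if (length(unique(degrees)) < 10) {
    stop("cannot fit: need >= 10 distinct positive degrees")
  }
  if (!is.null(xmin)) {
    cand <- xmin
    if (sum(degrees >= xmin) < 2) stop("cannot fit: empty tail above xmin")
  } else {
    cand <- sort(unique(degrees))
    cand <- cand[vapply(cand, function(x) sum(degrees >= x) >= min_tail,
                        logical(1))]
    if (!length(cand)) stop("cannot fit: no xmin leaves a large enough tail")
  }
  best <- NULL
  for (xmin in cand) {
    tail_d <- degrees[degrees >= xmin]
    n <- length(tail_d)
    denom <- sum(log(tail_d / (xmin - 0.5)))
    if (denom <= 0) next
    alpha <- 1 + n / denom
    ux <- sort(unique(tail_d))
    emp <- vapply(ux, function(x) mean(tail_d >= x), numeric(1))
    fit <- ((ux - 0.5) / (xmin - 0.5))^(1 - alpha)
    ks <- max(abs(emp - fit))
    if (is.null(best) || ks < best$ks_distance) {
      best <- list(alpha = alpha, xmin = xmin, ks_distance = ks, n_tail = n)
    }
  }
  if (is.null(best)) stop("cannot fit: degenerate degree sequence")
  best
}

# decile bin index (1..10) by degree rank; ties share a bin
degree_decile <- function(deg) {
  as.integer(cut(rank(deg, ties.method = "average"),
                 breaks = seq(0, length(deg), length.out = 11), labels = FALSE,
                 include.lowest = TRUE))
}

#' Degree versus co-expression trend
#'
#' Bins network nodes into degree deciles and reports, per bin, the mean
#' Pearson correlation of incident edges, with a Spearman rank trend across
#' bins. A scale-free ceRNA network in which highly connected genes are
#' more strongly co-expressed shows a positive trend.
#'
#' @param network a `cerna_network` with edge correlations.
#' @return list with `table` (bin, n_nodes, mean_r), `spearman_rho`,
#'   `p_value`, `degenerate` (TRUE when the trend is undefined, in which
#'   case `spearman_rho` is reported as 0).
#' @export
degree_vs_coexpression <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$edges) == 0L) stop("network has no edges")
  deg <- network_degrees(network)
  bin <- degree_decile(deg)
  names(bin) <- names(deg)
  e <- network$edges
  node_mean_r <- vapply(names(deg), function(g) {
    mean(e$r[e$gene_a == g | e$gene_b == g])
  }, numeric(1))
  tab <- data.frame(
    bin = sort(unique(bin)),
    n_nodes = as.vector(table(bin)),
    mean_r = vapply(sort(unique(bin)),
                    function(b) mean(node_mean_r[bin == b]), numeric(1))
  )
  ok <- is.finite(tab$mean_r)
  if (sum(ok) < 3 || stats::sd(tab$mean_r[ok]) == 0) {
    return(list(table = tab, spearman_rho = 0, p_value = NA_real_,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(tab$bin[ok], tab$mean_r[ok],
                                         method = "spearman"))
  list(table = tab, spearman_rho = unname(ct$estimate),
       p_value = ct$p.value, degenerate = FALSE)
}

#' Shared-miRNA count versus co-expression
#'
#' Groups edges by their shared-miRNA count and reports the mean
#' correlation per group plus a Spearman trend over edges; bins with fewer
#' than 5 edges are flagged.
#'
#' @param network a `cerna_network` whose edges carry `n_shared` and `r`.
#' @return list with `table` (n_shared, n_edges, mean_r, small_bin),
#'   `spearman_rho`, `p_value`.
#' @export
shared_mirna_vs_correlation <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  e <- network$edges
  if (nrow(e) == 0L) stop("network has no edges")
  counts <- sort(unique(e$n_shared))
  tab <- data.frame(
    n_shared = counts,
    n_edges = vapply(counts, function(k) sum(e$n_shared == k), integer(1)),
    mean_r = vapply(counts, function(k) mean(e$r[e$n_shared == k]), numeric(1))
  )
  tab$small_bin <- tab$n_edges < 5
  if (length(counts) < 2 || stats::sd(e$r) == 0) {
    return(list(table = tab, spearman_rho = 0, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(e$n_shared, e$r, method = "spearman"))
  list(table = tab, spearman_rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Pair-degree versus co-expression comparison
#'
#' The pair degree of an edge is the sum of its endpoint degrees. Edges in
#' the top `top_frac` of pair degrees are compared against edges whose both
#' endpoint degrees lie in `low_degrees`, with a one-sided Mann-Whitney U
#' test of stronger co-expression in the high-degree group.
#'
#' @param network a `cerna_network`.
#' @param top_frac fraction defining the high-pair-degree group.
#' @param low_degrees endpoint degrees defining the low group.
#' @return list with group sizes, group mean correlations, and `p_value`
#'   (NA with `note` when a group is empty).
#' @export
pairdegree_vs_coexpression <- function(network, top_frac = 0.10,
                                       low_degrees = c(1, 2)) {
  stopifnot(inherits(network, "cerna_network"))
  e <- network$edges
  if (nrow(e) == 0L) stop("network has no edges")
  deg <- network_degrees(network)
  pd <- deg[e$gene_a] + deg[e$gene_b]
  k <- max(1L, ceiling(top_frac * length(pd)))
  thresh <- sort(pd, decreasing = TRUE)[k]
  high <- e$r[pd >= thresh]
  low <- e$r[deg[e$gene_a] %in% low_degrees & deg[e$gene_b] %in% low_degrees]
  if (!length(high) || !length(low)) {
    return(list(n_high = length(high), n_low = length(low),
                mean_r_high = NA_real_, mean_r_low = NA_real_,
                p_value = NA_real_, note = "empty group"))
  }
  wt <- suppressWarnings(stats::wilcox.test(high, low, alternative = "greater"))
  list(n_high = length(high), n_low = length(low),
       mean_r_high = mean(high), mean_r_low = mean(low),
       p_value = wt$p.value, note = NA_character_)
}

#' Detect modularity communities in a ceRNA network
#'
#' Runs multi-level greedy modularity optimization (Louvain, unweighted)
#' and retains communities whose size lies strictly between `min_size - 1`
#' and `max_size + 1` — with the defaults, more than 3 and fewer than 300
#' members.
#'
#' @param network a `cerna_network`.
#' @param min_size,max_size inclusive size bounds for retained communities.
#' @param seed optional seed for the (stochastic) optimizer.
#' @return list with `communities` (list of character member vectors),
#'   `sizes_all` (sizes before filtering), `method`.
#' @export
detect_communities <- function(network, min_size = 4, max_size = 299,
                               seed = NULL) {
  stopifnot(inherits(network, "cerna_network"))
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0L) {
    return(list(communities = list(), sizes_all = integer(0),
                method = "modularity"))
  }
  run <- function() igraph::cluster_louvain(g)
  cl <- if (is.null(seed)) run() else with_stage_seed(seed, run())
  mem <- igraph::membership(cl)
  groups <- split(names(mem), as.integer(mem))
  sizes <- lengths(groups)
  keep <- groups[sizes >= min_size & sizes <= max_size]
  keep <- lapply(unname(keep), sort)
  list(communities = keep, sizes_all = unname(sizes), method = "modularity")
}

#' Dicer-stratified co-expression of ceRNA pairs
#'
#' Splits samples at the median expression of a Dicer-proxy gene (ties to
#' the low group), recomputes pair correlations within each group, and
#' tests with a one-sided Mann-Whitney U whether co-expression is stronger
#' in the Dicer-low group — the behavior expected when ceRNA cross-talk is
#' limited by miRNA abundance.
#'
#' @param profile an [expression_profile] containing the Dicer gene.
#' @param pairs data.frame with `gene_a`, `gene_b` (e.g. retained edges or
#'   candidate pairs).
#' @param dicer_gene_id row name of the Dicer-proxy gene.
#' @return list with `r_low`, `r_high` (per-pair correlations),
#'   `mean_r_low`, `mean_r_high`, `p_value`.
#' @export
dicer_stratified_coexpression <- function(profile, pairs, dicer_gene_id) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!dicer_gene_id %in% profile$genes) {
    stop("Dicer gene '", dicer_gene_id, "' absent from profile")
  }
  dicer <- profile$values[dicer_gene_id, ]
  low <- dicer <= stats::median(dicer)
  if (sum(low) < 3 || sum(!low) < 3) {
    stop("each Dicer group needs at least 3 samples")
  }
  sub_profile <- function(keep) {
    expression_profile(profile$values[, keep, drop = FALSE],
                       profile$profile_id, profile$disease, profile$platform)
  }
  st_low <- pearson_edge_stats(sub_profile(low), pairs)
  st_high <- pearson_edge_stats(sub_profile(!low), pairs)
  wt <- suppressWarnings(stats::wilcox.test(st_low$r_pearson,
                                            st_high$r_pearson,
                                            alternative = "greater"))
  list(r_low = st_low$r_pearson, r_high = st_high$r_pearson,
       mean_r_low = mean(st_low$r_pearson),
       mean_r_high = mean(st_high$r_pearson), p_value = wt$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison of degree sequences
#'
#' @param network_a,network_b non-empty `cerna_network`s.
#' @return list with `D` and `p_value`.
#' @export
ks_compare_degrees <- function(network_a, network_b) {
  da <- network_degrees(network_a)
  db <- network_degrees(network_b)
  if (!length(da) || !length(db)) stop("both networks must be non-empty")
  kt <- suppressWarnings(stats::ks.test(as.numeric(da), as.numeric(db)))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
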