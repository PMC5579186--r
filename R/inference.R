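#' Upper-tail hypergeometric p-value for shared miRNA targeting
#'
#' Two genes targeted by `t` and `n` miRNAs out of a universe of `m` share
#' `r` miRNAs. Under the null that the two target sets are drawn
#' independently and uniformly, the shared count follows a hypergeometric
#' distribution; the test reports
#' \deqn{p = P(X \ge r) = 1 - \sum_{i=0}^{r-1}
#'   \binom{t}{i}\binom{m-t}{n-i} / \binom{m}{n}.}
#' The tail is evaluated via the hypergeometric survival function
#' (`phyper`), which works in log space internally and is stable for
#' universes far beyond 10^4.
#'
#' @param m miRNA universe size.
#' @param t,n miRNA counts of the two genes.
#' @param r shared miRNA count.
#' @return `P(X >= r)`; vectorized over all four arguments.
#' @export
hypergeom_pvalue <- function(m, t, n, r) {
  m <- as.numeric(m); t <- as.numeric(t); n <- as.numeric(n); r <- as.numeric(r)
  if (any(r < 0) || any(r > pmin(t, n)) || any(t > m) || any(n > m) ||
      any(t < 0) || any(n < 0)) {
    stop("require 0 <= r <= min(t, n) and t, n <= m")
  }
  stats::phyper(r - 1, t, m - t, n, lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' Family-wise error rate control: sort p-values ascending and take the
#' running maximum of `min(1, (k - j + 1) * p_(j))`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return BH q-values (monotone non-decreasing in the sorted order).
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Enumerate candidate ceRNA pairs from shared miRNA targets
#'
#' Lists every unordered gene pair sharing at least `min_shared` miRNAs in
#' the interaction table, scores each with the upper-tail hypergeometric
#' test ([hypergeom_pvalue]) and applies a single Holm correction across the
#' whole candidate universe. Pairs with `p_holm < alpha_holm` are flagged as
#' candidates; the correlation stage later tests only those (or all listed
#' pairs, at the caller's choice).
#'
#' @param interactions an `interaction_table`.
#' @param min_shared minimum shared miRNA count (default 3; pairs below it
#'   are excluded before any testing).
#' @param alpha_holm Holm-adjusted significance cut-off (default 0.01).
#' @return data.frame with columns `gene_a`, `gene_b` (canonical order),
#'   `t`, `n`, `r` (shared count), `m`, `p_hyper`, `p_holm`, `candidate`.
#' @export
candidate_pairs <- function(interactions, min_shared = 3, alpha_holm = 0.01) {
  stopifnot(inherits(interactions, "interaction_table"), min_shared >= 1)
  pairs <- interactions$pairs
  genes <- sort(unique(pairs$gene))
  mirnas <- sort(unique(pairs$mirna))
  inc <- Matrix::sparseMatrix(
    i = match(pairs$gene, genes),
    j = match(pairs$mirna, mirnas),
    x = 1,
    dims = c(length(genes), length(mirnas))
  )
  targ_counts <- Matrix::rowSums(inc)
  shared <- Matrix::tcrossprod(inc)
  trip <- Matrix::summary(shared)
  keep <- trip$i < trip$j & trip$x >= min_shared
  trip <- trip[keep, , drop = FALSE]
  if (!nrow(trip)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      t = integer(), n = integer(), r = integer(),
                      m = integer(), p_hyper = numeric(), p_holm = numeric(),
                      candidate = logical(), stringsAsFactors = FALSE))
  }
  m <- interactions$m
  t_a <- targ_counts[trip$i]
  t_b <- targ_counts[trip$j]
  p <- hypergeom_pvalue(m, t_a, t_b, trip$x)
  out <- data.frame(
    gene_a = genes[trip$i], gene_b = genes[trip$j],
    t = as.integer(t_a), n = as.integer(t_b), r = as.integer(trip$x),
    m = as.integer(m), p_hyper = p, p_holm = holm_adjust(p),
    stringsAsFactors = FALSE
  )
  out$candidate <- out$p_holm < alpha_holm
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation statistics for gene pairs in a profile
#'
#' Computes the sample Pearson correlation and its two-sided p-value (t
#' distribution with `n_samples - 2` degrees of freedom) for each supplied
#' gene pair. Pairs with a gene absent from the profile or with
#' zero-variance expression are skipped with a message, not an error.
#'
#' @param profile an [expression_profile].
#' @param pairs data.frame with columns `gene_a`, `gene_b` (other columns
#'   are carried through).
#' @return `pairs` restricted to testable rows, with columns `r_pearson`
#'   and `p_pearson` appended.
#' @export
pearson_edge_stats <- function(profile, pairs) {
  stopifnot(inherits(profile, "expression_profile"))
  present <- pairs$gene_a %in% profile$genes & pairs$gene_b %in% profile$genes
  if (!all(present)) {
    message(sum(!present), " pairs skipped: gene absent from profile ",
            profile$profile_id)
    pairs <- pairs[present, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    pairs$r_pearson <- numeric(0)
    pairs$p_pearson <- numeric(0)
    return(pairs)
  }
  x <- profile$values
  nsamp <- ncol(x)
  xc <- x - rowMeans(x)
  ss <- rowSums(xc^2)
  a <- match(pairs$gene_a, rownames(x))
  b <- match(pairs$gene_b, rownames(x))
  ok <- ss[a] > 0 & ss[b] > 0
  if (!all(ok)) {
    message(sum(!ok), " pairs skipped: zero-variance gene in profile ",
            profile$profile_id)
    pairs <- pairs[ok, , drop = FALSE]
    a <- a[ok]; b <- b[ok]
  }
  r <- rowSums(xc[a, , drop = FALSE] * xc[b, , drop = FALSE]) /
    sqrt(ss[a] * ss[b])
  r <- pmin(1, pmax(-1, r))
  df <- nsamp - 2
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  pairs$r_pearson <- unname(r)
  pairs$p_pearson <- pmin(1, unname(p))
  rownames(pairs) <- NULL
  pairs
}

#' Build a per-profile ceRNA network
#'
#' Second stage of the inference: candidate pairs are tested for positive
#' co-expression in one expression profile and the pairs with
#' `r_pearson > r_min` and `p_pearson < alpha_p` become edges. BH q-values
#' are computed across all pairs tested in this profile and stored on the
#' retained edges; setting `filter_on_q = TRUE` applies the `alpha_p`
#' threshold to the q-value instead of the raw p-value.
#'
#' @param profile an [expression_profile].
#' @param candidates output of [candidate_pairs].
#' @param r_min minimum correlation (default 0: positive correlation only).
#' @param alpha_p correlation significance cut-off (default 0.01).
#' @param candidates_only if TRUE (default) only Holm-significant pairs are
#'   tested; if FALSE every pair passing the shared-miRNA floor is tested.
#' @param filter_on_q filter on BH q instead of raw p.
#' @return a `cerna_network` at profile level (id = profile id).
#' @export
build_profile_network <- function(profile, candidates, r_min = 0,
                                  alpha_p = 0.01, candidates_only = TRUE,
                                  filter_on_q = FALSE) {
  stopifnot(inherits(profile, "expression_profile"))
  cand <- candidates
  if (candidates_only && "candidate" %in% names(cand)) {
    cand <- cand[cand$candidate, , drop = FALSE]
  }
  if (!nrow(cand)) {
    return(cerna_network(NULL, network_id = profile$profile_id))
  }
  tested <- pearson_edge_stats(profile, cand)
  if (!nrow(tested)) {
    return(cerna_network(NULL, network_id = profile$profile_id))
  }
  tested$q_bh <- bh_fdr(tested$p_pearson)
  crit <- if (filter_on_q) tested$q_bh else tested$p_pearson
  keep <- tested$r_pearson > r_min & crit < alpha_p
  edges <- tested[keep, , drop = FALSE]
  if (!nrow(edges)) {
    return(cerna_network(NULL, network_id = profile$profile_id))
  }
  cerna_network(
    data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
               r = edges$r_pearson, p = edges$p_pearson, q = edges$q_bh,
               n_shared = edges$r, stringsAsFactors = FALSE),
    network_id = profile$profile_id, level = "profile"
  )
}
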