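#' ceRNA network objects
#'
#' A `cerna_network` is an undirected graph of ceRNA (competing endogenous
#' RNA) cross-talk edges. Each edge joins two genes that share miRNA target
#' sites and carries the statistics produced during inference: the Pearson
#' correlation `r` and its p-value `p` in the supporting expression profile,
#' the Benjamini-Hochberg q-value `q` computed over all tested pairs of that
#' profile, and the number of shared miRNAs `n_shared`.
#'
#' Edges are stored canonically with `gene_a < gene_b` (lexicographic), with
#' self-loops rejected and duplicates removed, so two networks with the same
#' edge set compare equal regardless of input order.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `r`, `p`, `q`, `n_shared`. Missing statistic columns are filled with NA.
#' @param network_id character scalar identifying the network.
#' @param level one of `"profile"`, `"disease"`, `"global"`.
#' @return An object of class `cerna_network`: a list with elements
#'   `network_id`, `level`, `edges` (canonical edge data.frame) and `nodes`
#'   (character vector of gene ids).
#' @export
cerna_network <- function(edges, network_id = "network", level = "profile") {
  level <- match.arg(level, c("profile", "disease", "global"))
  stat_cols <- c("r", "p", "q", "n_shared")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), p = numeric(), q = numeric(),
                        n_shared = integer(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene_a", "gene_b") %in% names(edges))) {
      stop("edges must have columns 'gene_a' and 'gene_b'")
    }
    edges$gene_a <- as.character(edges$gene_a)
    edges$gene_b <- as.character(edges$gene_b)
    if (any(edges$gene_a == edges$gene_b)) {
      stop("self-loops are not allowed in a ceRNA network")
    }
    for (cl in stat_cols) {
      if (is.null(edges[[cl]])) edges[[cl]] <- NA_real_
    }
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges$gene_a <- a
    edges$gene_b <- b
    edges <- edges[!duplicated(edge_keys(edges)), c("gene_a", "gene_b", stat_cols)]
    edges <- edges[order(edges$gene_a, edges$gene_b), ]
    rownames(edges) <- NULL
  }
  structure(
    list(network_id = as.character(network_id), level = level,
         edges = edges, nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
    class = "cerna_network"
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network '%s' (%s level): %d nodes, %d edges\n",
              x$network_id, x$level, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonical "a\tb" string per edge; gene ids cannot contain tabs (TSV source)
edge_keys <- function(edges) {
  paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b),
        sep = "\t")
}

#' Convert a ceRNA network to an igraph graph
#'
#' Edge statistics become igraph edge attributes.
#'
#' @param network a `cerna_network`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$edges) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  igraph::graph_from_data_frame(network$edges, directed = FALSE)
}

#' Node degrees of a ceRNA network
#'
#' @param network a `cerna_network`.
#' @return named integer vector of degrees (nodes with at least one edge).
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  if (nrow(network$edges) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(c(network$edges$gene_a, network$edges$gene_b))
  stats::setNames(as.integer(tab), names(tab))
}

#' Neighbor set of a gene in a ceRNA network
#'
#' @param network a `cerna_network`.
#' @param gene gene id.
#' @return character vector of neighboring gene ids (empty if absent).
#' @export
network_neighbors <- function(network, gene) {
  stopifnot(inherits(network, "cerna_network"))
  e <- network$edges
  sort(unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])))
}

#' Expression profile objects
#'
#' A genes-by-samples numeric matrix with profile-level metadata. Values are
#' assumed to be on the log2 scale after ingestion (see [read_expression]).
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples.
#' @param profile_id,disease,platform metadata strings.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(values, profile_id, disease = "", platform = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (!all(is.finite(values))) stop("expression matrix must be finite")
  if (ncol(values) < 3L) stop("at least 3 samples are required")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  structure(
    list(profile_id = as.character(profile_id), disease = as.character(disease),
         platform = as.character(platform), genes = rownames(values),
         samples = colnames(values), values = values),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile '%s' (%s, %s): %d genes x %d samples\n",
              x$profile_id, x$disease, x$platform,
              length(x$genes), length(x$samples)))
  invisible(x)
}
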