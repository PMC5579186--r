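#' Read a miRNA-target interaction table
#'
#' Reads a tab-delimited table of miRNA-to-gene target interactions, the
#' universe for the shared-miRNA hypergeometric test. Duplicate
#' (miRNA, gene) rows are dropped (and counted in a message); the miRNA
#' universe size `m` defaults to the number of distinct miRNA ids but can be
#' overridden when a larger genome-wide universe is intended.
#'
#' @param path path to a TSV file whose first two columns are miRNA id and
#'   gene id.
#' @param header logical; does the file carry a header row?
#' @param m optional override of the miRNA universe size; must be at least
#'   the number of distinct miRNAs in the table.
#' @return an `interaction_table`: list with `pairs` (data.frame `mirna`,
#'   `gene`), `m` (integer universe size).
#' @export
read_interactions <- function(path, header = FALSE, m = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (file.size(path) == 0) stop("no interactions in ", path)
  raw <- utils::read.delim(path, header = header, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("no interactions in ", path)
  if (ncol(raw) < 2L) {
    stop("malformed interaction file (need >= 2 columns): ", path)
  }
  bad <- which(raw[[1]] == "" | raw[[2]] == "")
  if (length(bad)) {
    stop("malformed interaction row (empty id) at line ",
         bad[1] + as.integer(header))
  }
  interaction_table(data.frame(mirna = raw[[1]], gene = raw[[2]],
                               stringsAsFactors = FALSE), m = m)
}

#' Construct an interaction table from a data.frame
#'
#' @param pairs data.frame with columns `mirna` and `gene`.
#' @param m optional miRNA universe size override.
#' @return an `interaction_table`.
#' @export
interaction_table <- function(pairs, m = NULL) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "gene") %in% names(pairs)))
  pairs$mirna <- as.character(pairs$mirna)
  pairs$gene <- as.character(pairs$gene)
  if (any(pairs$mirna == "" | pairs$gene == "")) stop("ids must be non-empty")
  dup <- duplicated(paste(pairs$mirna, pairs$gene, sep = "\t"))
  if (any(dup)) {
    message(sum(dup), " duplicate interaction rows removed")
    pairs <- pairs[!dup, ]
  }
  rownames(pairs) <- NULL
  n_mirnas <- length(unique(pairs$mirna))
  if (is.null(m)) {
    m <- n_mirnas
  } else {
    m <- as.integer(m)
    if (m < n_mirnas) stop("m override smaller than distinct miRNA count")
  }
  structure(list(pairs = pairs, m = as.integer(m)), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table: %d miRNA-gene pairs, %d miRNAs (m = %d), %d genes\n",
              nrow(x$pairs), length(unique(x$pairs$mirna)), x$m,
              length(unique(x$pairs$gene))))
  invisible(x)
}

#' Read an expression profile from TSV
#'
#' First column gene id, remaining columns numeric sample values. When
#' `log2_transform` is TRUE (for profiles deposited as raw intensities)
#' values are transformed to `log2(x + 1)`; the +1 offset keeps zeros
#' finite. Duplicate gene rows (multiple probes per gene) are collapsed by
#' the chosen summary, applied after any transformation.
#'
#' @param path TSV path.
#' @param profile_id,disease,platform metadata attached to the profile.
#' @param log2_transform logical; apply `log2(x + 1)`.
#' @param collapse method for duplicate gene rows; only `"mean"` supported.
#' @return an [expression_profile].
#' @export
read_expression <- function(path, profile_id = basename(path), disease = "",
                            platform = "", log2_transform = FALSE,
                            collapse = c("mean")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 4L) stop("expression profile needs >= 3 sample columns")
  genes <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression value in ", path)
  if (log2_transform) vals <- log2(vals + 1)
  if (anyDuplicated(genes)) {
    # rowsum() and table() both order groups by sorted name
    vals <- rowsum(vals, group = genes) / as.vector(table(genes))
  } else {
    rownames(vals) <- genes
  }
  expression_profile(vals, profile_id, disease, platform)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (class `gene_set_collection`).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line ", i, " (need >= 3 fields)")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Construct a gene set collection
#'
#' @param sets named list of non-empty character vectors.
#' @return class `gene_set_collection` (a named list).
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  structure(lapply(sets, function(s) unique(as.character(s))),
            class = "gene_set_collection")
}

#' Write a gene set collection as GMT
#'
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a ceRNA network edge list
#'
#' Networks round-trip through a TSV edge list with columns
#' `gene_a, gene_b, r, p, q, n_shared_mirnas`; network id and level travel
#' in `#`-prefixed header comments.
#'
#' @param network a `cerna_network`.
#' @param path TSV path.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `cerna_network`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# network_id=%s", network$network_id),
               sprintf("# level=%s", network$level),
               paste(c("gene_a", "gene_b", "r", "p", "q", "n_shared_mirnas"),
                     collapse = "\t")), con)
  e <- network$edges
  if (nrow(e)) {
    num <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g"))
    writeLines(paste(e$gene_a, e$gene_b, num(e$r), num(e$p), num(e$q),
                     ifelse(is.na(e$n_shared), "NA", as.integer(e$n_shared)),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#\\s*", key, "="), "", hit[1]) else default
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), header = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) && any(tab$gene_a == tab$gene_b)) {
    stop("self-loop edge in network file ", path)
  }
  names(tab)[names(tab) == "n_shared_mirnas"] <- "n_shared"
  cerna_network(tab, network_id = get_meta("network_id", basename(path)),
                level = get_meta("level", "profile"))
}

#' Read a transcript feature table
#'
#' TSV with columns `gene`, `transcript_length`, `exon_count`,
#' `conservation_score`.
#'
#' @param path TSV path.
#' @return data.frame with the four columns, one row per gene.
#' @export
read_transcript_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "transcript_length", "exon_count", "conservation_score")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$transcript_length <= 0) || any(tab$exon_count < 1)) {
    stop("transcript lengths must be positive and exon counts >= 1")
  }
  tab[, need]
}

#' Read a pipeline run configuration from YAML
#'
#' See [run_config] for recognized fields; unknown fields are ignored.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
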