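# Graph and gene-set input/output.
#
# A gene_graph is a simple undirected weighted graph over opaque gene
# identifiers, stored as a sorted node vector plus a compressed sparse
# adjacency (CSR) so the walk sampler can enumerate neighbours in O(degree).

#' Construct a gene graph from an edge table
#'
#' Builds the canonical in-memory representation of a PPI network: a simple
#' undirected graph with strictly positive edge weights. Self-loops are
#' dropped and duplicate edges (in either orientation) are collapsed to the
#' first weight seen.
#'
#' @param from,to character vectors of endpoint gene identifiers.
#' @param weight numeric vector of positive edge weights (recycled scalar ok).
#' @param nodes optional character vector of node identifiers; the node set
#'   becomes the union of `nodes` and the edge endpoints, so identifiers
#'   without edges stay in the graph as isolated nodes.
#' @return an object of class `gene_graph` with elements `nodes` (sorted
#'   character vector), `edges` (data.frame `from`, `to`, `weight` with
#'   `from < to`), and CSR adjacency `adj_ptr`, `adj_idx`, `adj_wt`
#'   (0-based pointers, 1-based node indices, neighbours sorted).
#' @export
gene_graph <- function(from, to, weight = 1, nodes = NULL) {
  if (length(from) != length(to))
    abort_validation("'from' and 'to' must have equal length")
  weight <- rep_len(as.numeric(weight), length(from))
  if (length(from)) {
    if (any(!is.finite(weight)) || any(weight <= 0))
      abort_validation("edge weights must be strictly positive and finite")
    self <- from == to
    n_self <- sum(self)
    if (n_self > 0) {
      warning(sprintf("dropped %d self-loop edge(s)", n_self))
      from <- from[!self]; to <- to[!self]; weight <- weight[!self]
    }
    a <- pmin(from, to); b <- pmax(from, to)
    key <- paste0(a, "\r", b)
    dup <- duplicated(key)
    if (any(dup)) {
      keep <- !dup
      first_w <- weight[keep][match(key[dup], key[keep])]
      if (any(abs(first_w - weight[dup]) > 0))
        warning(sprintf(
          "%d duplicate edge(s) with conflicting weights; kept first seen",
          sum(abs(first_w - weight[dup]) > 0)))
      a <- a[keep]; b <- b[keep]; weight <- weight[keep]
    }
  } else {
    a <- b <- character(0)
  }
  nodes <- sort(unique(c(a, b, as.character(nodes))))
  n <- length(nodes)
  ii <- match(a, nodes); jj <- match(b, nodes)
  # symmetrize for CSR
  src <- c(ii, jj); dst <- c(jj, ii); w2 <- c(weight, weight)
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]; w2 <- w2[ord]
  adj_ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  g <- structure(
    list(nodes = nodes,
         edges = data.frame(from = a, to = b, weight = weight,
                            stringsAsFactors = FALSE),
         adj_ptr = as.integer(adj_ptr),
         adj_idx = as.integer(dst),
         adj_wt  = as.numeric(w2)),
    class = "gene_graph")
  g
}

#' Read a PPI network from an edge-list file
#'
#' Accepts whitespace/tab separated lines with two or three fields
#' (`gene_a gene_b [weight]`); lines starting with `#` are ignored.
#' Duplicate lines and reversed duplicates collapse to one edge (first
#' weight kept); self-loop lines are dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param default_weight weight assigned to two-field lines (default 1).
#' @return a [gene_graph()].
#' @export
read_edge_list <- function(path, default_weight = 1.0) {
  if (!file.exists(path)) abort_input(sprintf("edge list not found: %s", path))
  check_positive_scalar(default_weight, "default_weight")
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]; line_no <- seq_along(raw)[keep]
  if (!length(lines)) return(gene_graph(character(0), character(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    abort_parse(sprintf("line %d: expected 2 or 3 fields, got %d",
                        line_no[bad[1]], nf[bad[1]]))
  from <- vapply(fields, `[[`, "", 1L)
  to   <- vapply(fields, `[[`, "", 2L)
  w    <- rep(as.numeric(default_weight), length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[[`, "", 3L)
    wv <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wv))
      abort_parse(sprintf("line %d: weight '%s' is not a number",
                          line_no[has_w][which(is.na(wv))[1]],
                          wtxt[which(is.na(wv))[1]]))
    if (any(wv <= 0) || any(!is.finite(wv)))
      abort_validation(sprintf("line %d: weight must be positive and finite",
                               line_no[has_w][which(wv <= 0 | !is.finite(wv))[1]]))
    w[has_w] <- wv
  }
  gene_graph(from, to, w)
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node and edge counts of a gene graph
#' @param graph a [gene_graph()].
#' @return named list with `n_nodes` and `n_edges`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  list(n_nodes = length(graph$nodes), n_edges = nrow(graph$edges))
}

#' Neighbours of a node
#' @param graph a [gene_graph()].
#' @param node a gene identifier present in the graph.
#' @return data.frame with columns `neighbor` and `weight`.
#' @export
neighbors_of <- function(graph, node) {
  i <- match(node, graph$nodes)
  if (is.na(i)) abort_validation(sprintf("node '%s' not in graph", node))
  lo <- graph$adj_ptr[i] + 1L; hi <- graph$adj_ptr[i + 1L]
  if (hi < lo) return(data.frame(neighbor = character(0), weight = numeric(0)))
  data.frame(neighbor = graph$nodes[graph$adj_idx[lo:hi]],
             weight = graph$adj_wt[lo:hi], stringsAsFactors = FALSE)
}

degree_of <- function(graph, i) graph$adj_ptr[i + 1L] - graph$adj_ptr[i]

#' Convert a gene graph to an igraph object
#' @param graph a [gene_graph()].
#' @return an undirected weighted `igraph` graph with vertex names.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' Read a gene set (one identifier per line)
#'
#' Blank lines and `#` comments are ignored; duplicate identifiers are
#' removed with a message stating how many were dropped.
#'
#' @param path path to the gene list file.
#' @param label free-text label attached to the set.
#' @return a `gene_set`: character vector of unique ids with a `label`
#'   attribute.
#' @export
read_gene_set <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort_input(sprintf("gene set not found: %s", path))
  raw <- trimws(readLines(path, warn = FALSE))
  ids <- raw[!grepl("^(#|$)", raw)]
  n_dup <- sum(duplicated(ids))
  ids <- unique(ids)
  if (!length(ids)) abort_validation(sprintf("gene set '%s' is empty", path))
  if (n_dup > 0) message(sprintf("removed %d duplicate identifier(s)", n_dup))
  gene_set(ids, label = label)
}

#' Construct a gene set
#' @param ids character vector of gene identifiers (deduplicated).
#' @param label free-text label.
#' @return a `gene_set` object.
#' @export
gene_set <- function(ids, label = "genes") {
  ids <- unique(as.character(ids))
  structure(ids, label = label, class = c("gene_set", "character"))
}

#' Restrict a gene set to the nodes of a graph
#'
#' Positives must exist in the network to be embedded and scored; dropped
#' identifiers are reported via a message.
#'
#' @param genes a [gene_set()] (or character vector).
#' @param graph a [gene_graph()].
#' @return the intersection as a `gene_set`.
#' @export
restrict_to_graph <- function(genes, graph) {
  stopifnot(inherits(graph, "gene_graph"))
  ids <- unique(as.character(genes))
  keep <- ids %in% graph$nodes
  if (any(!keep))
    message(sprintf("dropped %d identifier(s) absent from the graph: %s",
                    sum(!keep), paste(head(ids[!keep], 5), collapse = ", ")))
  if (!any(keep))
    abort_validation("no usable genes: the set does not intersect the graph")
  gene_set(ids[keep], label = attr(genes, "label") %||% "genes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scored gene table as TSV
#'
#' Writes columns `gene`, `score`, `rank` in descending score order, with
#' optional `#`-prefixed provenance header lines.
#'
#' @param table data.frame with columns `gene`, `score` (and optionally
#'   `rank`, recomputed on write).
#' @param path output file path.
#' @param provenance optional named character vector written as
#'   `# name: value` comment lines.
#' @export
write_scores <- function(table, path, provenance = NULL) {
  stopifnot(is.data.frame(table), all(c("gene", "score") %in% names(table)))
  if (anyDuplicated(table$gene))
    abort_validation("scored gene table has duplicate gene identifiers")
  if (nrow(table)) {
    ord <- order(-table$score, table$gene)
    table <- table[ord, , drop = FALSE]
    table$rank <- seq_len(nrow(table))
  } else {
    table$rank <- integer(0)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  writeLines("gene\tscore\trank", con)
  if (nrow(table))
    writeLines(sprintf("%s\t%.10g\t%d", table$gene, table$score, table$rank),
               con)
  invisible(path)
}

#' Read a scored gene table written by [write_scores()]
#' @param path input TSV path.
#' @return data.frame with columns `gene`, `score`, `rank`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("score file not found: %s", path))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "numeric", "integer"),
                   stringsAsFactors = FALSE)
  names(df) <- c("gene", "score", "rank")
  df
}

#' Write a gene graph as an edge list
#' @param graph a [gene_graph()].
#' @param path output path.
#' @param provenance optional named character vector of `#` header lines.
#' @export
write_edge_list <- function(graph, path, provenance = NULL) {
  stopifnot(inherits(graph, "gene_graph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  e <- graph$edges
  if (all(e$weight == 1))
    writeLines(sprintf("%s\t%s", e$from, e$to), con)
  else
    writeLines(sprintf("%s\t%s\t%.10g", e$from, e$to, e$weight), con)
  invisible(path)
}

#' Write a gene set, one identifier per line
#' @param genes a [gene_set()] or character vector.
#' @param path output path.
#' @param provenance optional named character vector of `#` header lines.
#' @export
write_gene_set <- function(genes, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  writeLines(as.character(genes), con)
  invisible(path)
}
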