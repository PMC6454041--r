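# Second-order biased random walks (node2vec sampling rule).
#
# A walker at node v with previous position t chooses the next node x among
# the neighbours of v with unnormalized mass alpha(d_tx) * w_vx, where d_tx
# is the shortest distance between t and x (necessarily 0, 1 or 2 because x
# is adjacent to v). The return parameter p penalizes backtracking (d=0) and
# the in-out parameter q controls BFS-like (q > 1) versus DFS-like (q < 1)
# exploration (d=2).

#' Walk sampling parameters
#'
#' @param p return parameter (> 0); large p discourages revisiting the
#'   previous node.
#' @param q in-out parameter (> 0); q < 1 pushes the walk outward (DFS-like),
#'   q > 1 keeps it local (BFS-like).
#' @param walk_length nodes per walk (>= 1).
#' @param walks_per_node walks started from every node (>= 1).
#' @param seed integer RNG seed.
#' @return a `walk_params` list.
#' @export
walk_params <- function(p = 2, q = 0.1, walk_length = 80, walks_per_node = 10,
                        seed = 1L) {
  check_positive_scalar(p, "p")
  check_positive_scalar(q, "q")
  list(p = p, q = q,
       walk_length = check_count(walk_length, "walk_length"),
       walks_per_node = check_count(walks_per_node, "walks_per_node"),
       seed = check_count(seed, "seed", min = 0L))
}

#' Second-order bias factor alpha
#'
#' Returns `1/p` when the candidate next node is the previous node
#' (`d_tx = 0`), `1` when it is also adjacent to the previous node
#' (`d_tx = 1`), and `1/q` otherwise (`d_tx = 2`).
#'
#' @param d_tx shortest distance between the previous node t and candidate x;
#'   must be 0, 1 or 2.
#' @param p,q positive walk bias parameters.
#' @return the positive bias factor.
#' @export
alpha_bias <- function(d_tx, p, q) {
  check_positive_scalar(p, "p"); check_positive_scalar(q, "q")
  if (!all(d_tx %in% c(0, 1, 2)))
    abort_validation("d_tx must be 0, 1 or 2")
  out <- rep(1, length(d_tx))
  out[d_tx == 0] <- 1 / p
  out[d_tx == 2] <- 1 / q
  out
}

#' One-step transition distribution of the biased walk
#'
#' For the walker at `current` having arrived from `prev`, returns the
#' normalized probability of stepping to each neighbour of `current`. When
#' `prev` is `NULL` (first step of a walk) the distribution is first-order:
#' proportional to the edge weights.
#'
#' @param graph a [gene_graph()].
#' @param current current node identifier (must have at least one neighbour).
#' @param prev previous node identifier, or `NULL` on the first step.
#' @param params a [walk_params()].
#' @return named numeric vector of probabilities over the neighbours of
#'   `current`; sums to 1.
#' @export
transition_distribution <- function(graph, current, prev = NULL, params) {
  nb <- neighbors_of(graph, current)
  if (!nrow(nb))
    abort(sprintf("node '%s' is isolated: no transition exists", current),
          "n2asvm_degenerate_state_error")
  if (is.null(prev)) {
    mass <- nb$weight
  } else {
    if (is.na(match(prev, graph$nodes)))
      abort_validation(sprintf("prev node '%s' not in graph", prev))
    prev_nb <- neighbors_of(graph, prev)$neighbor
    d <- ifelse(nb$neighbor == prev, 0L,
                ifelse(nb$neighbor %in% prev_nb, 1L, 2L))
    mass <- alpha_bias(d, params$p, params$q) * nb$weight
  }
  pr <- mass / sum(mass)
  names(pr) <- nb$neighbor
  pr
}

#' Build an alias table for O(1) categorical sampling
#'
#' Vose's alias method: linear-time preprocessing after which each draw
#' needs one uniform index and one uniform accept/reject.
#'
#' @param probs named (or unnamed) numeric vector of nonnegative
#'   probabilities summing to 1 (within 1e-9).
#' @return an `alias_table` with elements `prob`, `alias`, `labels`.
#' @export
build_alias_table <- function(probs) {
  if (any(probs < 0)) abort_validation("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-9)
    abort_validation("probabilities must sum to 1 (within 1e-9)")
  k <- length(probs)
  tab <- cpp_alias_build(as.numeric(probs))
  structure(list(prob = tab$prob, alias = tab$alias,
                 labels = names(probs) %||% as.character(seq_len(k))),
            class = "alias_table")
}

#' Draw from an alias table
#'
#' @param table an `alias_table` from [build_alias_table()].
#' @param n number of draws.
#' @return character vector of `n` sampled labels (uses R's RNG stream).
#' @export
alias_sample <- function(table, n) {
  stopifnot(inherits(table, "alias_table"))
  idx <- cpp_alias_sample(table$prob, table$alias, as.integer(n))
  table$labels[idx]
}

#' Generate the biased random-walk corpus
#'
#' Starts `walks_per_node` walks at every node (nodes visited in sorted
#' order for determinism). The first move of each walk uses the first-order
#' distribution (edge weights); later moves use the second-order rule of
#' [transition_distribution()]. Isolated nodes yield length-1 walks.
#'
#' @param graph a [gene_graph()].
#' @param params a [walk_params()]; `params$seed` seeds the corpus.
#' @return a `walk_corpus`: list with `walks` (list of character vectors of
#'   node ids) and `params`.
#' @export
generate_walks <- function(graph, params) {
  stopifnot(inherits(graph, "gene_graph"))
  if (!length(graph$nodes)) abort_validation("graph has no nodes")
  set.seed(params$seed)
  w <- cpp_generate_walks(graph$adj_ptr, graph$adj_idx, graph$adj_wt,
                          as.integer(params$walk_length),
                          as.integer(params$walks_per_node),
                          params$p, params$q)
  walks <- lapply(w, function(idx) graph$nodes[idx])
  structure(list(walks = walks, params = params), class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks, %d tokens\n",
              length(x$walks), sum(lengths(x$walks))))
  invisible(x)
}

#' Write a walk corpus as plain text (one walk per line)
#' @param corpus a `walk_corpus`.
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$walks, paste, "", collapse = " "), path)
  invisible(path)
}

#' Read a walk corpus written by [write_corpus()]
#' @param path input path.
#' @return a `walk_corpus` (with `params = NULL`).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("corpus not found: %s", path))
  walks <- strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
  structure(list(walks = walks, params = NULL), class = "walk_corpus")
}
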