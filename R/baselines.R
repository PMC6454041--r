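# Baseline scorers: random walk with restart (RWR), shortest-path length
# (SPL) and Euclidean distance (ED). Each produces one score per candidate
# gene, oriented so that larger = more disease-like, so all methods share
# the same AUROC convention as the classifier.

#' Random-walk-with-restart parameters
#'
#' @param restart_prob probability of jumping back to the source at each
#'   step, in (0, 1) (default 0.5).
#' @param tolerance L1 convergence threshold per iteration (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return an `rwr_params` list.
#' @export
rwr_params <- function(restart_prob = 0.5, tolerance = 1e-10,
                       max_iter = 10000) {
  if (!is.numeric(restart_prob) || restart_prob <= 0 || restart_prob >= 1)
    abort_validation("restart_prob must lie strictly between 0 and 1")
  check_positive_scalar(tolerance, "tolerance")
  list(restart_prob = restart_prob, tolerance = tolerance,
       max_iter = check_count(max_iter, "max_iter"))
}

# row-normalized sparse transition matrix W (rows sum to 1; isolated rows 0)
rwr_transition <- function(graph) {
  n <- length(graph$nodes)
  deg <- diff(graph$adj_ptr)
  src <- rep.int(seq_len(n), deg)
  W <- Matrix::sparseMatrix(i = src, j = graph$adj_idx, x = graph$adj_wt,
                            dims = c(n, n))
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Diffusion state of one gene by random walk with restart
#'
#' Power iteration on `pi <- r e_source + (1 - r) t(W) pi` with W the
#' row-normalized weighted adjacency, stopping when the L1 change drops
#' below `params$tolerance`. The fixed point (the "diffusion state") is a
#' probability vector measuring network proximity to the source.
#'
#' @param graph a [gene_graph()].
#' @param source a gene identifier in the graph.
#' @param params an [rwr_params()].
#' @param W optional precomputed transition matrix from repeated calls.
#' @return named numeric probability vector over all nodes (sorted order).
#' @export
rwr_vector <- function(graph, source, params = rwr_params(), W = NULL) {
  s <- match(source, graph$nodes)
  if (is.na(s)) abort_validation(sprintf("source '%s' not in graph", source))
  n <- length(graph$nodes)
  e <- numeric(n); e[s] <- 1
  if (degree_of(graph, s) == 0L) {        # isolated source: all mass restarts
    names(e) <- graph$nodes
    return(e)
  }
  if (is.null(W)) W <- rwr_transition(graph)
  r <- params$restart_prob
  Wt <- Matrix::t(W)
  pi_v <- e
  for (it in seq_len(params$max_iter)) {
    pi_new <- as.numeric(r * e + (1 - r) * (Wt %*% pi_v))
    delta <- sum(abs(pi_new - pi_v))
    pi_v <- pi_new
    if (delta < params$tolerance) {
      names(pi_v) <- graph$nodes
      return(pi_v)
    }
  }
  abort(sprintf("RWR did not converge within %d iterations (residual %.3g)",
                params$max_iter, delta), "n2asvm_convergence_error")
}

#' Diffusion-state feature matrix
#'
#' Row i is the RWR diffusion state started from gene i; columns follow the
#' sorted node order. This n x n matrix is the feature input of the RWA-SVM
#' pipeline ablation.
#'
#' @param graph a [gene_graph()].
#' @param params an [rwr_params()].
#' @return numeric matrix with rownames and colnames equal to the sorted
#'   node ids; every row sums to 1.
#' @export
rwr_feature_matrix <- function(graph, params = rwr_params()) {
  if (!length(graph$nodes)) abort_validation("graph has no nodes")
  W <- rwr_transition(graph)
  out <- t(vapply(graph$nodes,
                  function(u) rwr_vector(graph, u, params, W = W),
                  numeric(length(graph$nodes))))
  dimnames(out) <- list(graph$nodes, graph$nodes)
  out
}

#' RWR proximity score of a candidate gene to a positive set
#'
#' Mean over the positive genes (excluding the candidate itself) of the
#' candidate's entry in the diffusion state started from each positive.
#' Larger = closer to the disease module.
#'
#' @param graph a [gene_graph()].
#' @param positives a [gene_set()] restricted to the graph.
#' @param candidates gene identifiers to score.
#' @param params an [rwr_params()].
#' @return named numeric vector of scores for `candidates`.
#' @export
rwr_score <- function(graph, positives, candidates, params = rwr_params()) {
  pos <- intersect(as.character(positives), graph$nodes)
  if (!length(pos)) abort_validation("no positives present in the graph")
  W <- rwr_transition(graph)
  diff_states <- vapply(pos, function(u) rwr_vector(graph, u, params, W = W),
                        numeric(length(graph$nodes)))  # nodes x positives
  rownames(diff_states) <- graph$nodes
  vapply(candidates, function(g) {
    use <- setdiff(pos, g)
    if (!length(use))
      abort_validation(sprintf("no positives left to score '%s'", g))
    mean(diff_states[g, use])
  }, numeric(1))
}

#' Shortest-path-length score of candidate genes
#'
#' Mean unweighted shortest-path distance (breadth-first search) from each
#' candidate to the positive genes, excluding the candidate itself when it
#' is a positive. Positives unreachable from the candidate contribute the
#' diameter of the candidate's connected component plus one, keeping scores
#' finite and rank-meaningful. The mean is negated on output so that larger
#' score = closer to the disease genes.
#'
#' @param graph a [gene_graph()].
#' @param positives a [gene_set()].
#' @param candidates gene identifiers to score.
#' @param aggregate `"mean"` (default) or `"min"` over positives.
#' @return named numeric vector of scores (negated distances).
#' @export
spl_score <- function(graph, positives, candidates, aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  pos <- intersect(as.character(positives), graph$nodes)
  if (!length(pos)) abort_validation("no positives present in the graph")
  bad <- setdiff(candidates, graph$nodes)
  if (length(bad))
    abort_validation(sprintf("candidate(s) not in graph: %s",
                             paste(head(bad, 5), collapse = ", ")))
  ig <- as_igraph(graph)
  D <- igraph::distances(ig, v = candidates, to = pos, weights = NA,
                         algorithm = "unweighted")
  comp <- igraph::components(ig)
  memb <- comp$membership[graph$nodes]
  names(memb) <- graph$nodes
  # diameter per component of the candidates we need
  comp_diam <- new.env()
  diam_of <- function(cid) {
    key <- as.character(cid)
    if (is.null(comp_diam[[key]])) {
      vs <- graph$nodes[memb == cid]
      sub <- igraph::induced_subgraph(ig, vs)
      comp_diam[[key]] <- igraph::diameter(sub, weights = NA)
    }
    comp_diam[[key]]
  }
  out <- vapply(seq_along(candidates), function(i) {
    g <- candidates[i]
    d <- D[i, , drop = TRUE]
    self <- colnames(D) == g
    d <- d[!self]
    if (!length(d))
      abort_validation(sprintf("no positives left to score '%s'", g))
    unreach <- !is.finite(d)
    if (any(unreach)) d[unreach] <- diam_of(memb[[g]]) + 1
    if (aggregate == "mean") -mean(d) else -min(d)
  }, numeric(1))
  names(out) <- candidates
  out
}

#' Euclidean-distance score of candidate genes
#'
#' Mean Euclidean distance between the candidate's feature row and each
#' positive's row (excluding the candidate itself when positive), negated
#' so that larger score = closer. By default the feature rows are the rows
#' of the binary adjacency matrix of the PPI network; any feature matrix
#' with gene rownames (e.g. embeddings) can be supplied instead.
#'
#' @param features numeric matrix with gene ids as rownames.
#' @param positives a [gene_set()].
#' @param candidates gene identifiers to score.
#' @return named numeric vector of scores (negated mean distances).
#' @export
euclid_score <- function(features, positives, candidates) {
  pos <- intersect(as.character(positives), rownames(features))
  if (!length(pos)) abort_validation("no positives have feature rows")
  bad <- setdiff(candidates, rownames(features))
  if (length(bad))
    abort_validation(sprintf("candidate(s) missing feature rows: %s",
                             paste(head(bad, 5), collapse = ", ")))
  P <- features[pos, , drop = FALSE]
  out <- vapply(candidates, function(g) {
    use <- rownames(P) != g
    if (!any(use))
      abort_validation(sprintf("no positives left to score '%s'", g))
    x <- features[g, ]
    d <- sqrt(rowSums(sweep(P[use, , drop = FALSE], 2, x)^2))
    -mean(d)
  }, numeric(1))
  names(out) <- candidates
  out
}

#' Binary adjacency feature rows of a graph
#' @param graph a [gene_graph()].
#' @return a dense 0/1 matrix with node rownames/colnames (sorted order).
#' @export
adjacency_features <- function(graph) {
  n <- length(graph$nodes)
  deg <- diff(graph$adj_ptr)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  A[cbind(rep.int(seq_len(n), deg), graph$adj_idx)] <- 1
  A
}
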