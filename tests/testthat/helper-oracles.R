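# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a direct, brute-force restatement of the quantity it
# checks, kept free of the package's production code paths.

# AUROC by explicit pair counting (ties = 1/2)
auroc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos)
    for (sn in neg)
      total <- total + (sp > sn) + 0.5 * (sp == sn)
  total / (length(pos) * length(neg))
}

# unit-weight Dijkstra from one source over a gene_graph; returns named
# distances (Inf when unreachable)
dijkstra_unit <- function(graph, source) {
  n <- length(graph$nodes)
  dist <- rep(Inf, n)
  names(dist) <- graph$nodes
  dist[source] <- 0
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    lo <- graph$adj_ptr[u] + 1L; hi <- graph$adj_ptr[u + 1L]
    if (hi >= lo) {
      for (k in lo:hi) {
        v <- graph$adj_idx[k]
        if (dist[u] + 1 < dist[v]) dist[v] <- dist[u] + 1
      }
    }
  }
  dist
}

# reconstruction MSE of the best rank-k linear (principal component)
# approximation, via eigendecomposition of the covariance
pca_truncation_mse <- function(X, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  R <- Xc - Xc %*% V %*% t(V)
  mean(rowSums(R^2))
}

# direct inverse-CDF categorical sampler (oracle for the alias method)
inverse_cdf_sample <- function(probs, n) {
  cum <- cumsum(probs)
  idx <- findInterval(runif(n), cum) + 1L
  names(probs)[idx]
}

# Erdos-Renyi gene_graph over n nodes, guaranteed connected enough for the
# tests by retrying the seed offset until no isolated nodes remain
random_gnp_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  gene_graph(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]], nodes = nodes)
}

# pooled chi-square statistic of observed one-step transition counts
# against expected probabilities; returns the p-value
transition_chisq_p <- function(obs_counts, probs_by_source) {
  stat <- 0; df <- 0
  for (src in names(probs_by_source)) {
    p <- probs_by_source[[src]]
    obs <- obs_counts[[src]]
    if (is.null(obs) || sum(obs) < 50) next
    exp_cnt <- p * sum(obs)
    o <- obs[names(p)]
    o[is.na(o)] <- 0
    stat <- stat + sum((o - exp_cnt)^2 / exp_cnt)
    df <- df + length(p) - 1
  }
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# tabulate one-step transitions of a corpus as per-source counts of
# cur -> nxt (the preceding node is ignored)
first_order_counts <- function(corpus) {
  src <- unlist(lapply(corpus$walks, function(w) head(w, -1L)),
                use.names = FALSE)
  dst <- unlist(lapply(corpus$walks, function(w) w[-1L]), use.names = FALSE)
  tab <- table(src, dst)
  out <- lapply(rownames(tab), function(s) {
    v <- tab[s, ]
    setNames(as.integer(v), colnames(tab))
  })
  names(out) <- rownames(tab)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# barbell graph: two cliques of size k joined by a single edge
barbell_graph <- function(k = 10) {
  cl <- function(ids) t(combn(ids, 2))
  a <- sprintf("a%02d", seq_len(k)); b <- sprintf("b%02d", seq_len(k))
  ea <- cl(a); eb <- cl(b)
  gene_graph(c(ea[, 1], eb[, 1], a[1]), c(ea[, 2], eb[, 2], b[1]))
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
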