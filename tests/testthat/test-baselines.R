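# RWR, shortest-path and Euclidean-distance scorers.

test_that("RWR closed forms: degenerate and two-node graphs", {
  # isolated source keeps all mass by restarting
  g_iso <- gene_graph("A", "B", nodes = c("A", "B", "Z"))
  pi_z <- rwr_vector(g_iso, "Z")
  expect_equal(unname(pi_z[c("A", "B", "Z")]), c(0, 0, 1))

  # two nodes, one edge, r = 0.5: pi_s = 1/(2 - r) solves the fixed point
  g2 <- gene_graph("A", "B")
  pi_a <- rwr_vector(g2, "A", rwr_params(restart_prob = 0.5))
  expect_equal(unname(pi_a["A"]), 2 / 3, tolerance = 1e-8)
  expect_equal(unname(pi_a["B"]), 1 / 3, tolerance = 1e-8)

  M <- rwr_feature_matrix(g2, rwr_params(restart_prob = 0.5))
  expect_equal(unname(M), matrix(c(2, 1, 1, 2) / 3, 2, byrow = TRUE),
               tolerance = 1e-8)
  expect_equal(M["A", ], pi_a)
})

test_that("power iteration agrees with the direct linear solve", {
  p <- rwr_params(restart_prob = 0.4)
  for (s in 1:5) {
    g <- random_gnp_graph(30, 0.15, 700 + s)
    W <- matrix(0, 30, 30, dimnames = list(g$nodes, g$nodes))
    for (v in g$nodes) {
      nb <- neighbors_of(g, v)
      if (nrow(nb)) W[v, nb$neighbor] <- nb$weight / sum(nb$weight)
    }
    src <- g$nodes[5]
    e <- as.numeric(g$nodes == src)
    direct <- solve(diag(30) - (1 - p$restart_prob) * t(W),
                    p$restart_prob * e)
    expect_lt(max(abs(rwr_vector(g, src, p) - direct)), 1e-8)
  }
})

test_that("diffusion states are probability vectors row by row", {
  g <- random_gnp_graph(25, 0.2, 710)
  M <- rwr_feature_matrix(g)
  expect_equal(unname(rowSums(M)), rep(1, 25), tolerance = 1e-8)
  expect_true(all(M >= 0))
  expect_equal(M[g$nodes[3], ], rwr_vector(g, g$nodes[3]))
})

test_that("RWR proximity scores favour the disease neighbourhood", {
  g <- barbell_graph(6)
  pos <- gene_set(c("a01", "a02", "a03"))
  sc <- rwr_score(g, pos, c("a04", "b04"))
  expect_gt(sc["a04"], sc["b04"])
})

test_that("shortest-path scores match hand BFS and the Dijkstra oracle", {
  g <- gene_graph(c("A", "B"), c("B", "C"))
  expect_equal(spl_score(g, gene_set("A"), "C"), c(C = -2))
  # candidate adjacent to every positive: raw mean 1
  star <- gene_graph(rep("hub", 3), c("p1", "p2", "p3"))
  expect_equal(spl_score(star, gene_set(c("p1", "p2", "p3")), "hub"),
               c(hub = -1))
  # a positive candidate is excluded from its own mean
  expect_equal(spl_score(g, gene_set(c("A", "C")), "C"), c(C = -2))

  # BFS distances equal unit-weight Dijkstra for all pairs sampled
  g2 <- random_gnp_graph(50, 0.08, 720)
  ig <- as_igraph(g2)
  D <- igraph::distances(ig, weights = NA, algorithm = "unweighted")
  for (src in sample(g2$nodes, 5)) {
    expect_equal(D[src, g2$nodes], dijkstra_unit(g2, src))
  }
})

test_that("unreachable positives contribute component diameter plus one", {
  # two components: A-B-C and X-Y
  g <- gene_graph(c("A", "B", "X"), c("B", "C", "Y"))
  # candidate X: positive A unreachable, component {X,Y} has diameter 1
  expect_equal(spl_score(g, gene_set("A"), "X"), c(X = -2))
  # mixed reachable/unreachable
  expect_equal(spl_score(g, gene_set(c("A", "Y")), "X"),
               c(X = -(2 + 1) / 2))
})

test_that("shortest-path distances satisfy the triangle inequality", {
  g <- random_gnp_graph(30, 0.12, 730)
  D <- igraph::distances(as_igraph(g), weights = NA,
                         algorithm = "unweighted")
  set.seed(731)
  for (k in 1:50) {
    tri <- sample(g$nodes, 3)
    d_ab <- D[tri[1], tri[2]]; d_bc <- D[tri[2], tri[3]]
    d_ac <- D[tri[1], tri[3]]
    if (is.finite(d_ab) && is.finite(d_bc))
      expect_lte(d_ac, d_ab + d_bc)
  }
})

test_that("Euclidean scores match hand arithmetic and a brute-force oracle", {
  F1 <- matrix(c(0, 0, 2, 0, 1, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("p1", "p2", "cand"), NULL))
  expect_equal(euclid_score(F1, gene_set(c("p1", "p2")), "cand"),
               c(cand = -1))
  # candidate identical to the only positive: raw mean 0
  F2 <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("p1", "cand"), NULL))
  expect_equal(euclid_score(F2, gene_set("p1"), "cand"), c(cand = 0))

  set.seed(740)
  FF <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(sprintf("g%02d", 1:20), NULL))
  pos <- gene_set(sprintf("g%02d", 1:6))
  cand <- "g10"
  brute <- -mean(vapply(1:6, function(i)
    sqrt(sum((FF[cand, ] - FF[i, ])^2)), numeric(1)))
  expect_equal(unname(euclid_score(FF, pos, cand)), brute)

  # translation invariance
  shift <- sweep(FF, 2, c(5, -3, 2, 0, 100), `+`)
  expect_equal(euclid_score(shift, pos, rownames(FF)),
               euclid_score(FF, pos, rownames(FF)))
  expect_error(euclid_score(FF, pos, "nope"),
               class = "n2asvm_validation_error")
})

test_that("scorers are equivariant under gene relabelling", {
  g <- random_gnp_graph(20, 0.2, 750)
  pos <- gene_set(g$nodes[1:4])
  cands <- g$nodes[5:10]
  relabel <- setNames(sprintf("zz%02d", seq_along(g$nodes)), g$nodes)
  g2 <- gene_graph(relabel[g$edges$from], relabel[g$edges$to])
  s1 <- spl_score(g, pos, cands)
  s2 <- spl_score(g2, gene_set(relabel[as.character(pos)]), relabel[cands])
  expect_equal(unname(s2), unname(s1))
  r1 <- rwr_score(g, pos, cands)
  r2 <- rwr_score(g2, gene_set(relabel[as.character(pos)]), relabel[cands])
  expect_equal(unname(r2), unname(r1), tolerance = 1e-9)
})
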