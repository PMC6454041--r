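# The second-order transition rule and the walk sampler.

path_graph <- function(ids) gene_graph(head(ids, -1), ids[-1])

test_that("alpha bias follows the three-case rule", {
  expect_equal(alpha_bias(0, p = 2, q = 0.5), 0.5)
  expect_equal(alpha_bias(1, p = 17, q = 0.01), 1.0)
  expect_equal(alpha_bias(2, p = 1, q = 1), 1.0)
  expect_equal(alpha_bias(2, p = 1, q = 4), 0.25)
  expect_error(alpha_bias(3, 1, 1), class = "n2asvm_validation_error")
  expect_error(alpha_bias(1, p = 0, q = 1), class = "n2asvm_validation_error")
})

test_that("transition distribution matches hand-evaluated cases", {
  g <- path_graph(c("A", "B", "C", "D"))
  pr <- transition_distribution(g, "B", "A", walk_params(p = 1, q = 0.25))
  expect_equal(pr, c(A = 0.2, C = 0.8))

  # weighted triangle-with-tail: C adjacent to prev A so d_tC = 1
  g2 <- gene_graph(c("A", "B", "A"), c("B", "C", "C"), weight = c(1, 2, 1))
  pr2 <- transition_distribution(g2, "B", "A", walk_params(p = 2, q = 3))
  expect_equal(pr2, c(A = 0.2, C = 0.8))

  # p = q = 1, unit weights: uniform over neighbours
  g3 <- random_gnp_graph(15, 0.3, 401)
  v <- g3$nodes[which.max(diff(g3$adj_ptr))]
  t_node <- neighbors_of(g3, v)$neighbor[1]
  pr3 <- transition_distribution(g3, v, t_node, walk_params(p = 1, q = 1))
  expect_equal(unname(pr3), rep(1 / length(pr3), length(pr3)))

  # first step (no previous node): first-order, proportional to weights
  pr4 <- transition_distribution(g2, "B", NULL, walk_params(p = 9, q = 9))
  expect_equal(pr4, c(A = 1 / 3, C = 2 / 3))

  expect_error(
    transition_distribution(gene_graph("A", "B", nodes = "Z"), "Z", NULL,
                            walk_params()),
    class = "n2asvm_degenerate_state_error")
})

test_that("transition distributions are normalized and supported on neighbours", {
  params <- walk_params(p = 3, q = 0.2)
  for (s in 1:5) {
    g <- random_gnp_graph(20, 0.2, 410 + s)
    v <- g$nodes[which(diff(g$adj_ptr) > 1)[1]]
    t_node <- neighbors_of(g, v)$neighbor[1]
    pr <- transition_distribution(g, v, t_node, params)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_setequal(names(pr), neighbors_of(g, v)$neighbor)
    expect_true(all(pr > 0))
  }
})

test_that("decreasing q strictly shifts mass to distance-2 neighbours", {
  g <- random_gnp_graph(25, 0.15, 420)
  checked <- 0L
  for (v in g$nodes) {
    nb <- neighbors_of(g, v)$neighbor
    if (length(nb) < 2) next
    t_node <- nb[1]
    prev_nb <- neighbors_of(g, t_node)$neighbor
    far <- setdiff(nb, c(t_node, prev_nb))
    if (!length(far)) next
    mass_at <- function(q) sum(transition_distribution(
      g, v, t_node, walk_params(p = 2, q = q))[far])
    expect_true(mass_at(0.2) > mass_at(1) & mass_at(1) > mass_at(5))
    checked <- checked + 1L
    if (checked >= 5L) break
  }
  expect_gte(checked, 1L)
})

test_that("alias sampler reproduces its target distribution", {
  # degenerate distribution
  tab <- build_alias_table(c(A = 1.0))
  set.seed(430)
  expect_true(all(alias_sample(tab, 100) == "A"))

  # symmetric two-point distribution
  tab2 <- build_alias_table(c(A = 0.5, B = 0.5))
  set.seed(431)
  freq <- table(alias_sample(tab2, 1e5)) / 1e5
  expect_true(all(abs(freq - 0.5) < 0.01))

  # three-point distribution vs an inverse-CDF oracle on equal draw counts
  probs <- c(A = 0.2, B = 0.3, C = 0.5)
  tab3 <- build_alias_table(probs)
  set.seed(432)
  draws <- alias_sample(tab3, 1e5)
  chi <- suppressWarnings(stats::chisq.test(table(draws)[names(probs)],
                                            p = probs))
  expect_gt(chi$p.value, 0.001)
  set.seed(432)
  oracle_draws <- inverse_cdf_sample(probs, 1e5)
  chi_o <- suppressWarnings(stats::chisq.test(
    table(oracle_draws)[names(probs)], p = probs))
  expect_gt(chi_o$p.value, 0.001)

  expect_error(build_alias_table(c(0.5, -0.1, 0.6)),
               class = "n2asvm_validation_error")
  expect_error(build_alias_table(c(0.5, 0.2)),
               class = "n2asvm_validation_error")
})

test_that("walk corpus respects its structural invariants", {
  g <- random_gnp_graph(20, 0.2, 440)
  gi <- gene_graph(g$edges$from, g$edges$to, nodes = c(g$nodes, "zzz_iso"))
  params <- walk_params(p = 2, q = 0.5, walk_length = 10, walks_per_node = 3,
                        seed = 99)
  corpus <- generate_walks(gi, params)
  expect_length(corpus$walks, length(gi$nodes) * 3L)
  # every walk starts at its designated source, in sorted node order
  expect_equal(vapply(corpus$walks, `[[`, "", 1L),
               rep(gi$nodes, each = 3L))
  # isolated node yields length-1 walks
  iso_walks <- corpus$walks[vapply(corpus$walks, `[[`, "", 1L) == "zzz_iso"]
  expect_true(all(lengths(iso_walks) == 1L))
  # every consecutive pair is an edge
  edge_keys <- paste(gi$edges$from, gi$edges$to)
  for (w in corpus$walks[seq(1, length(corpus$walks), by = 7)]) {
    if (length(w) < 2) next
    steps <- paste(pmin(head(w, -1), w[-1]), pmax(head(w, -1), w[-1]))
    expect_true(all(steps %in% edge_keys))
  }
})

test_that("forced path: the only neighbour is always taken", {
  g <- gene_graph("A", "B")
  corpus <- generate_walks(g, walk_params(walk_length = 3, walks_per_node = 5,
                                          seed = 1))
  from_a <- corpus$walks[1:5]
  expect_true(all(vapply(from_a, identical, TRUE, c("A", "B", "A"))))
})

test_that("walk generation is deterministic given the seed", {
  g <- random_gnp_graph(15, 0.25, 450)
  params <- walk_params(p = 2, q = 0.1, walk_length = 12, walks_per_node = 4,
                        seed = 7)
  c1 <- generate_walks(g, params)
  c2 <- generate_walks(g, params)
  expect_identical(c1$walks, c2$walks)
  params2 <- params; params2$seed <- 8
  expect_false(identical(c1$walks, generate_walks(g, params2)$walks))
})

test_that("outward bias: q < 1 sends the walker away from the previous node", {
  g <- path_graph(c("A", "B", "C", "D"))
  corpus <- generate_walks(g, walk_params(p = 1, q = 0.25, walk_length = 60,
                                          walks_per_node = 120, seed = 452))
  hits <- 0L; total <- 0L
  for (w in corpus$walks) {
    if (length(w) < 3) next
    for (i in seq_len(length(w) - 2L)) {
      if (w[i] == "A" && w[i + 1L] == "B") {
        total <- total + 1L
        hits <- hits + (w[i + 2L] == "C")
      }
    }
  }
  expect_gt(total, 500)
  se <- sqrt(0.8 * 0.2 / total)
  expect_lt(abs(hits / total - 0.8), 3 * se)
})

test_that("corpus text round-trips through one-walk-per-line files", {
  g <- random_gnp_graph(10, 0.3, 460)
  corpus <- generate_walks(g, walk_params(walk_length = 6, walks_per_node = 2,
                                          seed = 3))
  f <- tempfile()
  write_corpus(corpus, f)
  expect_identical(read_corpus(f)$walks, corpus$walks)
})
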