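# Synthetic fixtures with known planted structure.
#
# The planted-partition (stochastic block model) graph embodies the
# guilt-by-association premise: "disease" genes live in block 1, which is
# denser inside than between blocks, so every pipeline stage can be tested
# offline against ground truth.

#' Planted-partition configuration
#'
#' @param block_sizes integer sizes of the blocks; block 1 is the disease
#'   community (default `c(60, 120, 120)`).
#' @param p_in within-block edge probability (default 0.15).
#' @param p_out between-block edge probability (default 0.01);
#'   `p_out < p_in` required.
#' @param n_positives known disease genes sampled from block 1
#'   (default 30, at most `block_sizes[1]`).
#' @param seed integer RNG seed.
#' @return a `planted_config` list.
#' @export
planted_config <- function(block_sizes = c(60, 120, 120), p_in = 0.15,
                           p_out = 0.01, n_positives = 30, seed = 1L) {
  block_sizes <- vapply(block_sizes, check_count, integer(1),
                        name = "block_sizes")
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_out < 0 || p_out >= p_in || p_in > 1)
    abort_validation("need 0 <= p_out < p_in <= 1")
  n_positives <- check_count(n_positives, "n_positives")
  if (n_positives > block_sizes[1])
    abort_validation("n_positives cannot exceed the first block size")
  list(block_sizes = block_sizes, p_in = p_in, p_out = p_out,
       n_positives = n_positives, seed = check_count(seed, "seed", min = 0L))
}

#' Generate a planted-partition network with a disease community
#'
#' Every within-block node pair is an edge independently with probability
#' `p_in`, every between-block pair with `p_out`. `n_positives` genes are
#' sampled from block 1 as the known disease genes; the remaining block-1
#' genes are returned as held-out truth (the "undiscovered" disease genes).
#'
#' @param config a [planted_config()].
#' @return list with `graph` (a [gene_graph()]), `positives`,
#'   `held_out_truth` (both [gene_set()]s) and `blocks` (named integer
#'   block membership).
#' @export
planted_partition <- function(config = planted_config()) {
  set.seed(config$seed)
  sizes <- config$block_sizes
  n <- sum(sizes)
  width <- nchar(as.character(n))
  nodes <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  block <- rep.int(seq_along(sizes), sizes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  prob <- ifelse(same, config$p_in, config$p_out)
  keep <- runif(nrow(pairs)) < prob
  graph <- gene_graph(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]],
                      nodes = nodes)
  block1 <- nodes[block == 1L]
  pos <- sort(sample(block1, config$n_positives))
  truth <- setdiff(block1, pos)
  names(block) <- nodes
  list(graph = graph,
       positives = gene_set(pos, label = "planted positives"),
       held_out_truth = gene_set(truth, label = "held-out truth"),
       blocks = block)
}

#' Pure-noise feature matrix (null control)
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param seed integer RNG seed.
#' @param ids optional rownames.
#' @return matrix of iid standard normal entries.
#' @export
noise_features <- function(n_rows, n_cols, seed = 1L, ids = NULL) {
  check_count(n_rows, "n_rows"); check_count(n_cols, "n_cols")
  set.seed(check_count(seed, "seed", min = 0L))
  m <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

#' Low-rank data in a random linear subspace
#'
#' Latent standard-normal points of dimension `intrinsic_dim` are mapped
#' through a fixed random linear map into `ambient_dim` dimensions (map
#' entries scaled by `1/sqrt(intrinsic_dim)` so ambient entries have unit
#' variance), plus isotropic Gaussian noise. The reference fixture for
#' autoencoder-versus-PCA checks.
#'
#' @param n_rows number of points.
#' @param ambient_dim ambient dimension.
#' @param intrinsic_dim subspace dimension (< `ambient_dim`).
#' @param noise_sd isotropic noise standard deviation.
#' @param seed integer RNG seed.
#' @return `n_rows x ambient_dim` numeric matrix.
#' @export
subspace_data <- function(n_rows, ambient_dim, intrinsic_dim, noise_sd = 0,
                          seed = 1L) {
  check_count(n_rows, "n_rows")
  ambient_dim <- check_count(ambient_dim, "ambient_dim")
  intrinsic_dim <- check_count(intrinsic_dim, "intrinsic_dim")
  if (intrinsic_dim >= ambient_dim)
    abort_validation("intrinsic_dim must be smaller than ambient_dim")
  if (noise_sd < 0) abort_validation("noise_sd must be nonnegative")
  set.seed(check_count(seed, "seed", min = 0L))
  Z <- matrix(rnorm(n_rows * intrinsic_dim), n_rows, intrinsic_dim)
  A <- matrix(rnorm(intrinsic_dim * ambient_dim) / sqrt(intrinsic_dim),
              intrinsic_dim, ambient_dim)
  X <- Z %*% A
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), sd = noise_sd),
                                    nrow(X), ncol(X))
  X
}
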