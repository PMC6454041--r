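# Skip-gram-with-negative-sampling (SGNS) embeddings of the walk corpus.
#
# Each gene becomes a dense vector; genes that co-occur within a context
# window on the walks end up with similar vectors, so network neighbourhoods
# (and disease modules, under guilt-by-association) become geometric
# clusters. The input (center) vectors are the exported representation.

#' Embedding hyperparameters
#'
#' @param dimension embedding width (default 512).
#' @param window skip-gram context radius along a walk (default 10).
#' @param negatives negative samples per observed pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param learning_rate initial SGD step size, linearly decayed to 1% of the
#'   initial value over training (default 0.025).
#' @param seed integer RNG seed.
#' @return an `embed_params` list.
#' @export
embed_params <- function(dimension = 512, window = 10, negatives = 5,
                         epochs = 5, learning_rate = 0.025, seed = 1L) {
  check_positive_scalar(learning_rate, "learning_rate")
  list(dimension = check_count(dimension, "dimension"),
       window = check_count(window, "window"),
       negatives = check_count(negatives, "negatives"),
       epochs = check_count(epochs, "epochs"),
       learning_rate = learning_rate,
       seed = check_count(seed, "seed", min = 0L))
}

#' Enumerate skip-gram (center, context) pairs of a corpus
#'
#' For every position i of every walk, emits the pair (walk[i], walk[j]) for
#' each j != i with |i - j| <= window. Used for corpus statistics and as the
#' reference enumeration of what the trainer consumes.
#'
#' @param corpus a `walk_corpus`.
#' @param window context radius (>= 1).
#' @return data.frame with character columns `center`, `context`.
#' @export
extract_pairs <- function(corpus, window) {
  window <- check_count(window, "window")
  res <- lapply(corpus$walks, function(wk) {
    L <- length(wk)
    if (L < 2L) return(NULL)
    ctr <- character(0); ctx <- character(0)
    for (i in seq_len(L)) {
      js <- max(1L, i - window):min(L, i + window)
      js <- js[js != i]
      ctr <- c(ctr, rep(wk[i], length(js)))
      ctx <- c(ctx, wk[js])
    }
    data.frame(center = ctr, context = ctx, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(center = character(0), context = character(0)))
  do.call(rbind, res)
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Maximizes `log sigmoid(u_c . v_ctx) + sum_k log sigmoid(-u_c . v_neg_k)`
#' over all windowed pairs by single-threaded SGD, negatives drawn from the
#' unigram distribution smoothed by the 0.75 power. Deterministic given
#' `params$seed`.
#'
#' @param corpus a `walk_corpus` (non-empty).
#' @param params an [embed_params()].
#' @return an `embedding_matrix`: list with `ids` (sorted gene ids),
#'   `vectors` (numeric matrix, one row per id, `params$dimension` columns,
#'   rownames = ids) and `epoch_loss` (mean SGNS loss per epoch).
#' @export
train_sgns <- function(corpus, params) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (!length(corpus$walks) || !sum(lengths(corpus$walks)))
    abort_validation("corpus is empty")
  ids <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  walks_idx <- lapply(corpus$walks, function(wk) match(wk, ids))
  set.seed(params$seed)
  fit <- cpp_train_sgns(walks_idx, length(ids),
                        as.integer(params$dimension),
                        as.integer(params$window),
                        as.integer(params$negatives),
                        as.integer(params$epochs),
                        params$learning_rate)
  vectors <- fit$vectors
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors,
                 epoch_loss = as.numeric(fit$epoch_loss),
                 params = params),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix: %d genes x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Build an embedding_matrix from a plain matrix
#' @param vectors numeric matrix with rownames giving gene ids.
#' @return an `embedding_matrix`.
#' @export
embedding_matrix <- function(vectors) {
  if (is.null(rownames(vectors)))
    abort_validation("vectors must have rownames (gene identifiers)")
  structure(list(ids = rownames(vectors), vectors = vectors,
                 epoch_loss = NULL, params = NULL),
            class = "embedding_matrix")
}

#' Save embeddings in word2vec text format
#'
#' First line `<count> <dimension>`, then one line per gene: the identifier
#' followed by the vector entries (>= 8 significant digits).
#'
#' @param matrix an `embedding_matrix` (or any matrix with rownames).
#' @param path output file path.
#' @export
save_embeddings <- function(matrix, path) {
  v <- if (inherits(matrix, "embedding_matrix")) matrix$vectors else matrix
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], formatC(v[i, ], format = "g",
                                               digits = 9)),
                     collapse = " "), con)
  invisible(path)
}

#' Load embeddings from word2vec text format
#' @param path input file path.
#' @return an `embedding_matrix`.
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("embedding file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), " +")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    abort_parse("malformed header: expected '<count> <dimension>'")
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1L != n)
    abort_parse(sprintf("header promises %d rows, file has %d", n,
                        length(lines) - 1L))
  ids <- character(n)
  vectors <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), " +")[[1]]
    if (length(f) != d + 1L)
      abort_parse(sprintf("row %d ('%s'): expected %d values, found %d",
                          i, f[1], d, length(f) - 1L))
    ids[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      abort_parse(sprintf("row %d ('%s'): non-numeric entry", i, f[1]))
    vectors[i, ] <- vals
  }
  rownames(vectors) <- ids
  embedding_matrix(vectors)
}
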