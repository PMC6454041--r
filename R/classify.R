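# Balanced negative sampling, SVM classification, stratified k-fold AUROC,
# pipeline variants and candidate ranking.

#' SVM hyperparameters
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C soft-margin cost (> 0, default 1).
#' @param gamma RBF width: `"scale"` (default; `1 / (n_features * var(X))`)
#'   or a positive number.
#' @return an `svm_params` list.
#' @export
svm_params <- function(kernel = c("rbf", "linear"), C = 1.0, gamma = "scale") {
  kernel <- match.arg(kernel)
  check_positive_scalar(C, "C")
  if (!identical(gamma, "scale")) check_positive_scalar(gamma, "gamma")
  list(kernel = kernel, C = C, gamma = gamma)
}

#' Cross-validation configuration
#'
#' @param k number of folds (>= 2, default 10).
#' @param seed integer RNG seed for the fold assignment.
#' @param stratified keep the class ratio in every fold (default `TRUE`).
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 10, seed = 1L, stratified = TRUE) {
  list(k = check_count(k, "k", min = 2L),
       seed = check_count(seed, "seed", min = 0L),
       stratified = isTRUE(stratified))
}

#' Sample a balanced negative gene set
#'
#' Uniform sample without replacement from the genes not in the positive
#' set, of exactly the positive set's size.
#'
#' @param all_genes universe of candidate genes (a [gene_set()] or character
#'   vector, e.g. the graph nodes).
#' @param positives the positive [gene_set()].
#' @param seed integer RNG seed.
#' @return a `gene_set` of negatives, disjoint from the positives.
#' @export
sample_negatives <- function(all_genes, positives, seed) {
  pool <- setdiff(sort(unique(as.character(all_genes))),
                  as.character(positives))
  n_pos <- length(unique(as.character(positives)))
  if (n_pos == 0L) abort_validation("positive set is empty")
  if (length(pool) < n_pos)
    abort_validation(sprintf(
      "only %d non-positive genes available but %d needed", length(pool), n_pos))
  set.seed(check_count(seed, "seed", min = 0L))
  gene_set(sample(pool, n_pos), label = "negatives")
}

#' Assemble a balanced labeled dataset
#'
#' Rows are the positives (label 1) followed by the negatives (label 0),
#' each block sorted by gene id for determinism.
#'
#' @param features numeric matrix with gene rownames.
#' @param positives,negatives disjoint [gene_set()]s with feature rows.
#' @return a `labeled_features` list with `ids`, `X`, `y`.
#' @export
make_dataset <- function(features, positives, negatives) {
  pos <- sort(unique(as.character(positives)))
  neg <- sort(unique(as.character(negatives)))
  overlap <- intersect(pos, neg)
  if (length(overlap))
    abort_validation(sprintf("positive and negative sets overlap: %s",
                             paste(head(overlap, 5), collapse = ", ")))
  ids <- c(pos, neg)
  missing <- setdiff(ids, rownames(features))
  if (length(missing))
    abort_validation(sprintf("no feature row for: %s",
                             paste(head(missing, 5), collapse = ", ")))
  structure(list(ids = ids,
                 X = features[ids, , drop = FALSE],
                 y = c(rep(1L, length(pos)), rep(0L, length(neg)))),
            class = "labeled_features")
}

#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' Over all (positive, negative) pairs, the fraction where the positive's
#' score exceeds the negative's, counting ties as 1/2. Computed from ranks.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels (1 = positive, 0 = negative).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort_validation("scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort("AUROC undefined: both classes must be present",
          "n2asvm_undefined_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified (or plain) fold assignment; returns integer fold id per sample
make_folds <- function(y, cv) {
  n <- length(y)
  if (cv$stratified) {
    if (any(table(y) < cv$k))
      abort_validation(sprintf(
        "stratified %d-fold CV needs >= %d samples per class", cv$k, cv$k))
    fold <- integer(n)
    set.seed(cv$seed)
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(cv$k), length(idx))
    }
  } else {
    if (n < cv$k) abort_validation("more folds than samples")
    set.seed(cv$seed)
    fold <- rep_len(seq_len(cv$k), n)[sample.int(n)]
  }
  fold
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.numeric(X))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(X) * v)
  } else gamma
}

fit_svm <- function(X, y, svm) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
             kernel = if (svm$kernel == "rbf") "radial" else "linear",
             cost = svm$C, gamma = resolve_gamma(svm$gamma, X),
             scale = FALSE)
}

# decision values oriented so larger = class "1"
decision_values <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # column name "a/b": positive values favour class a
  if (startsWith(colnames(dv)[1], "0/")) -dv[, 1] else dv[, 1]
}

#' Stratified k-fold cross-validated AUROC of an SVM
#'
#' Splits the balanced dataset into `cv$k` stratified folds, trains the SVM
#' on the remaining folds and scores the held-out fold by its decision
#' values; every sample is tested exactly once.
#'
#' @param data a [make_dataset()] result.
#' @param svm an [svm_params()].
#' @param cv a [cv_config()].
#' @return list with `fold_auroc` (length k) and `mean_auroc`.
#' @export
kfold_auroc <- function(data, svm = svm_params(), cv = cv_config()) {
  stopifnot(inherits(data, "labeled_features"))
  fold <- make_folds(data$y, cv)
  fa <- vapply(seq_len(cv$k), function(f) {
    tr <- fold != f; te <- !tr
    model <- fit_svm(data$X[tr, , drop = FALSE], data$y[tr], svm)
    auroc(decision_values(model, data$X[te, , drop = FALSE]), data$y[te])
  }, numeric(1))
  list(fold_auroc = fa, mean_auroc = mean(fa))
}

#' Train the final model and rank unlabeled genes by calibrated probability
#'
#' Trains the SVM on all labeled rows, fits a sigmoid (Platt) calibration on
#' cross-validated decision values, then scores every unlabeled gene by its
#' calibrated probability of being a disease gene. Ties are broken by gene
#' id so the ranking is deterministic.
#'
#' @param data a [make_dataset()] result (the full labeled set).
#' @param features feature matrix with rows for the unlabeled genes.
#' @param unlabeled character vector of gene ids to rank; must be disjoint
#'   from the labeled ids.
#' @param svm an [svm_params()].
#' @param calib_folds folds for the calibration decision values (default 5).
#' @param seed RNG seed for the calibration folds.
#' @return a `scored_gene_table` data.frame with columns `gene`, `score`
#'   (probability in \[0, 1\]), `rank`.
#' @export
rank_candidates <- function(data, features, unlabeled, svm = svm_params(),
                            calib_folds = 5, seed = 1L) {
  stopifnot(inherits(data, "labeled_features"))
  unlabeled <- unique(as.character(unlabeled))
  clash <- intersect(unlabeled, data$ids)
  if (length(clash))
    abort_validation(sprintf("unlabeled genes overlap the training set: %s",
                             paste(head(clash, 5), collapse = ", ")))
  missing <- setdiff(unlabeled, rownames(features))
  if (length(missing))
    abort_validation(sprintf("no feature row for: %s",
                             paste(head(missing, 5), collapse = ", ")))
  # cross-validated decision values for Platt calibration
  cvc <- cv_config(k = calib_folds, seed = seed)
  fold <- make_folds(data$y, cvc)
  dv_cv <- numeric(length(data$y))
  for (f in seq_len(cvc$k)) {
    tr <- fold != f
    model_f <- fit_svm(data$X[tr, , drop = FALSE], data$y[tr], svm)
    dv_cv[!tr] <- decision_values(model_f, data$X[!tr, , drop = FALSE])
  }
  calib <- suppressWarnings(
    glm(y ~ dv, data = data.frame(y = data$y, dv = dv_cv),
        family = binomial()))
  model <- fit_svm(data$X, data$y, svm)
  dv_new <- decision_values(model, features[unlabeled, , drop = FALSE])
  prob <- as.numeric(predict(calib, newdata = data.frame(dv = dv_new),
                             type = "response"))
  tab <- data.frame(gene = unlabeled, score = prob, stringsAsFactors = FALSE)
  ord <- order(-tab$score, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("scored_gene_table", "data.frame")
  tab
}

#' Run one pipeline variant end to end and evaluate it
#'
#' Variants:
#' * `"N2A-SVM"`: biased walks -> skip-gram embedding -> autoencoder code ->
#'   k-fold SVM AUROC (the full pipeline).
#' * `"N2V-SVM"`: walks -> embedding -> SVM (no dimension reduction).
#' * `"RWA-SVM"`: RWR diffusion-state features -> autoencoder -> SVM.
#' * `"RWR"`, `"SPL"`, `"ED"`: baseline proximity scores on the same labeled
#'   genes, one AUROC (no model fitting).
#'
#' All stage seeds are derived from `config$master_seed`, so a record is
#' reproducible from its provenance.
#'
#' @param graph a [gene_graph()].
#' @param positives a [gene_set()] of known disease genes (restricted to the
#'   graph).
#' @param variant one of `"N2A-SVM"`, `"N2V-SVM"`, `"RWA-SVM"`, `"RWR"`,
#'   `"SPL"`, `"ED"`.
#' @param config a [run_config()].
#' @param features optional precomputed feature matrix (gene rownames) to
#'   reuse across variants; when supplied, the feature-construction stages
#'   are skipped for the SVM variants.
#' @return an `eval_record` list: `variant`, `mean_auroc`, `fold_auroc`,
#'   `negatives`, `seeds`, `config`.
#' @export
run_pipeline <- function(graph, positives,
                         variant = c("N2A-SVM", "N2V-SVM", "RWA-SVM",
                                     "RWR", "SPL", "ED"),
                         config = run_config(), features = NULL) {
  variant <- match.arg(variant)
  positives <- restrict_to_graph(positives, graph)
  seeds <- list(negatives = derive_seed(config$master_seed, "negatives"),
                walks = derive_seed(config$master_seed, "walks"),
                embed = derive_seed(config$master_seed, "embed"),
                autoencoder = derive_seed(config$master_seed, "autoencoder"),
                cv = derive_seed(config$master_seed, "cv"))
  negatives <- sample_negatives(graph$nodes, positives, seeds$negatives)
  labeled <- c(as.character(positives), as.character(negatives))
  labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))

  if (variant %in% c("RWR", "SPL", "ED")) {
    scores <- switch(variant,
      RWR = rwr_score(graph, positives, labeled, config$rwr),
      SPL = spl_score(graph, positives, labeled),
      ED  = euclid_score(features %||% adjacency_features(graph),
                         positives, labeled))
    a <- auroc(scores, labels)
    return(structure(list(variant = variant, mean_auroc = a,
                          fold_auroc = NULL, scores = scores,
                          negatives = negatives, seeds = seeds,
                          config = config),
                     class = "eval_record"))
  }

  if (is.null(features)) {
    features <- pipeline_features(graph, variant, config, seeds)
  }
  cvc <- config$cv
  cvc$seed <- seeds$cv
  data <- make_dataset(features, positives, negatives)
  res <- kfold_auroc(data, config$svm, cvc)
  structure(list(variant = variant, mean_auroc = res$mean_auroc,
                 fold_auroc = res$fold_auroc, feature_dim = ncol(features),
                 negatives = negatives, seeds = seeds, config = config),
            class = "eval_record")
}

#' Build the feature matrix of an SVM pipeline variant
#'
#' @param graph a [gene_graph()].
#' @param variant `"N2A-SVM"`, `"N2V-SVM"` or `"RWA-SVM"`.
#' @param config a [run_config()].
#' @param seeds optional list of stage seeds (derived from
#'   `config$master_seed` when omitted).
#' @return numeric feature matrix with gene rownames.
#' @export
pipeline_features <- function(graph, variant, config = run_config(),
                              seeds = NULL) {
  if (is.null(seeds))
    seeds <- list(walks = derive_seed(config$master_seed, "walks"),
                  embed = derive_seed(config$master_seed, "embed"),
                  autoencoder = derive_seed(config$master_seed, "autoencoder"))
  if (variant %in% c("N2A-SVM", "N2V-SVM")) {
    wp <- config$walk; wp$seed <- seeds$walks
    ep <- config$embed; ep$seed <- seeds$embed
    corpus <- generate_walks(graph, wp)
    emb <- train_sgns(corpus, ep)
    if (variant == "N2V-SVM") return(emb$vectors)
    ap <- config$ae; ap$seed <- seeds$autoencoder
    ap$layer_sizes[1] <- ncol(emb$vectors)
    ap <- do.call(ae_params, ap)
    enc <- train_autoencoder(emb$vectors, ap)
    return(encode(enc, emb$vectors))
  }
  if (variant == "RWA-SVM") {
    feats <- rwr_feature_matrix(graph, config$rwr)
    ap <- config$ae; ap$seed <- seeds$autoencoder
    ap$layer_sizes[1] <- ncol(feats)
    ap <- do.call(ae_params, ap)
    enc <- train_autoencoder(feats, ap)
    return(encode(enc, feats))
  }
  abort_validation(sprintf("variant '%s' has no feature matrix", variant))
}

#' @export
print.eval_record <- function(x, ...) {
  cat(sprintf("%s: mean AUROC %.4f", x$variant, x$mean_auroc))
  if (!is.null(x$fold_auroc))
    cat(sprintf(" (%d folds, sd %.4f)", length(x$fold_auroc),
                stats::sd(x$fold_auroc)))
  cat("\n")
  invisible(x)
}
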