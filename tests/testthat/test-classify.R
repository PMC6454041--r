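# Negative sampling, AUROC, cross-validation, ranking, pipeline records.

test_that("negative sampling is balanced, disjoint and reproducible", {
  all_g <- sprintf("g%02d", 1:10)
  pos <- gene_set(all_g[1:3])
  neg <- sample_negatives(all_g, pos, seed = 1)
  expect_length(neg, 3L)
  expect_length(intersect(as.character(neg), as.character(pos)), 0L)
  expect_identical(as.character(sample_negatives(all_g, pos, seed = 1)),
                   as.character(neg))
  draws <- unique(vapply(1:100, function(s)
    paste(sort(as.character(sample_negatives(all_g, pos, s))),
          collapse = ","), ""))
  expect_gt(length(draws), 10)
  expect_error(sample_negatives(all_g, gene_set(all_g), seed = 1),
               class = "n2asvm_validation_error")
  expect_error(sample_negatives(all_g[1:5], gene_set(all_g[1:3]), seed = 1),
               class = "n2asvm_validation_error")
})

test_that("labeled datasets are balanced with deterministic row order", {
  feats <- noise_features(10, 4, seed = 801, ids = sprintf("g%02d", 1:10))
  d <- make_dataset(feats, gene_set(c("g03", "g01", "g02")),
                    gene_set(c("g09", "g07", "g08")))
  expect_equal(d$ids, c("g01", "g02", "g03", "g07", "g08", "g09"))
  expect_equal(d$y, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(nrow(d$X), 6L)
  expect_error(make_dataset(feats, gene_set(c("g01", "g02")),
                            gene_set(c("g02", "g03"))),
               "overlap", class = "n2asvm_validation_error")
  expect_error(make_dataset(feats, gene_set("g01"), gene_set("nope")),
               "nope", class = "n2asvm_validation_error")
})

test_that("AUROC equals Mann-Whitney pair counting", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)),
               class = "n2asvm_undefined_metric_error")

  set.seed(802)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(runif(n), 2))   # rounded to force ties
    expect_equal(auroc(scores, labels), auroc_pair_count(scores, labels))
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(803)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(2 * scores + 7, labels), a)
  expect_equal(auroc(rank(scores), labels), a)
})

test_that("stratified folds partition both classes evenly", {
  y <- c(rep(1L, 20), rep(0L, 20))
  cv <- cv_config(k = 10, seed = 4)
  fold <- n2asvm:::make_folds(y, cv)
  expect_setequal(unique(fold), 1:10)
  for (f in 1:10) {
    expect_equal(sum(fold == f & y == 1), 2)
    expect_equal(sum(fold == f & y == 0), 2)
  }
  expect_error(n2asvm:::make_folds(c(1L, 0L), cv_config(k = 5)),
               class = "n2asvm_validation_error")
})

test_that("cross-validated AUROC hits the separable and null regimes", {
  ids <- sprintf("g%02d", 1:40)
  y <- c(rep(1L, 20), rep(0L, 20))
  # perfect signal: features are the label duplicated
  Xp <- cbind(y, y) + noise_features(40, 2, seed = 804) * 0.01
  rownames(Xp) <- ids
  d <- make_dataset(Xp, gene_set(ids[1:20]), gene_set(ids[21:40]))
  expect_equal(kfold_auroc(d, svm_params(), cv_config(k = 10, seed = 1))$mean_auroc,
               1.0)
  # pure noise: mean over repetitions near chance
  means <- vapply(1:5, function(r) {
    Xn <- noise_features(200, 8, seed = 810 + r,
                         ids = sprintf("q%03d", 1:200))
    dn <- make_dataset(Xn, gene_set(sprintf("q%03d", 1:100)),
                       gene_set(sprintf("q%03d", 101:200)))
    kfold_auroc(dn, svm_params(), cv_config(k = 5, seed = r))$mean_auroc
  }, numeric(1))
  expect_gt(mean(means), 0.4)
  expect_lt(mean(means), 0.6)
})

test_that("candidate ranking is calibrated, ordered and consistent", {
  set.seed(820)
  ids <- sprintf("g%02d", 1:40)
  y <- c(rep(1L, 20), rep(0L, 20))
  X <- cbind(y * 2 - 1, y * 2 - 1) + noise_features(40, 2, seed = 821) * 0.3
  rownames(X) <- ids
  d <- make_dataset(X, gene_set(ids[1:20]), gene_set(ids[21:40]))
  newX <- rbind(pos_like = c(1, 1), neg_like = c(-1, -1),
                mid = c(0, 0), x2 = c(0.9, 1.1), x3 = c(-1.2, -0.8))
  tab <- rank_candidates(d, rbind(X, newX), rownames(newX), svm_params(),
                         seed = 2)
  expect_s3_class(tab, "scored_gene_table")
  expect_equal(tab$rank, 1:5)
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_lt(which(tab$gene == "pos_like"), which(tab$gene == "neg_like"))
  expect_error(rank_candidates(d, rbind(X, newX), c("g01", "mid")),
               class = "n2asvm_validation_error")
})

test_that("pipeline records carry provenance and differ only where stated", {
  fx <- planted_partition(planted_config(block_sizes = c(30, 40, 40),
                                         n_positives = 15, seed = 5))
  cfg <- demo_config(3)
  cfg$embed$epochs <- 2L
  rec_a <- run_pipeline(fx$graph, fx$positives, "N2A-SVM", cfg)
  rec_v <- run_pipeline(fx$graph, fx$positives, "N2V-SVM", cfg)
  expect_equal(rec_a$seeds, rec_v$seeds)
  expect_identical(as.character(rec_a$negatives),
                   as.character(rec_v$negatives))
  expect_equal(rec_a$feature_dim, 16L)
  expect_equal(rec_v$feature_dim, 64L)
  expect_length(rec_a$fold_auroc, 10L)

  # baselines produce a single AUROC without folds
  rec_ed <- run_pipeline(fx$graph, fx$positives, "ED", cfg)
  expect_null(rec_ed$fold_auroc)
  expect_true(rec_ed$mean_auroc >= 0 && rec_ed$mean_auroc <= 1)
})

test_that("a full pipeline run is reproducible from its master seed", {
  fx <- planted_partition(planted_config(block_sizes = c(24, 30, 30),
                                         n_positives = 12, seed = 6))
  cfg <- demo_config(4)
  cfg$walk$walk_length <- 20L; cfg$walk$walks_per_node <- 3L
  cfg$embed$epochs <- 2L; cfg$ae$epochs <- 30L
  r1 <- run_pipeline(fx$graph, fx$positives, "N2A-SVM", cfg)
  r2 <- run_pipeline(fx$graph, fx$positives, "N2A-SVM", cfg)
  expect_identical(r1$fold_auroc, r2$fold_auroc)
  expect_identical(as.character(r1$negatives), as.character(r2$negatives))
})
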