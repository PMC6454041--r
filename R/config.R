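# Run configuration: one object bundling every stage's parameter block plus
# a master seed from which stage seeds are derived (see derive_seed), so a
# whole pipeline run is reproducible from a single integer.

#' Bundle all pipeline parameters into one run configuration
#'
#' Any block can be overridden by passing a list built with the matching
#' constructor ([walk_params()], [embed_params()], [ae_params()],
#' [rwr_params()], [svm_params()], [cv_config()], [planted_config()]).
#' Stage seeds inside the blocks are ignored by [run_pipeline()], which
#' derives them from `master_seed`.
#'
#' @param master_seed integer master seed.
#' @param walk,embed,ae,rwr,svm,cv,planted parameter blocks.
#' @return a `run_config` list.
#' @export
run_config <- function(master_seed = 1L,
                       walk = walk_params(),
                       embed = embed_params(),
                       ae = ae_params(),
                       rwr = rwr_params(),
                       svm = svm_params(),
                       cv = cv_config(),
                       planted = planted_config()) {
  structure(list(master_seed = check_count(master_seed, "master_seed", 0L),
                 walk = walk, embed = embed, ae = ae, rwr = rwr,
                 svm = svm, cv = cv, planted = planted),
            class = "run_config")
}

#' Desk-scale configuration for the planted demonstration network
#'
#' The full-scale defaults (512-dimensional embeddings compressed to 200)
#' are sized for an interactome of ~13k genes. On the 300-gene planted
#' fixture that width is badly over-parameterized and slow, so the
#' demonstration configuration uses 5 walks of length 40 per node, window-5
#' skip-gram with 64 dimensions over 3 epochs, and a 64-16 autoencoder
#' trained for 150 epochs. These sizes are the package's reference settings
#' for the planted fixture, used by the examples, the test-suite and the
#' evaluation script alike.
#'
#' @param master_seed integer master seed.
#' @return a `run_config`.
#' @export
demo_config <- function(master_seed = 1L) {
  run_config(
    master_seed = master_seed,
    walk = walk_params(p = 2, q = 0.5, walk_length = 40, walks_per_node = 5),
    embed = embed_params(dimension = 64, window = 5, negatives = 5,
                         epochs = 3),
    ae = ae_params(layer_sizes = c(64, 16), epochs = 150, batch_size = 32,
                   learning_rate = 0.01))
}

#' Read a run configuration from a YAML file
#'
#' The file holds one top-level key per block (`walk`, `embed`, `ae`,
#' `rwr`, `svm`, `cv`, `planted`) plus `master_seed`; omitted keys take the
#' package defaults and unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("master_seed", "walk", "embed", "ae", "rwr", "svm", "cv",
             "planted")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  ctors <- list(walk = walk_params, embed = embed_params, ae = ae_params,
                rwr = rwr_params, svm = svm_params, cv = cv_config,
                planted = planted_config)
  args <- list(master_seed = raw$master_seed %||% 1L)
  for (blk in names(ctors)) {
    over <- raw[[blk]] %||% list()
    bad <- setdiff(names(over), names(formals(ctors[[blk]])))
    if (length(bad))
      abort_validation(sprintf("unknown key(s) in '%s' block: %s", blk,
                               paste(bad, collapse = ", ")))
    args[[blk]] <- do.call(ctors[[blk]], over)
  }
  do.call(run_config, args)
}

#' Provenance header lines for written artifacts
#' @param config a `run_config`.
#' @param stage character stage name.
#' @return named character vector suitable for the `provenance` argument of
#'   the writer functions.
#' @export
config_provenance <- function(config, stage) {
  c(package = sprintf("n2asvm %s",
                      as.character(utils::packageVersion("n2asvm"))),
    stage = stage,
    master_seed = as.character(config$master_seed))
}
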