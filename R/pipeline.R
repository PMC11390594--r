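#' Seeded end-to-end run over both halves of the package
#'
#' Orchestrates the stages the analysis drivers use interactively:
#' generate a synthetic database, run the meta-analysis (median
#' significance, Venn partition, recovery scoring, inhibition contrasts),
#' simulate the model bundle and evaluate the phenotype criteria. Every
#' artifact written is recorded in a manifest with its MD5 hash, so a
#' rerun with the same config can be checked for byte-identical
#' reproduction of the stochastic stages.
#'
#' @param out_dir Output directory for CSV artifacts.
#' @param seed Integer seed driving all stochastic stages.
#' @param stages Subset of `c("synth", "meta", "model")`; empty runs
#'   nothing and returns an empty manifest.
#' @param config A [generator_config()] for the synthetic stage (its
#'   seed is overridden by `seed`).
#' @param alpha Significance level for the median calls.
#' @return A list with `manifest` (data frame of `path`, `md5`) and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         stages = c("synth", "meta", "model"),
                         config = generator_config(), alpha = 0.05) {
  stopifnot(all(stages %in% c("synth", "meta", "model")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character()
  results <- list()
  db <- NULL
  if ("synth" %in% stages) {
    config$seed <- as.integer(seed)
    db <- generate_database(config)
    manifest <- c(manifest, save_database(db, out_dir))
    truth_path <- file.path(out_dir, "truth_classes.csv")
    utils::write.csv(db$truth$classes, truth_path, row.names = FALSE)
    manifest <- c(manifest, truth_path)
    results$db <- db
  }
  if ("meta" %in% stages) {
    if (is.null(db)) stop("meta stage needs the synth stage")
    clean <- remove_outliers(db$genestats, db$comparisons)
    calls <- median_significance(clean, alpha = alpha)
    part <- venn_partition(calls)
    rec <- score_recovery(part, db$truth)
    calls_path <- file.path(out_dir, "median_calls.csv")
    utils::write.csv(calls, calls_path, row.names = FALSE)
    core_path <- file.path(out_dir, "core_signature.csv")
    utils::write.csv(part$core, core_path, row.names = FALSE)
    manifest <- c(manifest, calls_path, core_path)
    results$calls <- calls; results$partition <- part
    results$recovery <- rec
    results$contrast <- inhibition_contrast(db, "p53_inhibition",
                                            "DDIS", "CDKN1A")
  }
  if ("model" %in% stages) {
    bundle <- simulate_bundle()
    crit <- evaluate_criteria(bundle)
    for (nm in names(bundle)) {
      p <- file.path(out_dir, sprintf("trajectory_%s.csv", nm))
      write_trajectory(bundle[[nm]], p)
      manifest <- c(manifest, p)
    }
    crit_path <- file.path(out_dir, "criteria.csv")
    utils::write.csv(as.data.frame(crit), crit_path, row.names = FALSE)
    manifest <- c(manifest, crit_path)
    results$criteria <- crit
  }
  list(manifest = data.frame(path = manifest,
                             md5 = as.character(tools::md5sum(manifest)),
                             row.names = NULL),
       results = results)
}
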