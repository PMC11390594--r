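#' Contrast intervention comparisons against untreated controls
#'
#' Tests whether an intervention (p53 or RelA inhibition) shifts a gene's
#' logFC within one senescence inducer. The inhibited group contains all
#' comparisons of that inducer flagged with the intervention, excluding
#' replicative senescence and any comparison later than `max_day` days
#' (late outliers distort the inhibition window); the control group
#' contains all intervention-free comparisons of the inducer with a
#' day-denominated time in `[control_days[1], control_days[2]]`. Because
#' comparisons from one study share study-level effects, each group is
#' aggregated to one mean logFC per study before testing; the study means
#' are compared with the unpaired rank-sum test (the groups are different
#' studies with no pairing key).
#'
#' @param db A `"senodb"` database (comparisons will be binned if needed).
#' @param intervention `"p53_inhibition"` or `"RelA_inhibition"`.
#' @param inducer One inducer category.
#' @param gene Gene symbol.
#' @param control_days Inclusive day window for controls (default 1-11).
#' @param max_day Latest day admitted to the inhibited group (default 27).
#' @return A list of class `"inhibition_contrast"` with per-group
#'   summaries (`n`, `median_logfc`), the [rank_test()] result, and its
#'   significance stars.
#' @export
inhibition_contrast <- function(db, intervention = c("p53_inhibition",
                                                     "RelA_inhibition"),
                                inducer, gene, control_days = c(1, 11),
                                max_day = 27) {
  intervention <- match.arg(intervention)
  cm <- db$comparisons
  if (is.null(cm$time_bin)) cm <- bin_comparisons(cm)
  inhibited <- filter_comparisons(cm, list(
    intervention = intervention, inducer = inducer,
    exclude_inducer = "REP", max_day = max_day))
  control <- filter_comparisons(cm, list(
    intervention = "none", inducer = inducer,
    min_day = control_days[1], max_day = control_days[2]))
  gs <- db$genestats[normalize_gene(db$genestats$gene) ==
                       normalize_gene(gene), ]
  study_means <- function(group) {
    sel <- gs[gs$comparison_id %in% group$comparison_id, ]
    study <- group$study_accession[match(sel$comparison_id,
                                         group$comparison_id)]
    if (!nrow(sel)) return(numeric(0))
    as.numeric(tapply(sel$logFC, study, mean))
  }
  x <- study_means(inhibited)
  y <- study_means(control)
  if (!length(x))
    stop(sprintf("no %s comparisons for %s / %s", intervention, inducer,
                 gene))
  if (!length(y))
    stop(sprintf("no control comparisons in days %d-%d for %s / %s",
                 control_days[1], control_days[2], inducer, gene))
  test <- rank_test(x, y, mode = "unpaired")
  structure(list(
    gene = gene, inducer = inducer, intervention = intervention,
    inhibited = list(n = length(x), median_logfc = stats::median(x)),
    control = list(n = length(y), median_logfc = stats::median(y)),
    direction = sign(stats::median(x) - stats::median(y)),
    test = test, stars = significance_stars(test$p)),
    class = "inhibition_contrast")
}

#' @export
print.inhibition_contrast <- function(x, ...) {
  cat(sprintf("%s on %s in %s: median logFC %.3f (n=%d) vs control %.3f (n=%d), p = %.4g %s\n",
              x$intervention, x$gene, x$inducer,
              x$inhibited$median_logfc, x$inhibited$n,
              x$control$median_logfc, x$control$n, x$test$p, x$stars))
  invisible(x)
}
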