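#' Inverted p-value statistic
#'
#' Maps a (p, logFC) pair to `(1 / p) * sign(logFC)`, placing significant
#' upregulation and significant downregulation at opposite ends of one
#' scale with non-significant observations in the middle. Observations
#' with `logFC == 0` have an undefined sign and are returned as `NA`
#' (callers exclude them with a recorded count).
#'
#' @param p Numeric vector in (0, 1].
#' @param logFC Numeric vector, same length.
#' @return Signed numeric vector; `NA` where `logFC == 0`.
#' @export
invert_p <- function(p, logFC) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  out <- sign(logFC) / p
  out[logFC == 0] <- NA_real_
  out
}

#' Tukey-fence outlier mask for one gene x time-group sample
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). A value is an outlier iff it lies strictly
#' below `Q1 - 1.5 IQR` or strictly above `Q3 + 1.5 IQR`, with fences
#' computed once from the original sample (no iterative re-fencing).
#' Groups smaller than `min_group_size` pass through unfiltered: fences
#' from two or three points are dominated by the points themselves.
#'
#' @param values Numeric vector (one gene, one time group).
#' @param min_group_size Groups below this size are not filtered
#'   (default 4).
#' @return A list with `keep` (logical mask, `TRUE` = retained) and
#'   `rule` (list with `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`,
#'   `filtered` flag).
#' @export
filter_outliers <- function(values, min_group_size = 4) {
  n <- length(values)
  if (n == 0)
    return(list(keep = logical(0),
                rule = list(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                            lower_fence = NA_real_, upper_fence = NA_real_,
                            filtered = FALSE)))
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7,
                              names = FALSE))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  filtered <- n >= min_group_size
  keep <- if (filtered) values >= lo & values <= hi else rep(TRUE, n)
  list(keep = keep,
       rule = list(q1 = q[1], q3 = q[2], iqr = iqr, lower_fence = lo,
                   upper_fence = hi, filtered = filtered))
}

#' Remove gross logFC outliers per gene and time group
#'
#' Applies [filter_outliers()] to the logFC values of every
#' (gene, time_bin) group of a gene-stat table joined to binned
#' comparisons, mirroring the pre-analysis cleaning step the aggregation
#' statistics assume.
#'
#' @param genestats Gene-stat data frame (`comparison_id`, `gene`,
#'   `logFC`, `p`).
#' @param comparisons Binned comparison data frame (needs `time_bin`).
#' @param min_group_size Passed to [filter_outliers()].
#' @return `genestats` with rows outside the fences removed and columns
#'   `time_bin`, `inducer`, `intervention` carried over from the
#'   comparison table.
#' @export
remove_outliers <- function(genestats, comparisons, min_group_size = 4) {
  j <- match(genestats$comparison_id, comparisons$comparison_id)
  if (anyNA(j)) stop("gene stats reference unknown comparison")
  gs <- genestats
  gs$time_bin <- comparisons$time_bin[j]
  gs$inducer <- comparisons$inducer[j]
  gs$intervention <- comparisons$intervention[j]
  key <- paste(normalize_gene(gs$gene), gs$time_bin)
  keep <- unlist(lapply(split(seq_len(nrow(gs)), key), function(idx) {
    idx[filter_outliers(gs$logFC[idx], min_group_size)$keep]
  }), use.names = FALSE)
  gs[sort(keep), , drop = FALSE]
}

#' Median-significance calls per gene and inducer
#'
#' For every gene and inducer, takes the median of the inverted p-values
#' over all retained comparisons of that inducer (even counts average the
#' two central values; zero-logFC observations are excluded first) and
#' calls the gene `up` if the median is at least `1 / alpha`, `down` if
#' at most `-1 / alpha`, otherwise `ns`. Because the median mixes signs,
#' genes significant in both directions across comparisons cancel to
#' non-significance rather than being double-counted.
#'
#' @param genestats Outlier-filtered gene-stat table carrying an
#'   `inducer` column (see [remove_outliers()]); rows with
#'   `intervention != "none"` are ignored if that column is present.
#' @param alpha Significance level for the median call (default 0.05).
#' @return Data frame with `gene`, `inducer`, `median_pi`, `n`, `call`.
#' @export
median_significance <- function(genestats, alpha = 0.05) {
  gs <- genestats
  if (!is.null(gs$intervention)) gs <- gs[gs$intervention == "none", ]
  pi <- invert_p(gs$p, gs$logFC)
  ok <- !is.na(pi)
  gs <- gs[ok, ]; pi <- pi[ok]
  key <- paste(normalize_gene(gs$gene), gs$inducer, sep = "\r")
  med <- tapply(pi, key, stats::median)
  n <- tapply(pi, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    inducer = vapply(parts, `[`, "", 2),
    median_pi = as.numeric(med), n = as.integer(n),
    stringsAsFactors = FALSE)
  thr <- 1 / alpha
  out$call <- ifelse(out$median_pi >= thr, "up",
                     ifelse(out$median_pi <= -thr, "down", "ns"))
  rownames(out) <- NULL
  out[order(out$inducer, out$gene), ]
}

#' Partition significant genes by the inducers that call them
#'
#' Given per-inducer significance calls for exactly the four
#' meta-analysed inducers, assigns every significant gene to the Venn
#' cell of the exact subset of inducers in which it is significant. The
#' four-way cell (the core signature) is additionally annotated `up`,
#' `down`, or `inducer_dependent` by direction agreement across the four
#' calls.
#'
#' @param calls Output of [median_significance()] restricted to four
#'   inducers (default set `DDIS`, `OIS`, `REP`, `BYS`).
#' @param inducers The four inducers expected in `calls`.
#' @return A list of class `"venn_partition"` with `cells` (named list of
#'   gene vectors, names like `"DDIS+OIS"`), and `core` (data frame for
#'   the four-way cell: `gene`, `direction`).
#' @export
venn_partition <- function(calls, inducers = c("DDIS", "OIS", "REP",
                                               "BYS")) {
  if (length(inducers) != 4) stop("exactly four inducers required")
  missing <- setdiff(inducers, unique(calls$inducer))
  if (length(missing)) stop("missing inducer in calls: ", missing[1])
  sig <- calls[calls$call != "ns" & calls$inducer %in% inducers, ]
  cells <- list()
  if (nrow(sig)) {
    memb <- tapply(sig$inducer, sig$gene, function(x)
      paste(inducers[inducers %in% x], collapse = "+"))
    cells <- split(names(memb), unname(memb))
    cells <- lapply(cells, sort)
  }
  four_key <- paste(inducers, collapse = "+")
  core_genes <- if (four_key %in% names(cells)) cells[[four_key]]
                else character(0)
  direction <- vapply(core_genes, function(g) {
    d <- sig$call[sig$gene == g]
    if (all(d == "up")) "up"
    else if (all(d == "down")) "down"
    else "inducer_dependent"
  }, "")
  structure(list(cells = cells,
                 core = data.frame(gene = core_genes,
                                   direction = unname(direction),
                                   stringsAsFactors = FALSE)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  sizes <- vapply(x$cells, length, 0L)
  cat("venn partition over", length(x$cells), "non-empty cells\n")
  for (nm in names(sizes)) cat(sprintf("  %-22s %d\n", nm, sizes[nm]))
  if (nrow(x$core))
    cat("core signature:", sum(x$core$direction == "up"), "up,",
        sum(x$core$direction == "down"), "down,",
        sum(x$core$direction == "inducer_dependent"),
        "inducer-dependent\n")
  invisible(x)
}

#' Score core-signature recovery against planted truth
#'
#' @param partition A [venn_partition()].
#' @param truth The `truth` element of a generated database.
#' @return List with `sensitivity` (fraction of planted core genes in the
#'   four-way cell) and `null_fpr` (fraction of null genes in it).
#' @export
score_recovery <- function(partition, truth) {
  core_found <- partition$core$gene
  list(sensitivity = mean(truth$panel$core %in% core_found),
       null_fpr = mean(truth$panel$null %in% core_found))
}
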