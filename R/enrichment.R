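#' Minimal preranked enrichment scorer
#'
#' Weighted Kolmogorov-Smirnov-style running-sum statistic on a ranked
#' gene list. Genes are sorted by decreasing score; walking down the
#' list, hitting a set member increments the running sum by
#' `|score| / sum(|score| over members)` (weight exponent 1) and missing
#' one decrements it by `1 / (N - m)`. The enrichment score ES is the
#' extremum of the running sum (largest in absolute value), so
#' `|ES| <= 1` by construction. The null is generated by random
#' gene-label permutation; NES divides ES by the mean |null ES| of the
#' same sign, and the permutation p-value is computed among the same-sign
#' null draws, `(1 + #{same-sign null with |ES_null| >= |ES|}) /
#' (1 + #{same-sign null})`, so it is approximately uniform for a random
#' gene set.
#'
#' @param scores Named numeric vector (gene -> ranking score, e.g. a
#'   median inverted p-value).
#' @param gene_set Character vector of member genes; must be a subset of
#'   `names(scores)`, of size between 2 and `N - 2`.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Optional integer seed for the permutation stream.
#' @return A list of class `"enrichment_result"` with `es`, `nes`,
#'   `perm_p`, `n_perm`, `size`.
#' @export
preranked_enrichment <- function(scores, gene_set, n_perm = 1000,
                                 seed = NULL) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  if (n_perm < 100) stop("n_perm must be >= 100")
  gene_set <- unique(normalize_gene(gene_set))
  genes <- normalize_gene(names(scores))
  if (!all(gene_set %in% genes)) stop("gene set outside ranking domain")
  N <- length(scores)
  m <- length(gene_set)
  if (m < 2 || m > N - 2) stop("gene set size must be in [2, N - 2]")
  ord <- order(scores, decreasing = TRUE)
  s <- abs(scores[ord])
  hit <- genes[ord] %in% gene_set
  es <- running_sum_extremum(s, hit)
  if (!is.null(seed)) set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    running_sum_extremum(s, sample(hit))
  }, 0)
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  perm_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, perm_p = perm_p,
                 n_perm = n_perm, size = m),
            class = "enrichment_result")
}

running_sum_extremum <- function(abs_scores, hit) {
  w_hit <- sum(abs_scores[hit])
  inc <- ifelse(hit,
                if (w_hit > 0) abs_scores / w_hit else 1 / sum(hit),
                -1 / sum(!hit))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES = %.4f, NES = %.3f, permutation p = %.4g (%d perms, set size %d)\n",
              x$es, x$nes, x$perm_p, x$n_perm, x$size))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}
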