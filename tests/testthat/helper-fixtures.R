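# Small in-code fixtures shared across the suite.

tiny_db <- function() {
  studies <- data.frame(
    accession = c("GSE-A", "GSE-B"),
    inducers = c("DDIS", "OIS;REP"),
    control_types = c("proliferating", "proliferating"),
    cell_lines = c("IMR90", "WI38"),
    timepoints = c("6:days", "7:days;88:PD"),
    platform = "rnaseq", stringsAsFactors = FALSE)
  comparisons <- data.frame(
    comparison_id = c("A-c1", "B-c1", "B-c2"),
    study_accession = c("GSE-A", "GSE-B", "GSE-B"),
    inducer = c("DDIS", "OIS", "REP"),
    control_type = "proliferating",
    cell_line = c("IMR90", "WI38", "WI38"),
    time_value = c(6, 7, 88),
    time_unit = c("days", "days", "PD"),
    intervention = "none", platform = "rnaseq",
    stringsAsFactors = FALSE)
  genestats <- data.frame(
    comparison_id = rep(c("A-c1", "B-c1"), each = 2),
    gene = rep(c("CDKN1A", "CDKN2A"), 2),
    logFC = c(1.2, 0.3, 0.8, 1.5),
    p = c(0.01, 0.4, 0.03, 0.002),
    stringsAsFactors = FALSE)
  structure(list(studies = studies, comparisons = comparisons,
                 genestats = genestats), class = "senodb")
}

# Brute-force enumeration oracles for the rank tests (independent of the
# generating-function implementation).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

enum_rank_sum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  sets <- utils::combn(length(r), m)
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Type-7 quartile oracle written from the interpolation definition.
oracle_quartile <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

small_model_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle()
    cache
  }
})
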