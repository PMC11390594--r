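#' Wilcoxon rank tests with exact tie-aware null distributions
#'
#' `rank_test()` provides the paired signed-rank test and the unpaired
#' rank-sum test used by the time-bin and inhibition contrasts. For small
#' samples the two-sided p-value is exact even in the presence of ties:
#' the null distribution of the statistic over tie-averaged ranks is built
#' by generating-function convolution over doubled ranks (which are
#' integers), equivalent to full enumeration of all sign assignments
#' (paired) or group labellings (unpaired). Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' Paired mode drops zero differences; if all differences are zero the
#' test is degenerate and returns p = 1 with a warning.
#'
#' @param x,y Numeric samples; equal length required for paired mode.
#' @param mode `"paired"` (signed-rank on `x - y`, or on `x` alone if `y`
#'   is omitted) or `"unpaired"` (rank-sum).
#' @param exact_limit Largest effective sample size (pairs after
#'   zero-dropping, or combined size) for the exact branch (default 25).
#' @return A list of class `"rank_test"`: `statistic` (W+ for paired, the
#'   rank sum of `x` for unpaired), `p`, `method`, `n`.
#' @export
rank_test <- function(x, y = NULL, mode = c("paired", "unpaired"),
                      exact_limit = 25) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    d <- if (is.null(y)) x else {
      if (length(x) != length(y)) stop("paired mode requires equal lengths")
      x - y
    }
    d <- d[is.finite(d)]
    if (!length(d)) stop("no observations")
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      warning("all differences are zero; degenerate test")
      return(structure(list(statistic = 0, p = 1,
                            method = "signed_rank_exact", n = 0L),
                       class = "rank_test"))
    }
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    if (n <= exact_limit) {
      dist <- signed_rank_distribution(r)
      p <- two_sided_from_dist(dist, 2 * w)
      method <- "signed_rank_exact"
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(ties^3 - ties) / 48
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "signed_rank_normal"
    }
    structure(list(statistic = w, p = p, method = method, n = n),
              class = "rank_test")
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    m <- length(x); n <- length(y)
    if (m == 0 || n == 0) stop("both groups must be non-empty")
    r <- rank(c(x, y))
    w <- sum(r[seq_len(m)])
    N <- m + n
    if (N <= exact_limit) {
      dist <- rank_sum_distribution(r, m)
      p <- two_sided_from_dist(dist, 2 * w)
      method <- "rank_sum"
    } else {
      mu <- m * (N + 1) / 2
      ties <- table(r)
      sigma2 <- m * n / 12 *
        ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "rank_sum"
    }
    structure(list(statistic = w, p = p, method = method,
                   n = c(m, n)), class = "rank_test")
  }
}

# Null distribution of 2*W+ over sign assignments: probability vector
# indexed by doubled statistic 0..sum(2r).
signed_rank_distribution <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  dist
}

# Null distribution of 2*(rank sum of the size-m group) over labellings.
rank_sum_distribution <- function(ranks, m) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # dp[[k]] = counts over doubled sums using exactly k-1 chosen ranks
  dp <- lapply(seq_len(m + 1), function(i) numeric(total + 1))
  dp[[1]][1] <- 1
  for (r in r2) {
    for (k in rev(seq_len(m))) {
      src <- dp[[k]]
      shifted <- c(numeric(r), src[seq_len(total + 1 - r)])
      dp[[k + 1]] <- dp[[k + 1]] + shifted
    }
  }
  dp[[m + 1]] / choose(length(ranks), m)
}

two_sided_from_dist <- function(dist, w2) {
  idx <- w2 + 1
  lower <- sum(dist[seq_len(min(idx, length(dist)))])
  upper <- sum(dist[seq(min(idx, length(dist)), length(dist))])
  min(1, 2 * min(lower, upper))
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: W = %g, n = %s, p = %.5g %s\n", x$method, x$statistic,
              paste(x$n, collapse = "/"), x$p, significance_stars(x$p)))
  invisible(x)
}

#' Significance stars at the fixed thresholds used in figure annotation
#'
#' Thresholds 0.05, 0.01, 0.001, 0.0001 map to one to four stars; no
#' multiple-testing correction is applied anywhere in the package.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of `""` to `"****"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) return("")
    paste(rep("*", sum(pp < c(0.05, 0.01, 0.001, 0.0001))), collapse = "")
  }, "")
}
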