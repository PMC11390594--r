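test_that("inverted p evaluates the defining formula", {
  expect_equal(invert_p(0.05, 2.3), 20)
  expect_equal(invert_p(0.01, -0.5), -100)
  expect_equal(invert_p(1, 3), 1)
  expect_true(is.na(invert_p(0.5, 0)))
  expect_error(invert_p(0, 1), "\\(0, 1\\]")
  expect_error(invert_p(1.2, 1), "\\(0, 1\\]")
  # antisymmetric in the sign of logFC; |value| strictly decreasing in p
  set.seed(1)
  p <- runif(200, 1e-6, 1)
  fc <- rnorm(200)
  fc[fc == 0] <- 1
  expect_equal(invert_p(p, fc), -invert_p(p, -fc))
  p_sorted <- sort(p)
  expect_true(all(diff(abs(invert_p(p_sorted, 1))) < 0))
})

test_that("fences match the worked example and the quartile oracle", {
  res <- filter_outliers(c(1, 2, 3, 4, 100))
  expect_equal(res$rule$lower_fence, -1)
  expect_equal(res$rule$upper_fence, 7)
  expect_equal(res$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # zero IQR: identical values sit on the fences, none removed
  expect_true(all(filter_outliers(c(5, 5, 5, 5))$keep))
  # small groups bypass filtering entirely
  expect_true(all(filter_outliers(c(1, 100, -100))$keep))
  expect_equal(filter_outliers(numeric(0))$keep, logical(0))
  # random-sample agreement with the interpolation oracle
  set.seed(2)
  for (i in 1:30) {
    x <- rnorm(sample(4:40, 1), sd = sample(1:5, 1))
    res <- filter_outliers(x)
    q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
    expect_equal(res$rule$q1, q1)
    expect_equal(res$rule$q3, q3)
    lo <- q1 - 1.5 * (q3 - q1); hi <- q3 + 1.5 * (q3 - q1)
    expect_identical(res$keep, x >= lo & x <= hi)
    # removed values strictly outside, retained inside or on fences
    expect_true(all(x[!res$keep] < lo | x[!res$keep] > hi))
    expect_true(all(x[res$keep] >= lo & x[res$keep] <= hi))
  }
})

test_that("outlier removal is grouped per gene and time bin, single pass", {
  db <- tiny_db()
  db$comparisons <- bin_comparisons(db$comparisons)
  # build a group of 5 DDIS comparisons in one bin with one gross outlier
  cm <- db$comparisons[rep(1, 5), ]
  cm$comparison_id <- paste0("A-c", 1:5)
  db$comparisons <- cm
  db$genestats <- data.frame(
    comparison_id = cm$comparison_id, gene = "CDKN1A",
    logFC = c(1, 2, 3, 4, 100), p = 0.01)
  kept <- remove_outliers(db$genestats, db$comparisons)
  expect_equal(sort(kept$logFC), c(1, 2, 3, 4))
  expect_true(all(c("time_bin", "inducer", "intervention") %in%
                    names(kept)))
})

test_that("median significance applies the threshold at 1/alpha", {
  gs <- data.frame(
    comparison_id = paste0("c", 1:8),
    gene = "G1",
    inducer = rep("DDIS", 8),
    logFC = c(1, 1, -1, 1, 1, 1, 1, -1),
    p = c(1 / 25, 1 / 30, 1 / 22, 1 / 15, 1 / 18, 1 / 19, 1 / 40,
          1 / 40))
  # {25, 30, -22}: median 25 -> up at alpha 0.05
  calls <- median_significance(gs[1:3, ], alpha = 0.05)
  expect_equal(calls$call, "up")
  expect_equal(calls$median_pi, 25)
  # {15, 18, 19}: ns at 0.05, up at 0.1
  expect_equal(median_significance(gs[4:6, ], alpha = 0.05)$call, "ns")
  expect_equal(median_significance(gs[4:6, ], alpha = 0.1)$call, "up")
  # symmetric cancellation: {40, -40} -> median 0 -> ns
  expect_equal(median_significance(gs[7:8, ], alpha = 0.05)$call, "ns")
})

test_that("venn partition is exact set algebra with direction annotation", {
  mkcalls <- function(sets, dir = "up") {
    do.call(rbind, lapply(names(sets), function(ind) {
      if (!length(sets[[ind]]))
        return(data.frame(gene = "ZZZ", inducer = ind, median_pi = 0,
                          n = 1L, call = "ns"))
      data.frame(gene = sets[[ind]], inducer = ind, median_pi = 100,
                 n = 3L, call = dir)
    }))
  }
  calls <- mkcalls(list(DDIS = c("G1", "G2"), OIS = "G1",
                        REP = c("G1", "G2"), BYS = "G1"))
  part <- venn_partition(calls)
  expect_equal(part$cells[["DDIS+OIS+REP+BYS"]], "G1")
  expect_equal(part$cells[["DDIS+REP"]], "G2")
  expect_equal(part$core$direction, "up")
  empty <- venn_partition(mkcalls(list(DDIS = character(0),
                                       OIS = character(0),
                                       REP = character(0),
                                       BYS = character(0))))
  expect_length(empty$cells, 0)
  expect_error(venn_partition(calls[calls$inducer != "BYS", ]),
               "missing inducer")
  # property: cells disjoint and exhaustive over random call sets
  set.seed(3)
  genes <- sprintf("G%02d", 1:30)
  for (i in 1:20) {
    sets <- lapply(setNames(nm = c("DDIS", "OIS", "REP", "BYS")),
                   function(x) sample(genes, sample(0:20, 1)))
    part <- venn_partition(mkcalls(sets))
    all_assigned <- unlist(part$cells)
    expect_false(any(duplicated(all_assigned)))
    expect_setequal(all_assigned, unique(unlist(sets)))
  }
})

test_that("mixed-direction four-way genes are annotated inducer-dependent", {
  calls <- rbind(
    data.frame(gene = "G1", inducer = c("DDIS", "OIS", "REP"),
               median_pi = 50, n = 3L, call = "up"),
    data.frame(gene = "G1", inducer = "BYS", median_pi = -50, n = 3L,
               call = "down"))
  part <- venn_partition(calls)
  expect_equal(part$core$direction, "inducer_dependent")
})

test_that("core-signature recovery meets its planted-signal targets", {
  # averaged over a handful of seeds here; the full 20-seed study runs in
  # the acceptance suite
  res <- sapply(1:5, function(s) {
    db <- generate_database(generator_config(seed = s))
    clean <- remove_outliers(db$genestats, db$comparisons)
    part <- venn_partition(median_significance(clean))
    unlist(score_recovery(part, db$truth))
  })
  expect_gte(mean(res["sensitivity", ]), 0.9)
  expect_lte(mean(res["null_fpr", ]), 0.05)
})
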