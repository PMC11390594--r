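test_that("database round-trips through CSV field for field", {
  db <- tiny_db()
  dir <- withr::local_tempdir()
  save_database(db, dir)
  db2 <- load_database(file.path(dir, "studies.csv"),
                       file.path(dir, "comparisons.csv"),
                       file.path(dir, "genestats.csv"), quiet = TRUE)
  expect_equal(db2$studies, db$studies)
  expect_equal(db2$comparisons, db$comparisons)
  expect_equal(db2$genestats, db$genestats)
})

test_that("validation names the offending row", {
  db <- tiny_db()
  db$genestats$p[2] <- 0
  expect_error(validate_database(db), "CDKN2A.*A-c1")
  db <- tiny_db()
  db$comparisons$study_accession[3] <- "GSE-MISSING"
  expect_error(validate_database(db), "B-c2.*GSE-MISSING")
  db <- tiny_db()
  db$studies$inducers[1] <- "NOT_A_TYPE"
  expect_error(validate_database(db), "unknown inducer")
})

test_that("empty gene-stat table with valid header loads cleanly", {
  db <- tiny_db()
  db$genestats <- db$genestats[0, ]
  dir <- withr::local_tempdir()
  save_database(db, dir)
  db2 <- load_database(file.path(dir, "studies.csv"),
                       file.path(dir, "comparisons.csv"),
                       file.path(dir, "genestats.csv"), quiet = TRUE)
  expect_equal(nrow(db2$genestats), 0)
})

test_that("the packaged study fixture matches the published inventory", {
  st <- load_study_fixture()
  expect_equal(nrow(st), 119)
  expect_false(anyDuplicated(st$accession) > 0)
  vocab_seen <- unique(unlist(strsplit(st$inducers, ";")))
  expect_setequal(setdiff(vocab_seen, ""), INDUCER_VOCAB)
  expect_length(INDUCER_VOCAB, 14)
  # every timepoint token parses as value:unit with nonnegative value
  toks <- unlist(strsplit(st$timepoints, ";"))
  parts <- strsplit(toks, ":")
  expect_true(all(vapply(parts, length, 0L) == 2))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  units <- vapply(parts, `[`, "", 2)
  expect_true(all(units %in% TIME_UNIT_VOCAB))
  expect_true(all(is.na(vals) | vals >= 0))
  expect_true(all(is.na(vals) == (units == "unknown")))
})

test_that("time-bin assignment follows the published scheme", {
  expect_equal(assign_time_bin("DDIS", 6, "days"), "D5_7")
  expect_equal(assign_time_bin("OIS", 15, "days"), "D15plus")
  expect_equal(assign_time_bin("REP", 88, "PD"), "REP0_40")
  expect_equal(assign_time_bin("REP", 56, "days"), "REP41plus")
  expect_equal(assign_time_bin("REP", NA, "unknown"), "REP0_40")
  expect_equal(assign_time_bin("OIS", NA, "unknown"), "UNBINNED")
  expect_error(assign_time_bin("DDIS", -1, "days"), "negative")
  # totality and disjointness over the grid of knowable inputs
  days <- c(0, 0.5, 2, 4, 4.9, 5, 7, 8, 11, 12, 14, 15, 28, 112)
  for (ind in c("DDIS", "OIS", "BYS", "REP")) {
    bins <- assign_time_bin(ind, days, "days")
    expect_true(all(bins %in% TIME_BINS))
    expect_false(any(bins == "UNBINNED"))
  }
})

test_that("prisma ledger reproduces the published screening arithmetic", {
  led <- prisma_ledger(5063, 32, 26, 82, 37)
  expect_equal(led$screened, 5069)
  expect_equal(led$total_included, 119)
  expect_equal(prisma_ledger(0, 0, 0, 0, 0)$screened, 0)
  expect_error(prisma_ledger(1, 0, 5, 0, 0), "duplicates")
  expect_error(prisma_ledger(-1, 0, 0, 0, 0), "nonnegative")
  # conservation identities over random counts
  set.seed(42)
  for (i in 1:25) {
    g <- sample(0:5000, 1); a <- sample(0:100, 1)
    d <- sample(0:(g + a), 1)
    i1 <- sample(0:200, 1); u <- sample(0:50, 1)
    led <- prisma_ledger(g, a, d, i1, u)
    expect_equal(led$screened, g + a - d)
    expect_equal(led$total_included, i1 + u)
  }
})

test_that("comparison filtering is declarative, stable and validated", {
  db <- generate_database(generator_config(seed = 7, n_null = 10))
  cm <- db$comparisons
  expect_identical(filter_comparisons(cm, list()), cm)
  sub <- filter_comparisons(cm, list(inducer = "DDIS",
                                     intervention = "none"))
  expect_true(all(sub$inducer == "DDIS" & sub$intervention == "none"))
  expect_identical(sub$comparison_id,
                   cm$comparison_id[cm$inducer == "DDIS" &
                                      cm$intervention == "none"])
  p53 <- filter_comparisons(cm, list(intervention = "p53_inhibition",
                                     exclude_inducer = "REP",
                                     max_day = 27))
  expect_true(all(p53$intervention == "p53_inhibition"))
  expect_false(any(p53$inducer == "REP"))
  expect_true(all(p53$time_value <= 27 & p53$time_unit == "days"))
  expect_error(filter_comparisons(cm, list(nonsense = 1)),
               "unknown filter criterion")
})
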