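#!/usr/bin/env Rscript

# Stage 1: study inventory, screening ledger, and a seeded synthetic
# comparison database with planted effects.
#
#   Rscript analysis/01_build_database.R [seed]

suppressPackageStartupMessages(library(senotemp))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# screening arithmetic of the underlying systematic review
led <- prisma_ledger(identified_geo = 5063, identified_ae = 32,
                     duplicates_removed = 26, included_initial = 82,
                     update_additions = 37)
print(led)
write.csv(data.frame(stage = c("identified_geo", "identified_ae",
                               "duplicates_removed", "screened",
                               "included_initial", "update_additions",
                               "total_included"),
                     count = c(5063, 32, 26, led$screened, 82, 37,
                               led$total_included)),
          file.path(out, "prisma_ledger.csv"), row.names = FALSE)

# the packaged transcription of the printed study inventory
fixture <- load_study_fixture()
message(sprintf("study inventory: %d studies, %d inducer categories",
                nrow(fixture), length(INDUCER_VOCAB)))
write.csv(fixture, file.path(out, "study_inventory.csv"),
          row.names = FALSE)

# synthetic database with planted core/specific/null structure
cfg <- generator_config(seed = seed)
db <- generate_database(cfg)
save_database(db, out)
write.csv(db$truth$classes, file.path(out, "truth_classes.csv"),
          row.names = FALSE)
message(sprintf("synthetic database (seed %d): %d studies, %d comparisons, %d gene rows",
                seed, nrow(db$studies), nrow(db$comparisons),
                nrow(db$genestats)))
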