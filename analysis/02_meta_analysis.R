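#!/usr/bin/env Rscript

# Stage 2: temporal meta-analysis of the database written by stage 1 —
# outlier removal, median significance calls, four-inducer core
# signature, recovery scoring, inhibition contrasts and an enrichment
# check of the recovered core set.
#
#   Rscript analysis/02_meta_analysis.R [seed]

suppressPackageStartupMessages(library(senotemp))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"
db <- load_database(file.path(out, "studies.csv"),
                    file.path(out, "comparisons.csv"),
                    file.path(out, "genestats.csv"), quiet = TRUE)
truth_classes <- read.csv(file.path(out, "truth_classes.csv"))

clean <- remove_outliers(db$genestats, db$comparisons)
message(sprintf("outlier removal: %d of %d rows retained",
                nrow(clean), nrow(db$genestats)))

calls <- median_significance(clean, alpha = 0.05)
write.csv(calls, file.path(out, "median_calls.csv"), row.names = FALSE)

part <- venn_partition(calls)
write.csv(part$core, file.path(out, "core_signature.csv"),
          row.names = FALSE)
cell_sizes <- data.frame(cell = names(part$cells),
                         n_genes = lengths(part$cells))
write.csv(cell_sizes, file.path(out, "venn_cells.csv"),
          row.names = FALSE)
message(sprintf("core signature: %d genes shared by all four inducers",
                nrow(part$core)))

panel <- list(core = unique(grep("^CORE", truth_classes$gene,
                                 value = TRUE)),
              null = unique(grep("^NULL", truth_classes$gene,
                                 value = TRUE)))
rec <- score_recovery(part, list(panel = panel))
message(sprintf("recovery vs planted truth: sensitivity %.3f, null FPR %.3f",
                rec$sensitivity, rec$null_fpr))

# inhibition contrasts on the planted marker genes
contrasts <- rbind(
  do.call(rbind, lapply(c("CDKN1A", "MDM2"), function(g) {
    ct <- inhibition_contrast(db, "p53_inhibition", "DDIS", g)
    data.frame(intervention = ct$intervention, gene = g,
               median_inhibited = ct$inhibited$median_logfc,
               median_control = ct$control$median_logfc,
               p = ct$test$p, stars = ct$stars)
  })),
  do.call(rbind, lapply(c("IL6", "CXCL8", "IL1B"), function(g) {
    ct <- inhibition_contrast(db, "RelA_inhibition", "DDIS", g)
    data.frame(intervention = ct$intervention, gene = g,
               median_inhibited = ct$inhibited$median_logfc,
               median_control = ct$control$median_logfc,
               p = ct$test$p, stars = ct$stars)
  })))
write.csv(contrasts, file.path(out, "inhibition_contrasts.csv"),
          row.names = FALSE)
print(contrasts)

# enrichment of the planted core set in the median inverted-p ranking
ddis <- calls[calls$inducer == "DDIS", ]
scores <- setNames(ddis$median_pi, ddis$gene)
core_set <- truth_classes$gene[truth_classes$class == "up" &
                                 truth_classes$inducer == "DDIS" &
                                 grepl("^CORE", truth_classes$gene)]
enr <- preranked_enrichment(scores, unique(core_set), n_perm = 1000,
                            seed = seed)
print(enr)
write.csv(data.frame(es = enr$es, nes = enr$nes, perm_p = enr$perm_p,
                     size = enr$size),
          file.path(out, "core_enrichment.csv"), row.names = FALSE)
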