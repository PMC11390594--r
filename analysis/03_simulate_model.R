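#!/usr/bin/env Rscript

# Stage 3: simulate the six-trajectory model bundle (DDIS and OIS, each
# without knockdown and with p53 / RelA knockdowns) and evaluate the
# twelve phenotype criteria.
#
#   Rscript analysis/03_simulate_model.R

suppressPackageStartupMessages(library(senotemp))

out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bundle <- simulate_bundle()
for (nm in names(bundle))
  write_trajectory(bundle[[nm]],
                   file.path(out, sprintf("trajectory_%s.csv", nm)))

crit <- evaluate_criteria(bundle)
print(crit)
write.csv(as.data.frame(crit), file.path(out, "criteria.csv"),
          row.names = FALSE)

# headline dynamical readouts
D <- bundle$DDIS.none
O <- bundle$OIS.none
readouts <- data.frame(
  quantity = c("NICD_drop_DDIS", "NICD_drop_OIS",
               "pp53_mean_DDIS_over_OIS", "p16_mean_OIS_over_DDIS",
               "IL6_mean_OIS_over_DDIS"),
  value = c(traj_at(D, "NICD", 70) / traj_at(D, "NICD", 60),
            traj_at(O, "NICD", 70) / traj_at(O, "NICD", 60),
            traj_mean(D, "pp53", c(40, 100)) /
              traj_mean(O, "pp53", c(40, 100)),
            traj_mean(O, "p16", c(40, 100)) /
              traj_mean(D, "p16", c(40, 100)),
            traj_mean(O, "IL6", c(65, 100)) /
              traj_mean(D, "IL6", c(65, 100))))
write.csv(readouts, file.path(out, "model_readouts.csv"),
          row.names = FALSE)
print(readouts)
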