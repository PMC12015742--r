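#!/usr/bin/env Rscript
# Stage 4 -- validation report. Reads the stage-3 tables and scores them
# against the synthetic ground truth: niche-optimum recovery (MIV vs true
# optimum), the MIV-EIV Spearman correlations per group, and the TPR summary
# by species group.

.af <- grep("--file=", commandArgs(), value = TRUE)
source(file.path(if (length(.af)) dirname(sub("--file=", "", .af[1])) else
  "analysis", "00_config.R"))

miv <- read.csv(file.path(RESULTS_DIR, "miv.csv"))
truth <- read.csv(file.path(RESULTS_DIR, "true_optima.csv"))
tpr <- read.csv(file.path(RESULTS_DIR, "tpr.csv"))
niche <- read.csv(file.path(RESULTS_DIR, "niche_correlations.csv"))
importance <- read.csv(file.path(RESULTS_DIR, "importance.csv"))

# niche-optimum recovery for the true driver variables
rec <- merge(miv, truth[, c("species_id", "group", "variable", "optimum")],
             by = c("species_id", "variable"))
rec$abs_error <- abs(rec$miv - rec$optimum)
write.csv(rec, file.path(RESULTS_DIR, "miv_recovery.csv"), row.names = FALSE)

cat("Niche-optimum recovery (driver variables):\n")
for (v in unique(rec$variable)) {
  sub <- rec[rec$variable == v, ]
  rho <- spearman_test(sub$miv, sub$optimum)
  cat(sprintf("  %s: n=%d, median |MIV - optimum| = %.3f, Spearman rho = %.2f (p = %.2g)\n",
              v, rho$n, median(sub$abs_error), rho$rho, rho$p))
}

cat("\nMIV-EIV correlations by group (importance cutoff applied):\n")
print(niche, digits = 2, row.names = FALSE)

cat("\nTPR against independent occurrences, by group:\n")
for (g in unique(tpr$group)) {
  t <- tpr$tpr[tpr$group == g & !is.na(tpr$tpr)]
  cat(sprintf("  %s: n=%d, median TPR %.2f, TPR > 0.5 for %.0f%%\n",
              g, length(t), median(t), 100 * mean(t > 0.5)))
}

top <- do.call(rbind, lapply(split(importance, importance$species_id),
                             function(d) d[which.max(d$importance), ]))
cat("\nMost important variable per species (count):\n")
print(table(top$variable))
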