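#!/usr/bin/env Rscript
# Stage 2 -- synthetic species, vegetation plots, occurrence records, EIVs.
# Builds the Gaussian-niche species truths over the landscape covariates,
# samples 12,000 plots (with 5% of plots carrying each filterable defect),
# draws GBIF-like occurrence records, generates noisy ordinal indicator
# values, applies the plot filter, and writes all tables as CSV.

.af <- grep("--file=", commandArgs(), value = TRUE)
source(file.path(if (length(.af)) dirname(sub("--file=", "", .af[1])) else
  "analysis", "00_config.R"))

cfg <- analysis_config()
landscape <- gen_landscape(cfg$landscape)
stack <- build_covariate_stack(landscape)
truths <- gen_species(cfg$species, stack)

plots <- gen_plots(cfg$n_plots, landscape, truths, cfg$attribute_noise,
                   child_seed(cfg$seed, 200))
fp <- filter_plots(plots, cfg$filter, stack)
write.csv(plots, file.path(RESULTS_DIR, "plots_raw.csv"), row.names = FALSE)
write.csv(fp$plots, file.path(RESULTS_DIR, "plots_filtered.csv"),
          row.names = FALSE)

occ <- gen_occurrences(truths, cfg$n_occurrences, cfg$occurrence_noise,
                       child_seed(cfg$seed, 300))
write.csv(occ, file.path(RESULTS_DIR, "occurrences_raw.csv"),
          row.names = FALSE)

eivs <- gen_eivs(cfg$species, cfg$eiv$scale, cfg$eiv$sign, cfg$eiv$noise_sd,
                 child_seed(cfg$seed, 500))
write.csv(eivs, file.path(RESULTS_DIR, "eivs.csv"), row.names = FALSE)

truth_optima <- do.call(rbind, lapply(cfg$species, function(s) {
  data.frame(species_id = s$species_id, group = s$group,
             variable = names(s$optima), optimum = unname(s$optima),
             breadth = unname(s$breadths), p_max = s$p_max)
}))
write.csv(truth_optima, file.path(RESULTS_DIR, "true_optima.csv"),
          row.names = FALSE)

cat(sprintf("Generated %d species over %d plots; filter rejected %d plots\n",
            length(truths), cfg$n_plots, cfg$n_plots - nrow(fp$plots)))
cat("  per rule:", paste(names(fp$rejections), fp$rejections, sep = "=",
                         collapse = ", "), "\n")
cat(sprintf("%d raw occurrence records; EIVs on a %d-%d scale for %d species\n",
            nrow(occ), cfg$eiv$scale[1], cfg$eiv$scale[2],
            length(unique(eivs$species_id))))
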