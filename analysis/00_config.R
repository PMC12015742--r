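# Shared configuration for the analysis scripts. Each numbered script is a
# thin driver over the wetsdm package: it regenerates what it needs
# deterministically from this configuration, does one stage of the workflow,
# and writes its tables under results/.

library(wetsdm)

ANALYSIS_SEED <- 20260924
RESULTS_DIR <- "results"

analysis_config <- function() {
  cfg <- default_config(seed = ANALYSIS_SEED)
  cfg$out_dir <- RESULTS_DIR
  cfg
}

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
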