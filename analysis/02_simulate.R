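#!/usr/bin/env Rscript
# Generate the demo dataset: 13 blastocysts x {ICM, TE} biopsy libraries with
# the study's sex mix (6 XY, 6 XX, L1 XO), four planted whole-chromosome
# events, and 120 planted H-vs-L differentially expressed genes.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

unlink(SIM_DIR, recursive = TRUE)
data <- ensure_demo_dataset()
message(sprintf(
  "%d genes x %d samples; %d planted DE genes; %d sample-level ploidy events",
  nrow(data$counts), ncol(data$counts), sum(data$truth_de$is_de),
  sum(data$truth_copy$state != "euploid")))
print(data$counts)
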