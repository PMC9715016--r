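#!/usr/bin/env Rscript
# RNA-based digital karyotyping of the demo dataset: Y-marker presence,
# X-dosage Z-scores, autosomal gain/loss calls at |z| > 2, and the
# per-blastocyst karyotype grid — compared against the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
cfg <- pipeline_config()
data <- ensure_demo_dataset()

k <- digital_karyotype(data$counts, data$tpm, data$annotation,
                       data$metadata, cfg)
write_tsv(k$calls, file.path(RESULTS_DIR, "karyotype", "calls.tsv"))
write_tsv(k$sex, file.path(RESULTS_DIR, "karyotype", "sex_calls.tsv"))
write_tsv(k$report, file.path(RESULTS_DIR, "karyotype", "report.tsv"))

truth_sex <- setNames(data$truth_sex$sex, data$truth_sex$blastocyst_id)
called <- setNames(k$sex$sex, k$sex$blastocyst_id)
agree <- sum((truth_sex == called[names(truth_sex)]) |
               (truth_sex == "XO" & called[names(truth_sex)] == "potential_XO"))
message(sprintf("sex calls matching truth: %d / %d", agree, length(truth_sex)))

planted <- data$truth_copy[data$truth_copy$state != "euploid", ]
key <- paste(k$calls$sample_id, k$calls$chromosome)
got <- k$calls$call[match(paste(planted$sample_id, planted$chromosome), key)]
message(sprintf("planted events recovered: %d / %d",
                sum(got == planted$state), nrow(planted)))
extra <- k$calls[k$calls$call != "euploid" &
                   !(key %in% paste(planted$sample_id, planted$chromosome)), ]
message(sprintf("calls outside the planted truth: %d (|z|>2 tail, %d tests)",
                nrow(extra), nrow(k$calls)))
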