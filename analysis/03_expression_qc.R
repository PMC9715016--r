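#!/usr/bin/env Rscript
# Expression QC of the demo biopsy libraries: expressed-gene counts per
# compartment, reference-set transcriptome coverage, and PCA of log2(TPM+1)
# (which should separate ICM from TE biopsies when lineage signal is present,
# and here mainly reflects embryo-level variation).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
cfg <- pipeline_config()
data <- ensure_demo_dataset()

qc <- qc_report(data$tpm, data$metadata, cfg)
write_tsv(qc, file.path(RESULTS_DIR, "qc", "qc_report.tsv"))
message(sprintf("coverage range: %.3f - %.3f",
                min(qc$coverage), max(qc$coverage)))

for (scope in c("ICM", "TE", "all")) {
  es <- expressed_gene_set(data$tpm, data$metadata,
                           min_tpm = cfg$expressed_min_tpm,
                           min_samples = cfg$expressed_min_samples,
                           scope = scope)
  message(sprintf("expressed genes (%s, TPM > %g in >= %d sample): %d",
                  scope, es$min_tpm, es$min_samples, length(es$genes)))
}

pca <- run_pca(data$tpm, n_components = 4L)
write_tsv(data.frame(sample_id = rownames(pca$coords),
                     compartment = data$metadata$compartment[
                       match(rownames(pca$coords), data$metadata$sample_id)],
                     round(pca$coords, 4)),
          file.path(RESULTS_DIR, "qc", "pca_coords.tsv"))
message("explained variance fractions: ",
        paste(sprintf("%.3f", pca$explained), collapse = ", "))
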