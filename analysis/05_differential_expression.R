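#!/usr/bin/env Rscript
# Differential expression on the demo dataset: NB Wald tests per compartment
# for the expectation-of-pregnancy comparison (H vs L), the Z-score
# reliability filter, direction splits, and the intersection with the
# Gardner-score regrouping.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
cfg <- pipeline_config()
data <- ensure_demo_dataset()

md <- data$metadata
# the demo metadata lacks ages/scores; borrow the study's Table-1 values so
# the age and Gardner regroupings are exercised
b <- table1_blastocysts()
idx <- match(md$blastocyst_id, b$blastocyst_id)
md$maternal_age <- b$maternal_age[idx]
md$gardner_score <- b$gardner_score[idx]
md <- sample_metadata(md)

de_results <- list()
for (comp in c("ICM", "TE")) {
  expr_set <- expressed_gene_set(data$tpm, md,
                                 min_tpm = cfg$expressed_min_tpm,
                                 min_samples = cfg$expressed_min_samples,
                                 scope = comp)
  for (scheme in c("expectation", "gardner", "age")) {
    sch <- grouping_scheme(md, scheme, comp, cfg)
    de <- nb_wald_test(data$counts, sch, cfg, genes = expr_set$genes)
    de <- reliability_filter(data$tpm, de, sch, cfg)
    de_results[[paste(scheme, comp, sep = "_")]] <- de
    split <- direction_split(de)
    message(sprintf(
      "%-12s %s: %4d DEGs (q < %.2g; %d up / %d down in %s), %d reliable",
      scheme, comp, sum(de$is_deg, na.rm = TRUE), cfg$deg_q_cutoff,
      length(split$up), length(split$down), sch$treatment,
      sum(de$reliable, na.rm = TRUE)))
    write_tsv(de[de$is_deg & !is.na(de$is_deg), ],
              file.path(RESULTS_DIR, "de",
                        sprintf("degs_%s_%s.tsv", scheme, comp)))
  }
}

# recovery of the planted truth (expectation scheme)
truth <- data$truth_de
for (comp in c("ICM", "TE")) {
  de <- de_results[[paste0("expectation_", comp)]]
  m <- merge(de, truth, by = "gene_id")
  tp <- sum(m$is_deg & m$is_de, na.rm = TRUE)
  fp <- sum(m$is_deg & !m$is_de, na.rm = TRUE)
  message(sprintf("%s: %d/%d planted DE genes recovered at q<%.2g, %d false",
                  comp, tp, sum(truth$is_de), cfg$deg_q_cutoff, fp))
}

# cross-grouping intersections per compartment
for (comp in c("ICM", "TE")) {
  common <- intersect_deg_sets(de_results[[paste0("expectation_", comp)]],
                               de_results[[paste0("gardner_", comp)]],
                               match_direction = TRUE)
  message(sprintf("%s: %d genes DEG in both expectation and Gardner groupings",
                  comp, nrow(common)))
  write_tsv(common, file.path(RESULTS_DIR, "de",
                              sprintf("common_expectation_gardner_%s.tsv", comp)))
}
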