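# Shared setup for the analysis drivers: the demo dataset emulating the
# 13-blastocyst study (default sex mix with the suspected XO, a handful of
# planted whole-chromosome events, and planted H-vs-L expression differences)
# is generated once under results/simulated/ and reused by later scripts.

library(blastomics)

RESULTS_DIR <- "results"
SIM_DIR <- file.path(RESULTS_DIR, "simulated")
DEMO_SEED <- 20220101L

demo_design <- function() {
  sim_design(
    genes_per_chromosome = 400L,
    ploidy_events = data.frame(
      blastocyst_id = c("H2", "H4", "L1", "M2"),
      compartment = c("both", "ICM", "both", "TE"),
      chromosome = c("16", "13", "6", "22"),
      event = c("gain", "loss", "gain", "loss")),
    de_config = list(n_genes = 120L, log2fc = 3, prop_up = 0.3),
    seed = DEMO_SEED
  )
}

ensure_demo_dataset <- function() {
  if (!file.exists(file.path(SIM_DIR, "counts.tsv"))) {
    message("simulating demo dataset under ", SIM_DIR)
    d <- demo_design()
    ann <- make_annotation(d)
    sim <- simulate_counts(d, ann)
    write_simulation(sim, ann, SIM_DIR)
  }
  ann <- read_annotation(file.path(SIM_DIR, "annotation.tsv"))
  md <- read_metadata(file.path(SIM_DIR, "metadata.tsv"))
  counts <- read_matrix(file.path(SIM_DIR, "counts.tsv"),
                        annotation = ann, metadata = md)
  list(annotation = ann, metadata = md, counts = counts,
       tpm = tpm_from_counts(counts, ann),
       truth_copy = utils::read.delim(file.path(SIM_DIR, "truth_copy_state.tsv"),
                                      colClasses = c(chromosome = "character")),
       truth_de = utils::read.delim(file.path(SIM_DIR, "truth_de.tsv")),
       truth_sex = utils::read.delim(file.path(SIM_DIR, "truth_sex.tsv")))
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
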