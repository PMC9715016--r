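#' Run the full blastocyst analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> digital karyotype -> differential
#' expression -> clinical classification, writing every stage's tables under
#' `out_dir` and a run manifest (config snapshot, seed, input digests, stage
#' outputs, package version, timestamp) last. Re-running with the same
#' manifest inputs reproduces identical outputs; all randomness flows from
#' `seed`.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the simulation stages.
#' @param inputs Either NULL (simulate a dataset with `design`) or a list
#'   with paths `counts`, `annotation`, `metadata` (TSV as written by the
#'   package) and optionally `cohort`.
#' @param design A [sim_design()] used when `inputs` is NULL; its seed is
#'   overridden by `seed`.
#' @param cohort_n,cohort_fractions,cohort_rates Clinical-cohort simulation
#'   parameters used when no cohort file is supplied; defaults are the
#'   published cohort's size, group mix and pregnancy rates.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L,
                         inputs = NULL, design = NULL,
                         cohort_n = 1890L,
                         cohort_fractions = c(676, 158, 1056) / 1890,
                         cohort_rates = c(0.590, 0.165, 0.342)) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, paste0(name, ".failed")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    tool = "blastomics",
    version = as.character(utils::packageVersion("blastomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    config = unclass(config),
    inputs = list(),
    outputs = list()
  )

  # --- inputs: simulate or load -------------------------------------------
  if (is.null(inputs)) {
    if (is.null(design)) design <- sim_design(seed = seed)
    design$seed <- as.integer(seed)
    annotation <- stage("simulate", make_annotation(design))
    sim <- stage("simulate", simulate_counts(design, annotation))
    counts <- sim$counts
    metadata <- sim$metadata
    sim_dir <- file.path(out_dir, "simulated")
    write_simulation(sim, annotation, sim_dir)
    manifest$inputs$simulated <- sim_dir
  } else {
    annotation <- stage("load", read_annotation(inputs$annotation))
    metadata <- stage("load", read_metadata(inputs$metadata))
    counts <- stage("load", read_matrix(inputs$counts, unit = "counts",
                                        annotation = annotation,
                                        metadata = metadata))
    digests <- tools::md5sum(unlist(inputs[c("counts", "annotation", "metadata")]))
    manifest$inputs$digests <- as.list(digests)
  }
  tpm <- stage("tpm", tpm_from_counts(counts, annotation))

  # --- qc ------------------------------------------------------------------
  qc <- stage("qc", qc_report(tpm, metadata, config))
  qc_path <- file.path(out_dir, "qc_report.tsv")
  utils::write.table(qc, qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pca <- stage("qc", run_pca(tpm, n_components = 2L))
  pca_path <- file.path(out_dir, "pca_coords.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(pca$coords), pca$coords,
               stringsAsFactors = FALSE),
    pca_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$outputs$qc <- qc_path
  manifest$outputs$pca <- pca_path

  # --- digital karyotype ---------------------------------------------------
  karyo <- stage("karyotype",
                 digital_karyotype(counts, tpm, annotation, metadata, config))
  karyo_path <- file.path(out_dir, "karyotype_calls.tsv")
  utils::write.table(karyo$calls, karyo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report_path <- file.path(out_dir, "karyotype_report.tsv")
  utils::write.table(karyo$report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$outputs$karyotype <- karyo_path
  manifest$outputs$karyotype_report <- report_path

  # --- differential expression (expectation scheme, both compartments) -----
  de_paths <- list()
  for (comp in c("ICM", "TE")) {
    de_res <- stage("de", {
      sch <- grouping_scheme(metadata, "expectation", comp, config)
      expr_set <- expressed_gene_set(tpm, metadata,
                                     min_tpm = config$expressed_min_tpm,
                                     min_samples = config$expressed_min_samples,
                                     scope = comp)
      de <- nb_wald_test(counts, sch, config, genes = expr_set$genes)
      reliability_filter(tpm, de, sch, config)
    })
    p <- file.path(out_dir, paste0("de_expectation_", comp, ".tsv"))
    utils::write.table(de_res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    de_paths[[comp]] <- p
  }
  manifest$outputs$de <- de_paths

  # --- clinical classification ---------------------------------------------
  cohort <- if (!is.null(inputs$cohort)) {
    stage("classify", utils::read.delim(inputs$cohort, sep = "\t",
                                        stringsAsFactors = FALSE))
  } else {
    stage("classify", simulate_cohort(cohort_n, cohort_fractions,
                                      cohort_rates, seed = seed,
                                      config = config))
  }
  cont <- stage("classify", contingency_analysis(cohort, config))
  clin_path <- file.path(out_dir, "clinical_contingency.tsv")
  clin <- data.frame(group = rownames(cont$table), cont$table,
                     rate = cont$rates, stringsAsFactors = FALSE)
  utils::write.table(clin, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin_tests_path <- file.path(out_dir, "clinical_tests.json")
  jsonlite::write_json(
    list(overall_chi2 = cont$overall_chi2, overall_p = cont$overall_p,
         pairwise = cont$pairwise),
    clin_tests_path, auto_unbox = TRUE, digits = NA)
  manifest$outputs$clinical <- clin_path
  manifest$outputs$clinical_tests <- clin_tests_path

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `out_dir` back in and returns figure-analog
#' tables: the blastocyst-by-chromosome karyotype grid, DEG counts per
#' compartment, and the clinical pregnancy-rate table. Missing stages give a
#' partial summary with a warning.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return List `karyotype_grid`, `deg_counts`, `clinical`, `qc`.
#' @export
summarize_run <- function(out_dir) {
  out <- list()
  read_tsv <- function(p) utils::read.delim(p, sep = "\t",
                                            stringsAsFactors = FALSE,
                                            check.names = FALSE)
  p <- file.path(out_dir, "karyotype_calls.tsv")
  if (file.exists(p)) {
    calls <- read_tsv(p)
    grid <- stats::xtabs(~ sample_id + chromosome,
                         data = calls[calls$call != "euploid", , drop = FALSE])
    out$karyotype_grid <- stats::reshape(
      calls[, c("sample_id", "chromosome", "call")],
      idvar = "sample_id", timevar = "chromosome", direction = "wide")
    names(out$karyotype_grid) <- sub("^call\\.", "chr", names(out$karyotype_grid))
  } else {
    warning("karyotype stage output missing")
  }
  degs <- list()
  for (comp in c("ICM", "TE")) {
    p <- file.path(out_dir, paste0("de_expectation_", comp, ".tsv"))
    if (file.exists(p)) {
      de <- read_tsv(p)
      degs[[comp]] <- data.frame(
        compartment = comp,
        n_deg = sum(de$is_deg, na.rm = TRUE),
        n_reliable = sum(de$reliable, na.rm = TRUE),
        n_up = sum(de$is_deg & de$log2fc > 0, na.rm = TRUE),
        n_down = sum(de$is_deg & de$log2fc < 0, na.rm = TRUE))
    } else {
      warning("DE stage output missing for ", comp)
    }
  }
  if (length(degs) > 0) out$deg_counts <- do.call(rbind, degs)
  p <- file.path(out_dir, "clinical_contingency.tsv")
  if (file.exists(p)) out$clinical <- read_tsv(p) else
    warning("clinical stage output missing")
  p <- file.path(out_dir, "qc_report.tsv")
  if (file.exists(p)) out$qc <- read_tsv(p)
  out
}
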