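#' Pipeline configuration
#'
#' Central container for every numeric threshold the pipeline uses. Defaults
#' are the operating values of the published analysis this package
#' reimplements for synthetic data: the TPM > 1 expressed-gene rule, the
#' 6-or-more-samples reference set, the > 250 summed-TPM Y-presence rule, the
#' +/- 2 autosomal Z-score cutoff, the q < 0.01 DEG call, the < 0.5 Z-score
#' reliability deviation, the 35-year maternal-age split, the 130 h / 140 h and
#' 170 um / 180 um growth-kinetics rules, and the p < 0.001 significance level
#' for the clinical contingency tests.
#'
#' @param expressed_min_tpm TPM threshold (strict `>`) for a gene to count as
#'   expressed in a sample. Default 1.
#' @param expressed_min_samples Minimum number of samples a gene must be
#'   expressed in to enter the expressed set. Default 1.
#' @param reference_min_samples Minimum number of samples for the final
#'   filtered reference set used by transcriptome coverage. Default 6.
#' @param y_tpm_threshold Summed TPM of the three Y-marker genes above which
#'   (strict `>`) the Y chromosome is called present. Default 250.
#' @param autosome_z_cutoff Absolute Z-score beyond which (strict) an autosome
#'   is called a potential gain/loss. Default 2.
#' @param deg_q_cutoff Benjamini-Hochberg q-value below which (strict) a gene
#'   is a DEG. Default 0.01.
#' @param reliability_max_dev Upper bound (strict `<`) on the within-group SD
#'   of per-sample expression Z-scores for a DEG to be called reliable.
#'   Default 0.5.
#' @param age_cutoff_years Maternal age below which (strict) a blastocyst is
#'   "young". Default 35.
#' @param group1_max_hours,group1_min_diameter_um Group 1 rule: fewer than
#'   `group1_max_hours` hours to reach a diameter greater than
#'   `group1_min_diameter_um` um. Defaults 130 h, 170 um.
#' @param group2_min_hours,group2_max_diameter_um Group 2 rule: more than
#'   `group2_min_hours` hours while still under `group2_max_diameter_um` um.
#'   Defaults 140 h, 180 um.
#' @param significance_alpha Significance level for the clinical contingency
#'   tests. Default 0.001.
#' @param xo_flag_z_upper X-dosage Z-score below which (both compartments,
#'   Y absent) a blastocyst is flagged potential XO rather than called XX.
#'   Default 0.5. This threshold is a design choice of this package: the
#'   original analysis only speculated XO from an intermediate X dosage, so
#'   the flag is advisory, never a definitive call.
#'
#' @return A validated list of class `"pipeline_config"`.
#' @seealso [read_config()]
#' @export
pipeline_config <- function(expressed_min_tpm = 1.0,
                            expressed_min_samples = 1L,
                            reference_min_samples = 6L,
                            y_tpm_threshold = 250.0,
                            autosome_z_cutoff = 2.0,
                            deg_q_cutoff = 0.01,
                            reliability_max_dev = 0.5,
                            age_cutoff_years = 35L,
                            group1_max_hours = 130.0,
                            group2_min_hours = 140.0,
                            group1_min_diameter_um = 170.0,
                            group2_max_diameter_um = 180.0,
                            significance_alpha = 0.001,
                            xo_flag_z_upper = 0.5) {
  cfg <- list(
    expressed_min_tpm = as.numeric(expressed_min_tpm),
    expressed_min_samples = as.integer(expressed_min_samples),
    reference_min_samples = as.integer(reference_min_samples),
    y_tpm_threshold = as.numeric(y_tpm_threshold),
    autosome_z_cutoff = as.numeric(autosome_z_cutoff),
    deg_q_cutoff = as.numeric(deg_q_cutoff),
    reliability_max_dev = as.numeric(reliability_max_dev),
    age_cutoff_years = as.integer(age_cutoff_years),
    group1_max_hours = as.numeric(group1_max_hours),
    group2_min_hours = as.numeric(group2_min_hours),
    group1_min_diameter_um = as.numeric(group1_min_diameter_um),
    group2_max_diameter_um = as.numeric(group2_max_diameter_um),
    significance_alpha = as.numeric(significance_alpha),
    xo_flag_z_upper = as.numeric(xo_flag_z_upper)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("config fields must be finite scalars: ",
         paste(names(cfg)[!num], collapse = ", "))
  }
  pos <- vapply(cfg, function(x) x > 0, logical(1))
  if (!all(pos)) {
    stop("config thresholds must be strictly positive: ",
         paste(names(cfg)[!pos], collapse = ", "))
  }
  if (cfg$group1_max_hours >= cfg$group2_min_hours) {
    stop("group1_max_hours must be < group2_min_hours")
  }
  if (cfg$group1_min_diameter_um >= cfg$group2_max_diameter_um) {
    stop("group1_min_diameter_um must be < group2_max_diameter_um")
  }
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys are exactly the [pipeline_config()] field names; keys absent from the
#' file keep their defaults. Unknown keys are an error so that typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Blastocyst pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}
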