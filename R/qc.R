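#' Expressed-gene set
#'
#' A gene is expressed in a sample when its TPM exceeds `min_tpm` (strictly);
#' it enters the expressed set when that holds in at least `min_samples` of
#' the in-scope samples. The defaults (TPM > 1 in >= 1 sample) give the
#' expressed-gene panel; `min_samples = 6` gives the final filtered reference
#' set used for transcriptome coverage.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param metadata A [sample_metadata()]; required when `scope` is not
#'   `"all"`.
#' @param min_tpm Strict TPM threshold (default from `config`).
#' @param min_samples Minimum number of qualifying samples.
#' @param scope `"all"`, `"ICM"` or `"TE"`.
#' @return List of class `"expressed_set"`: `genes` (character), `min_tpm`,
#'   `min_samples`, `scope`, `n_samples`.
#' @export
expressed_gene_set <- function(tpm, metadata = NULL, min_tpm = 1,
                               min_samples = 1L, scope = c("all", "ICM", "TE")) {
  scope <- match.arg(scope)
  if (matrix_unit(tpm) != "TPM") stop("expressed_gene_set needs a TPM matrix")
  cols <- colnames(tpm)
  if (scope != "all") {
    if (is.null(metadata)) stop("metadata required for compartment scope")
    keep <- metadata$sample_id[metadata$compartment == scope]
    cols <- intersect(cols, keep)
  }
  if (length(cols) == 0) stop("no samples in scope '", scope, "'")
  if (min_samples > length(cols)) {
    stop("min_samples (", min_samples, ") exceeds in-scope sample count (",
         length(cols), ")")
  }
  hits <- rowSums(unclass(tpm)[, cols, drop = FALSE] > min_tpm)
  out <- list(genes = rownames(tpm)[hits >= min_samples],
              min_tpm = min_tpm, min_samples = as.integer(min_samples),
              scope = scope, n_samples = length(cols))
  class(out) <- "expressed_set"
  out
}

#' @export
print.expressed_set <- function(x, ...) {
  cat(sprintf("<expressed_set> %d genes (TPM > %g in >= %d of %d %s samples)\n",
              length(x$genes), x$min_tpm, x$min_samples, x$n_samples, x$scope))
  invisible(x)
}

#' Transcriptome coverage of each sample
#'
#' Coverage is the proportion of reference-set genes a sample expresses above
#' the TPM threshold — a library-complexity check that low-expectation
#' biopsies are not simply degraded libraries.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param reference An [expressed_gene_set()] (typically the >= 6-sample
#'   reference set).
#' @param min_tpm Strict TPM threshold for "expressed in this sample".
#' @return Named numeric vector in `[0, 1]`, one entry per sample.
#' @export
coverage <- function(tpm, reference, min_tpm = 1) {
  stopifnot(inherits(reference, "expressed_set"))
  if (length(reference$genes) == 0) stop("reference set is empty")
  genes <- intersect(reference$genes, rownames(tpm))
  if (length(genes) == 0) stop("no reference genes present in matrix")
  colMeans(unclass(tpm)[genes, , drop = FALSE] > min_tpm)
}

#' Principal component analysis of expression profiles
#'
#' PCA on log2(TPM + 1), genes centered and not scaled. The sign of each
#' component is fixed by making its largest-magnitude gene loading positive,
#' so coordinates are deterministic and invariant to gene ordering.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param n_components Number of components to return.
#' @return List: `coords` (samples x components), `explained`
#'   (variance fractions, non-increasing), `loadings` (genes x components).
#' @export
run_pca <- function(tpm, n_components = 2L) {
  if (matrix_unit(tpm) != "TPM") stop("run_pca needs a TPM matrix")
  if (ncol(tpm) < 2) stop("PCA needs at least 2 samples")
  x <- t(log2(unclass(tpm) + 1))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- ncol(pr$x)
  if (n_components > rank) {
    warning("n_components truncated to rank ", rank)
    n_components <- rank
  }
  coords <- pr$x[, seq_len(n_components), drop = FALSE]
  load <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) {
      load[, k] <- -load[, k]
      coords[, k] <- -coords[, k]
    }
  }
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  list(coords = coords, explained = expl[seq_len(n_components)],
       loadings = load)
}

#' Per-sample QC report
#'
#' Expressed-gene counts and reference-set coverage per sample, the standard
#' per-library quality table.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param metadata A [sample_metadata()].
#' @param config A [pipeline_config()].
#' @return Data frame: `sample_id`, `compartment`, `n_expressed`, `coverage`.
#' @export
qc_report <- function(tpm, metadata, config = pipeline_config()) {
  ref <- expressed_gene_set(tpm, metadata,
                            min_tpm = config$expressed_min_tpm,
                            min_samples = config$reference_min_samples,
                            scope = "all")
  cov <- coverage(tpm, ref, min_tpm = config$expressed_min_tpm)
  n_expr <- colSums(unclass(tpm) > config$expressed_min_tpm)
  idx <- match(colnames(tpm), metadata$sample_id)
  data.frame(
    sample_id = colnames(tpm),
    compartment = metadata$compartment[idx],
    n_expressed = as.integer(n_expr),
    coverage = unname(cov[colnames(tpm)]),
    stringsAsFactors = FALSE
  )
}
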