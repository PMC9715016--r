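#' Detect Y-chromosome presence from marker-gene expression
#'
#' Sums the TPM of the three Y-linked sex-marker genes (DDX3Y, RPS4Y1,
#' EIF1AY) per sample; a strict total above `y_tpm_threshold` (default 250)
#' indicates a Y chromosome.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param annotation A [gene_annotation()] flagging exactly three
#'   `is_y_marker` genes.
#' @param config A [pipeline_config()].
#' @return Named logical vector per sample, with the summed marker TPM as
#'   attribute `"marker_tpm"`.
#' @export
detect_y <- function(tpm, annotation, config = pipeline_config()) {
  if (matrix_unit(tpm) != "TPM") stop("detect_y needs a TPM matrix")
  markers <- annotation$gene_id[annotation$is_y_marker]
  if (length(markers) != 3) {
    stop("annotation must flag exactly 3 Y-marker genes, found ",
         length(markers))
  }
  missing <- setdiff(markers, rownames(tpm))
  if (length(missing) > 0) {
    stop("Y-marker gene absent from matrix: ", missing[[1]])
  }
  tot <- colSums(unclass(tpm)[markers, , drop = FALSE])
  out <- tot > config$y_tpm_threshold
  attr(out, "marker_tpm") <- tot
  out
}

#' Per-chromosome normalized expression signal
#'
#' For every sample and chromosome, counts over the chromosome's expressed
#' genes are summed and scaled to reads-per-million of the sample's total
#' over all expressed genes. X-chromosome signal excludes pseudoautosomal
#' genes, which sit on both sex chromosomes and would dilute X dosage.
#' Chromosomes with no expressed genes are dropped with a warning.
#'
#' @param counts A counts [expression_matrix()].
#' @param annotation A [gene_annotation()].
#' @param expressed An [expressed_gene_set()] defining the gene panel.
#' @return Numeric matrix samples x chromosomes (reads per million).
#' @export
chromosome_signal <- function(counts, annotation, expressed) {
  if (matrix_unit(counts) != "counts") stop("chromosome_signal needs counts")
  stopifnot(inherits(expressed, "expressed_set"))
  genes <- intersect(expressed$genes, rownames(counts))
  if (length(genes) == 0) stop("expressed set shares no genes with matrix")
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) stop("expressed gene missing from annotation: ",
                       genes[is.na(idx)][[1]])
  ann <- annotation[idx, , drop = FALSE]
  sub <- unclass(counts)[genes, , drop = FALSE]
  depth <- colSums(sub)
  if (any(depth <= 0)) {
    stop("sample has zero expressed-gene counts: ",
         colnames(sub)[which(depth <= 0)[[1]]])
  }
  keep_gene <- !(ann$chromosome == "X" & ann$is_par)
  present <- intersect(CHROMOSOMES, unique(ann$chromosome[keep_gene]))
  absent <- setdiff(CHROMOSOMES, present)
  if (length(absent) > 0) {
    warning("no expressed genes on chromosome(s): ",
            paste(absent, collapse = ", "))
  }
  sig <- vapply(present, function(ch) {
    rows <- ann$chromosome == ch & keep_gene
    1e6 * colSums(sub[rows, , drop = FALSE]) / depth
  }, numeric(ncol(sub)))
  sig <- matrix(sig, nrow = ncol(sub), ncol = length(present),
                dimnames = list(colnames(sub), present))
  sig
}

#' Z-scores of chromosome signals within each compartment
#'
#' For every chromosome, the mean and SD of the normalized signal are taken
#' across the samples of each compartment (ICM and TE separately, the
#' operative convention; `pooled = TRUE` uses all samples together), and each
#' sample's signal is standardized. Sample SD (denominator n-1) by default.
#' Zero-variance chromosomes get z = 0 and are listed in attribute
#' `"zero_variance"`.
#'
#' @param signal Matrix from [chromosome_signal()].
#' @param metadata A [sample_metadata()] covering the signal's samples.
#' @param sd_type `"sample"` (n-1) or `"population"` (n).
#' @param pooled Standardize across all samples instead of per compartment.
#' @return Matrix samples x chromosomes of Z-scores.
#' @export
zscores_by_compartment <- function(signal, metadata,
                                   sd_type = c("sample", "population"),
                                   pooled = FALSE) {
  sd_type <- match.arg(sd_type)
  idx <- match(rownames(signal), metadata$sample_id)
  if (anyNA(idx)) stop("signal sample missing from metadata: ",
                       rownames(signal)[is.na(idx)][[1]])
  comp <- if (pooled) rep("all", nrow(signal)) else metadata$compartment[idx]
  z <- signal * NA_real_
  zero_var <- character(0)
  for (cp in unique(comp)) {
    rows <- comp == cp
    n <- sum(rows)
    if (n < 3) stop("need >= 3 samples per compartment, ", cp, " has ", n)
    sub <- signal[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    if (sd_type == "population") sdv <- sdv * sqrt((n - 1) / n)
    for (k in seq_len(ncol(sub))) {
      if (sdv[[k]] == 0 || is.na(sdv[[k]])) {
        z[rows, k] <- 0
        zero_var <- c(zero_var, paste0(cp, ":", colnames(sub)[[k]]))
      } else {
        z[rows, k] <- (sub[, k] - mu[[k]]) / sdv[[k]]
      }
    }
  }
  attr(z, "zero_variance") <- unique(zero_var)
  z
}

#' Call autosomal gains and losses from Z-scores
#'
#' A chromosome is a potential gain when its Z-score strictly exceeds the
#' cutoff (default +2), a potential loss when strictly below the negative
#' cutoff, and euploid otherwise (so z = 2 exactly is euploid). With n
#' samples per compartment the largest attainable |z| under the sample-SD
#' convention is (n-1)/sqrt(n); a warning is emitted when that makes calls
#' impossible.
#'
#' @param z Matrix from [zscores_by_compartment()].
#' @param config A [pipeline_config()].
#' @param metadata Optional [sample_metadata()] used only for the small-n
#'   warning.
#' @return Data frame of class `"karyotype_calls"`: `sample_id`,
#'   `chromosome`, `z`, `call` (euploid/gain/loss), autosomes only.
#' @export
call_autosomes <- function(z, config = pipeline_config(), metadata = NULL) {
  cutoff <- config$autosome_z_cutoff
  if (!is.null(metadata)) {
    idx <- match(rownames(z), metadata$sample_id)
    for (cp in unique(metadata$compartment[idx])) {
      n <- sum(metadata$compartment[idx] == cp, na.rm = TRUE)
      if ((n - 1) / sqrt(n) <= cutoff) {
        warning("compartment ", cp, " has only ", n,
                " samples; |z| > ", cutoff, " is unattainable")
      }
    }
  }
  autosomes <- intersect(colnames(z), as.character(1:22))
  long <- expand.grid(sample_id = rownames(z), chromosome = autosomes,
                      stringsAsFactors = FALSE)
  long$z <- z[cbind(long$sample_id, long$chromosome)]
  long$call <- ifelse(long$z > cutoff, "gain",
                      ifelse(long$z < -cutoff, "loss", "euploid"))
  class(long) <- c("karyotype_calls", "data.frame")
  long
}

#' Call embryo sex per blastocyst
#'
#' XY when the Y markers are present in both compartments; discordant when
#' the compartments disagree on Y presence. With Y absent in both, the
#' blastocyst is XX when the X-dosage Z-scores are high, but flagged
#' potential XO when both compartments' X Z-scores fall below
#' `xo_flag_z_upper` (default 0.5) — an intermediate X dosage with no Y. The
#' XO flag is advisory, not a definitive monosomy call.
#'
#' @param y_present Named logical from [detect_y()].
#' @param x_z Named numeric: per-sample X-chromosome Z-score (the `"X"`
#'   column of [zscores_by_compartment()]).
#' @param metadata A [sample_metadata()].
#' @param config A [pipeline_config()].
#' @return Data frame of class `"sex_calls"`: `blastocyst_id`, per-
#'   compartment Y flags and X Z-scores, `sex` in
#'   `{XY, XX, potential_XO, discordant}`. Blastocysts missing a compartment
#'   are skipped with a warning.
#' @export
call_sex <- function(y_present, x_z, metadata, config = pipeline_config()) {
  rows <- list()
  for (b in unique(metadata$blastocyst_id)) {
    icm <- metadata$sample_id[metadata$blastocyst_id == b &
                                metadata$compartment == "ICM"]
    te <- metadata$sample_id[metadata$blastocyst_id == b &
                               metadata$compartment == "TE"]
    if (length(icm) != 1 || length(te) != 1 ||
        !all(c(icm, te) %in% names(y_present)) ||
        !all(c(icm, te) %in% names(x_z))) {
      warning("blastocyst ", b, " lacks a compartment; skipped")
      next
    }
    y <- c(y_present[[icm]], y_present[[te]])
    xz <- c(x_z[[icm]], x_z[[te]])
    sex <- if (all(y)) {
      "XY"
    } else if (any(y)) {
      "discordant"
    } else if (all(xz < config$xo_flag_z_upper)) {
      "potential_XO"
    } else {
      "XX"
    }
    rows[[b]] <- data.frame(
      blastocyst_id = b, y_icm = y[[1]], y_te = y[[2]],
      x_z_icm = xz[[1]], x_z_te = xz[[2]], sex = sex,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no complete blastocysts to call")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("sex_calls", "data.frame")
  out
}

#' Per-blastocyst karyotype summary
#'
#' One row per blastocyst: the sex call and the list of autosomal
#' gain/loss events, each annotated with the compartment(s) showing it and
#' whether ICM and TE agree (an event in one compartment only suggests
#' mosaicism or a false call).
#'
#' @param calls A [call_autosomes()] result.
#' @param sex A [call_sex()] result.
#' @param metadata A [sample_metadata()].
#' @return Data frame of class `"karyotype_report"`: `blastocyst_id`, `sex`,
#'   `n_events`, `events` (semicolon-joined `compartment:chrN:gain|loss`
#'   strings, empty when euploid), `concordant_events`.
#' @export
karyotype_report <- function(calls, sex, metadata) {
  idx <- match(calls$sample_id, metadata$sample_id)
  calls$blastocyst_id <- metadata$blastocyst_id[idx]
  calls$compartment <- metadata$compartment[idx]
  rows <- lapply(sex$blastocyst_id, function(b) {
    ev <- calls[calls$blastocyst_id == b & calls$call != "euploid", ,
                drop = FALSE]
    if (nrow(ev) == 0) {
      ev_str <- ""
      n_conc <- 0L
    } else {
      key <- paste(ev$chromosome, ev$call)
      conc <- table(key)
      ev$concordance <- ifelse(conc[paste(ev$chromosome, ev$call)] == 2,
                               "concordant", "discordant")
      ev_str <- paste(sprintf("%s:chr%s:%s[%s]", ev$compartment,
                              ev$chromosome, ev$call, ev$concordance),
                      collapse = ";")
      n_conc <- sum(ev$concordance == "concordant") %/% 2L
    }
    data.frame(blastocyst_id = b,
               sex = sex$sex[sex$blastocyst_id == b],
               n_events = nrow(ev), events = ev_str,
               concordant_events = n_conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("karyotype_report", "data.frame")
  out
}

#' Run the full digital-karyotyping stage
#'
#' Convenience wrapper: expressed set (scope "all", >= 1 sample by default),
#' chromosome signals from counts, per-compartment Z-scores, autosome calls,
#' Y detection from TPM, sex calls, and the per-blastocyst report.
#'
#' @param counts,tpm Counts and TPM [expression_matrix()]s.
#' @param annotation A [gene_annotation()].
#' @param metadata A [sample_metadata()].
#' @param config A [pipeline_config()].
#' @return List: `signal`, `z`, `calls`, `y_present`, `sex`, `report`.
#' @export
digital_karyotype <- function(counts, tpm, annotation, metadata,
                              config = pipeline_config()) {
  expressed <- expressed_gene_set(tpm, metadata,
                                  min_tpm = config$expressed_min_tpm,
                                  min_samples = config$expressed_min_samples,
                                  scope = "all")
  sig <- chromosome_signal(counts, annotation, expressed)
  z <- zscores_by_compartment(sig, metadata)
  calls <- call_autosomes(z, config, metadata)
  y <- detect_y(tpm, annotation, config)
  if (!"X" %in% colnames(z)) stop("no X-chromosome signal available")
  sex <- call_sex(y, z[, "X"], metadata, config)
  report <- karyotype_report(calls, sex, metadata)
  list(signal = sig, z = z, calls = calls, y_present = y, sex = sex,
       report = report)
}
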