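#' Construct an expression matrix
#'
#' A gene-by-sample numeric matrix tagged with its unit. Counts must be
#' non-negative integers; a TPM matrix must have every column summing to 1e6
#' within relative tolerance 1e-6 (columns of all zeros are rejected for TPM).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param unit `"counts"` or `"TPM"`.
#' @return The matrix with class `"expr_matrix"` prepended and a `"unit"`
#'   attribute.
#' @export
expression_matrix <- function(values, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyNA(values)) stop("expression matrix contains NA")
  if (any(values < 0)) stop("expression matrix contains negative entries")
  if (unit == "counts") {
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("counts matrix must be integer-valued")
    }
    values <- round(values)
  } else {
    cs <- colSums(values)
    off <- abs(cs - 1e6) > 1e6 * 1e-6
    if (any(off)) {
      stop("TPM columns must sum to 1e6; offending sample: ",
           colnames(values)[which(off)[[1]]])
    }
  }
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' Unit tag of an expression matrix
#' @param x An `"expr_matrix"`.
#' @return `"counts"` or `"TPM"`.
#' @export
matrix_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("matrix has no unit tag; use expression_matrix()")
  u
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), matrix_unit(x)))
  invisible(x)
}

#' Read a gene-by-sample expression matrix
#'
#' TSV: header `gene_id<TAB>sample1<TAB>...`; an optional leading comment line
#' `# unit: counts` / `# unit: TPM` declares the unit (the `unit` argument
#' overrides it). MatrixMarket: `path` is the `.mtx` file with sidecars
#' `<path>.rownames` and `<path>.colnames` holding one gene/sample id per
#' line.
#'
#' When an annotation is supplied, every matrix gene must be annotated and
#' rows are reordered to annotation order; with metadata, every column must be
#' a known sample.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @param unit `"counts"` or `"TPM"`; required unless the TSV declares it.
#' @param annotation Optional [gene_annotation()] to validate/align against.
#' @param metadata Optional [sample_metadata()] to validate against.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"), unit = NULL,
                        annotation = NULL, metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    skip <- 0L
    if (grepl("^#", first)) {
      skip <- 1L
      m <- regmatches(first, regexec("unit:\\s*(counts|TPM)", first))[[1]]
      if (length(m) == 2 && is.null(unit)) unit <- m[[2]]
    }
    df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[[1]] != "gene_id") stop("first TSV column must be gene_id")
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$gene_id
  } else {
    mm <- Matrix::readMM(path)
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn)) {
      stop("MatrixMarket input needs sidecars ", rn, " and ", cn)
    }
    vals <- as.matrix(mm)
    rownames(vals) <- readLines(rn)
    colnames(vals) <- readLines(cn)
  }
  if (is.null(unit)) stop("unit not declared in file; pass unit=")
  if (!is.null(annotation)) {
    unknown <- setdiff(rownames(vals), annotation$gene_id)
    if (length(unknown) > 0) {
      stop("matrix genes absent from annotation: ",
           paste(utils::head(unknown, 10), collapse = ", "))
    }
    keep <- annotation$gene_id[annotation$gene_id %in% rownames(vals)]
    vals <- vals[keep, , drop = FALSE]
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(colnames(vals), metadata$sample_id)
    if (length(unknown) > 0) {
      stop("matrix samples absent from metadata: ",
           paste(utils::head(unknown, 10), collapse = ", "))
    }
  }
  expression_matrix(vals, unit = unit)
}

#' Write an expression matrix
#'
#' TSV output carries a `# unit:` comment line so the unit survives a
#' round trip; MatrixMarket output writes `.rownames`/`.colnames` sidecars.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  unit <- matrix_unit(x)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# unit: ", unit), con)
    df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rownames"))
    writeLines(colnames(x), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Transcripts per million from raw counts
#'
#' Standard single-length TPM: each gene's count is divided by its length in
#' kb to give a rate, and each sample's rates are scaled to sum to one
#' million. Zero counts map to zero TPM; every column of the result sums to
#' 1e6 by construction.
#'
#' @param counts A counts [expression_matrix()].
#' @param annotation A [gene_annotation()] covering all matrix genes.
#' @return A TPM [expression_matrix()] with the same dimensions.
#' @export
tpm_from_counts <- function(counts, annotation) {
  if (matrix_unit(counts) != "counts") stop("input must be a counts matrix")
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx)) {
    stop("counts genes absent from annotation: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 10), collapse = ", "))
  }
  len <- annotation$length_bp[idx]
  rate <- unclass(counts) / len
  tot <- colSums(rate)
  zero <- tot <= 0
  if (any(zero)) {
    stop("sample has no counts, TPM undefined: ",
         colnames(counts)[which(zero)[[1]]])
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(tpm, unit = "TPM")
}
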