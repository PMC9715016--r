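#' @keywords internal
CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Construct and validate a gene annotation table
#'
#' The annotation is the coordinate frame for all digital karyotyping: each
#' gene carries its chromosome (1-22, X, Y), its length in bp (used for TPM),
#' a pseudoautosomal-region flag (PAR genes are excluded from X-dosage
#' inference because they sit on both sex chromosomes), and a Y-marker flag
#' that is true for exactly the three Y-linked sex-marker genes
#' (DDX3Y, RPS4Y1, EIF1AY in the human genome).
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `length_bp`,
#'   `is_par`, `is_y_marker`.
#' @return The validated data frame with class `c("gene_annotation",
#'   "data.frame")`, chromosomes as character.
#' @export
gene_annotation <- function(df) {
  req <- c("gene_id", "chromosome", "length_bp", "is_par", "is_y_marker")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("annotation missing columns: ",
                             paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$length_bp <- as.integer(df$length_bp)
  df$is_par <- as.logical(df$is_par)
  df$is_y_marker <- as.logical(df$is_y_marker)

  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) stop("duplicate gene_id in annotation: ", dup[[1]])
  bad_chr <- !(df$chromosome %in% CHROMOSOMES)
  if (any(bad_chr)) {
    # contigs/patches are dropped, not fatal
    message("dropping ", sum(bad_chr), " gene(s) on unknown chromosomes")
    df <- df[!bad_chr, , drop = FALSE]
  }
  if (any(df$is_par & df$chromosome != "X")) {
    off <- df$gene_id[df$is_par & df$chromosome != "X"][[1]]
    stop("is_par set on non-X gene: ", off)
  }
  if (any(df$is_y_marker & df$chromosome != "Y")) {
    off <- df$gene_id[df$is_y_marker & df$chromosome != "Y"][[1]]
    stop("is_y_marker set on non-Y gene: ", off)
  }
  if (any(is.na(df$length_bp)) || any(df$length_bp < 1L)) {
    stop("length_bp must be a positive integer for every gene")
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation table
#'
#' TSV is the canonical format (header `gene_id`, `chromosome`, `length_bp`,
#' `is_par`, `is_y_marker`). A GTF can be supplied instead; gene lengths are
#' then the summed exon span of each gene's longest transcript, and the PAR
#' and Y-marker flags are derived from the PAR interval fixture shipped with
#' the package (see `system.file("extdata", "par_intervals_hg19.tsv")`) and
#' the three marker gene names.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"gtf"`.
#' @return A [gene_annotation()] data frame.
#' @export
read_annotation <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(chromosome = "character"))
    return(gene_annotation(df))
  }
  gene_annotation(annotation_from_gtf(path))
}

# GTF support goes through rtracklayer; length = summed exon widths of the
# longest transcript. PAR membership from the hg19 interval fixture.
annotation_from_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package; ",
         "convert to the TSV annotation format instead")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon records")
  gid <- as.character(ex$gene_id)
  tid <- as.character(ex$transcript_id)
  w <- BiocGenerics::width(ex)
  chr <- sub("^chr", "", as.character(GenomicRanges::seqnames(ex)))
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  tx_len <- tapply(w, tid, sum)
  tx_gene <- tapply(gid, tid, function(x) x[[1]])
  gene_len <- tapply(as.numeric(tx_len), as.character(tx_gene), max)
  gene_chr <- tapply(chr, gid, function(x) x[[1]])
  gene_start <- tapply(st, gid, min)
  gene_end <- tapply(en, gid, max)
  ids <- names(gene_len)
  par <- par_intervals()
  par_x <- par[par$chromosome == "X", , drop = FALSE]
  is_par <- rep(FALSE, length(ids))
  on_x <- gene_chr[ids] == "X"
  for (i in seq_len(nrow(par_x))) {
    is_par <- is_par | (on_x &
                          gene_start[ids] <= par_x$end[i] &
                          gene_end[ids] >= par_x$start[i])
  }
  is_y_marker <- toupper(ids) %in% Y_MARKER_GENES &
    gene_chr[ids] == "Y"
  data.frame(
    gene_id = ids,
    chromosome = as.character(gene_chr[ids]),
    length_bp = as.integer(gene_len[ids]),
    is_par = as.logical(is_par),
    is_y_marker = as.logical(is_y_marker),
    stringsAsFactors = FALSE
  )
}

#' The three Y-linked sex-marker genes
#'
#' Summed TPM of these genes above the configured threshold indicates the
#' presence of a Y chromosome.
#' @export
Y_MARKER_GENES <- c("DDX3Y", "RPS4Y1", "EIF1AY")

#' hg19 pseudoautosomal intervals
#'
#' PAR1/PAR2 coordinates (1-based, closed) on X and Y in hg19, shipped as a
#' plain-text fixture for users deriving `is_par` flags from a real GTF.
#' @return Data frame with columns `par`, `chromosome`, `start`, `end`.
#' @export
par_intervals <- function() {
  path <- system.file("extdata", "par_intervals_hg19.tsv",
                      package = "blastomics", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Write a gene annotation table to TSV
#' @param annotation A [gene_annotation()] data frame.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
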