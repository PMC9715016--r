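#' Construct and validate a sample metadata table
#'
#' One row per RNA-seq library. Each blastocyst contributes at most one inner
#' cell mass (ICM) and one trophectoderm (TE) sample; the compartment is never
#' missing. The expectation group records the growth-kinetics classification
#' of the source blastocyst: H (high, Group 1), M (intermediate, Group 3),
#' L (low, Group 2), or NA when unknown.
#'
#' @param df Data frame with columns `sample_id`, `blastocyst_id`,
#'   `compartment` (`"ICM"`/`"TE"`), and optionally `expectation_group`
#'   (`"H"`/`"M"`/`"L"`/NA), `maternal_age` (years), `gardner_score` (e.g.
#'   `"4BB"`, NA allowed).
#' @return Validated data frame with class `c("sample_metadata",
#'   "data.frame")`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "blastocyst_id", "compartment")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("metadata missing columns: ",
                             paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  for (opt in c("expectation_group", "gardner_score")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  }
  if (!"maternal_age" %in% names(df)) df$maternal_age <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df$blastocyst_id <- as.character(df$blastocyst_id)
  df$compartment <- as.character(df$compartment)
  df$expectation_group <- as.character(df$expectation_group)
  df$maternal_age <- as.integer(df$maternal_age)
  df$gardner_score <- as.character(df$gardner_score)

  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][[1]])
  }
  if (any(is.na(df$compartment)) || !all(df$compartment %in% c("ICM", "TE"))) {
    stop("compartment must be ICM or TE for every sample")
  }
  tab <- table(df$blastocyst_id, df$compartment)
  if (any(tab > 1)) {
    stop("a blastocyst has more than one sample per compartment: ",
         rownames(tab)[which(tab > 1, arr.ind = TRUE)[1, 1]])
  }
  known <- is.na(df$expectation_group) | df$expectation_group %in% c("H", "M", "L")
  if (!all(known)) stop("expectation_group must be H, M, L or NA")
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV file with the [sample_metadata()] columns.
#' @return A `"sample_metadata"` data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sample_metadata(utils::read.delim(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Write sample metadata to TSV
#' @param metadata A `"sample_metadata"` data frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The 13-blastocyst study design fixture
#'
#' Transcription of the published study's blastocyst table: 13 blastocysts
#' (H1-H5 high, M1-M4 intermediate, L1-L4 low expectation of pregnancy) with
#' maternal age and Gardner score. `table1_blastocysts()` returns one row per
#' blastocyst; `table1_samples()` expands it to the 26 RNA-seq libraries
#' (ICM + TE per blastocyst).
#'
#' @return `table1_blastocysts()`: data frame with columns `blastocyst_id`,
#'   `growth_group`, `expectation_group`, `maternal_age`, `gardner_score`.
#'   `table1_samples()`: a [sample_metadata()] data frame of 26 samples with
#'   ids like `"H1_ICM"`.
#' @export
table1_blastocysts <- function() {
  path <- system.file("extdata", "table1_blastocysts.tsv",
                      package = "blastomics", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname table1_blastocysts
#' @export
table1_samples <- function() {
  b <- table1_blastocysts()
  df <- data.frame(
    sample_id = paste(rep(b$blastocyst_id, each = 2), c("ICM", "TE"), sep = "_"),
    blastocyst_id = rep(b$blastocyst_id, each = 2),
    compartment = rep(c("ICM", "TE"), times = nrow(b)),
    expectation_group = rep(b$expectation_group, each = 2),
    maternal_age = rep(b$maternal_age, each = 2),
    gardner_score = rep(b$gardner_score, each = 2),
    stringsAsFactors = FALSE
  )
  sample_metadata(df)
}
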