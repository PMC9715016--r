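#' Synthetic study design
#'
#' Describes a synthetic biopsy-scale RNA-seq experiment mirroring the
#' 13-blastocyst study layout: blastocysts per expectation group, genes per
#' chromosome, the negative-binomial noise level, library-size spread, the
#' sex of each blastocyst, planted whole-chromosome gains/losses, and planted
#' H-versus-L differential expression.
#'
#' Counts for gene g in sample j are drawn NB(mu, alpha) with
#' `mu = baseline_g * ploidy dosage * sex dosage * DE fold change * library
#' size` and variance `mu + alpha * mu^2`. Defaults: gained chromosomes at
#' 1.5x, lost at 0.5x, the single X of an XY embryo at 0.5x, and the X of an
#' XO embryo at 0.7x — intermediate between XX and XY, emulating the
#' intermediately expressed X reported for the suspected XO blastocyst.
#' Intermediate-group (M) samples receive half the planted H-vs-L log2 fold
#' change so planted markers show graded expression across groups.
#'
#' @param n_blastocysts_per_group Named integer vector `c(H=, M=, L=)`.
#'   Default `c(H = 5, M = 4, L = 4)`, the study's 13 blastocysts.
#' @param genes_per_chromosome Genes simulated per chromosome (default 400).
#' @param baseline_log2_mean Mean and SD of per-gene baseline log2 mean
#'   counts, default `c(6, 2)` — roughly 1.6 million counts over 9600 genes
#'   per unit library, the depth scale of a sequenced SMART-Seq biopsy
#'   library.
#' @param nb_dispersion NB dispersion alpha (default 0.10, typical low-input
#'   bulk). 0 gives Poisson counts.
#' @param library_size_range Library size factors drawn log-uniformly in this
#'   range (default 0.5x-2x).
#' @param sex_assignment Named character vector blastocyst id -> `"XX"`,
#'   `"XY"` or `"XO"`. Default: L1 is XO (when present) and the remaining
#'   blastocysts alternate XY/XX, giving the study's 6 XY + 6 XX + 1 XO at the
#'   default design size.
#' @param ploidy_events Data frame with columns `blastocyst_id`,
#'   `compartment` (`"ICM"`, `"TE"` or `"both"`), `chromosome`, `event`
#'   (`"gain"`/`"loss"`), or NULL for a fully euploid design.
#' @param de_config List `n_genes`, `log2fc`, `prop_up`: number of autosomal
#'   genes given a planted H-vs-L fold change, its magnitude, and the
#'   fraction up in H. Default no planted DE.
#' @param dosage_factors Named numerics `gain`, `loss`, `xo_x`.
#' @param par_fraction Fraction of X genes flagged pseudoautosomal
#'   (default 0.05).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `"sim_design"`.
#' @export
sim_design <- function(n_blastocysts_per_group = c(H = 5L, M = 4L, L = 4L),
                       genes_per_chromosome = 400L,
                       baseline_log2_mean = c(6, 2),
                       nb_dispersion = 0.10,
                       library_size_range = c(0.5, 2),
                       sex_assignment = NULL,
                       ploidy_events = NULL,
                       de_config = list(n_genes = 0L, log2fc = 2,
                                        prop_up = 0.5),
                       dosage_factors = c(gain = 1.5, loss = 0.5, xo_x = 0.7),
                       par_fraction = 0.05,
                       seed = 1L) {
  stopifnot(all(c("H", "M", "L") %in% names(n_blastocysts_per_group)),
            all(n_blastocysts_per_group >= 0),
            genes_per_chromosome >= 1,
            length(baseline_log2_mean) == 2, baseline_log2_mean[[2]] >= 0,
            nb_dispersion >= 0,
            length(library_size_range) == 2,
            all(library_size_range > 0),
            library_size_range[[1]] <= library_size_range[[2]],
            all(c("gain", "loss", "xo_x") %in% names(dosage_factors)),
            all(dosage_factors > 0),
            par_fraction >= 0, par_fraction < 1)
  if (!(dosage_factors[["gain"]] > 1 && dosage_factors[["loss"]] < 1)) {
    stop("dosage factors must satisfy gain > 1 > loss")
  }
  ids <- c(
    if (n_blastocysts_per_group[["H"]] > 0)
      paste0("H", seq_len(n_blastocysts_per_group[["H"]])),
    if (n_blastocysts_per_group[["M"]] > 0)
      paste0("M", seq_len(n_blastocysts_per_group[["M"]])),
    if (n_blastocysts_per_group[["L"]] > 0)
      paste0("L", seq_len(n_blastocysts_per_group[["L"]]))
  )
  if (length(ids) == 0) stop("design has no blastocysts")
  if (is.null(sex_assignment)) {
    default13 <- c(H1 = "XY", H2 = "XX", H3 = "XY", H4 = "XX", H5 = "XY",
                   M1 = "XX", M2 = "XY", M3 = "XX", M4 = "XY",
                   L1 = "XO", L2 = "XX", L3 = "XY", L4 = "XX")
    if (setequal(ids, names(default13))) {
      # the study layout: 6 XY, 6 XX, one suspected XO (L1)
      sex_assignment <- default13
    } else {
      sex_assignment <- stats::setNames(
        rep(c("XY", "XX"), length.out = length(ids)), ids)
      if ("L1" %in% ids) sex_assignment[["L1"]] <- "XO"
    }
  }
  if (!all(ids %in% names(sex_assignment))) {
    stop("sex_assignment must cover every blastocyst id")
  }
  sex_assignment <- sex_assignment[ids]
  if (!all(sex_assignment %in% c("XX", "XY", "XO"))) {
    stop("sex must be XX, XY or XO")
  }
  if (!is.null(ploidy_events)) {
    ploidy_events <- as.data.frame(ploidy_events)
    req <- c("blastocyst_id", "compartment", "chromosome", "event")
    if (!all(req %in% names(ploidy_events))) {
      stop("ploidy_events needs columns ", paste(req, collapse = ", "))
    }
    ploidy_events$chromosome <- as.character(ploidy_events$chromosome)
    stopifnot(all(ploidy_events$blastocyst_id %in% ids),
              all(ploidy_events$compartment %in% c("ICM", "TE", "both")),
              all(ploidy_events$chromosome %in% CHROMOSOMES),
              all(ploidy_events$event %in% c("gain", "loss")))
  }
  de_defaults <- list(n_genes = 0L, log2fc = 2, prop_up = 0.5)
  de_config <- utils::modifyList(de_defaults, as.list(de_config))
  design <- list(
    n_blastocysts_per_group = n_blastocysts_per_group,
    blastocyst_ids = ids,
    genes_per_chromosome = as.integer(genes_per_chromosome),
    baseline_log2_mean = as.numeric(baseline_log2_mean),
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_range = as.numeric(library_size_range),
    sex_assignment = sex_assignment,
    ploidy_events = ploidy_events,
    de_config = de_config,
    dosage_factors = dosage_factors,
    par_fraction = as.numeric(par_fraction),
    seed = as.integer(seed)
  )
  class(design) <- "sim_design"
  design
}

#' Simulate a gene annotation for a synthetic design
#'
#' 24 chromosomes (1-22, X, Y) each carrying `genes_per_chromosome` genes;
#' exactly three Y genes are flagged as the Y sex markers, a configurable
#' fraction of X genes is flagged pseudoautosomal, and lengths are drawn
#' uniformly in 500-5000 bp. Deterministic given `design$seed`.
#'
#' @param design A [sim_design()].
#' @return A [gene_annotation()] of `24 * genes_per_chromosome` genes.
#' @export
make_annotation <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  g <- design$genes_per_chromosome
  if (g < 3) stop("genes_per_chromosome must be >= 3 to host the three Y markers")
  set.seed(design$seed)
  chrom <- rep(CHROMOSOMES, each = g)
  gene_id <- paste0("chr", chrom, "_g", rep(seq_len(g), times = length(CHROMOSOMES)))
  len <- sample(500:5000, length(gene_id), replace = TRUE)
  is_y_marker <- rep(FALSE, length(gene_id))
  y_idx <- which(chrom == "Y")[1:3]
  gene_id[y_idx] <- Y_MARKER_GENES
  is_y_marker[y_idx] <- TRUE
  is_par <- rep(FALSE, length(gene_id))
  x_idx <- which(chrom == "X")
  n_par <- floor(design$par_fraction * length(x_idx))
  if (n_par > 0) is_par[sample(x_idx, n_par)] <- TRUE
  gene_annotation(data.frame(
    gene_id = gene_id, chromosome = chrom, length_bp = len,
    is_par = is_par, is_y_marker = is_y_marker, stringsAsFactors = FALSE
  ))
}

# dosage multiplier matrix (genes x samples) for sex chromosomes and planted
# ploidy events; PAR genes stay at one copy-pair dose except in XO (0.5)
sim_dosage <- function(design, annotation, metadata) {
  G <- nrow(annotation)
  S <- nrow(metadata)
  dos <- matrix(1, G, S, dimnames = list(annotation$gene_id, metadata$sample_id))
  x_genes <- annotation$chromosome == "X" & !annotation$is_par
  par_genes <- annotation$is_par
  y_genes <- annotation$chromosome == "Y"
  for (j in seq_len(S)) {
    sex <- design$sex_assignment[[metadata$blastocyst_id[[j]]]]
    if (sex == "XY") {
      dos[x_genes, j] <- 0.5
    } else if (sex == "XO") {
      dos[x_genes, j] <- design$dosage_factors[["xo_x"]]
      dos[par_genes, j] <- 0.5
      dos[y_genes, j] <- 0
    }
    if (sex == "XX") dos[y_genes, j] <- 0
  }
  ev <- design$ploidy_events
  if (!is.null(ev) && nrow(ev) > 0) {
    fac <- ifelse(ev$event == "gain",
                  design$dosage_factors[["gain"]],
                  design$dosage_factors[["loss"]])
    for (k in seq_len(nrow(ev))) {
      rows <- annotation$chromosome == ev$chromosome[[k]]
      cols <- metadata$blastocyst_id == ev$blastocyst_id[[k]]
      if (ev$compartment[[k]] != "both") {
        cols <- cols & metadata$compartment == ev$compartment[[k]]
      }
      dos[rows, cols] <- dos[rows, cols] * fac[[k]]
    }
  }
  dos
}

#' Simulate biopsy-scale RNA-seq counts with planted truth
#'
#' Draws one ICM and one TE library per blastocyst from the negative-binomial
#' model described in [sim_design()]. Y-marker genes get a baseline well
#' above the average gene so that an XY embryo's summed marker TPM clears the
#' Y-presence threshold by a wide margin, and Y genes have mean zero in
#' non-XY samples.
#'
#' @param design A [sim_design()].
#' @param annotation The matching [make_annotation()] output.
#' @return List with `counts` (an [expression_matrix()]), `metadata`
#'   (a [sample_metadata()]) and `truth` (list `sex`, `copy_state`, `de` —
#'   see Details).
#' @details `truth$sex` maps blastocyst id to XX/XY/XO; `truth$copy_state` is
#'   a long data frame (`sample_id`, `chromosome`, `state`) with state
#'   euploid/gain/loss; `truth$de` has `gene_id`, `is_de`, `sign` (+1 = up in
#'   H relative to L).
#' @export
simulate_counts <- function(design, annotation) {
  stopifnot(inherits(design, "sim_design"), inherits(annotation, "gene_annotation"))
  set.seed(design$seed + 1L)
  ids <- design$blastocyst_ids
  metadata <- sample_metadata(data.frame(
    sample_id = paste(rep(ids, each = 2), c("ICM", "TE"), sep = "_"),
    blastocyst_id = rep(ids, each = 2),
    compartment = rep(c("ICM", "TE"), length(ids)),
    expectation_group = rep(substr(ids, 1, 1), each = 2),
    stringsAsFactors = FALSE
  ))
  G <- nrow(annotation)
  S <- nrow(metadata)

  base <- 2^stats::rnorm(G, design$baseline_log2_mean[[1]],
                         design$baseline_log2_mean[[2]])
  # markers sit ~6x above the average gene (16x the median) so an XY embryo
  # clears the summed 250-TPM rule with a wide margin at any marker length
  base[annotation$is_y_marker] <- 2^(design$baseline_log2_mean[[1]] + 4)

  # planted DE: autosomal non-marker genes, fold change applied to H (full)
  # and M (half) samples relative to the L baseline
  de <- data.frame(gene_id = annotation$gene_id, is_de = FALSE, sign = 0L,
                   stringsAsFactors = FALSE)
  n_de <- design$de_config$n_genes
  de_fc <- matrix(1, G, S)
  if (n_de > 0) {
    eligible <- which(annotation$chromosome %in% as.character(1:22))
    if (n_de > length(eligible)) stop("more DE genes requested than autosomal genes")
    pick <- sample(eligible, n_de)
    n_up <- round(design$de_config$prop_up * n_de)
    sgn <- c(rep(1L, n_up), rep(-1L, n_de - n_up))
    de$is_de[pick] <- TRUE
    de$sign[pick] <- sgn
    lfc <- design$de_config$log2fc * sgn
    h_cols <- metadata$expectation_group == "H"
    m_cols <- metadata$expectation_group == "M"
    de_fc[pick, h_cols] <- 2^lfc
    de_fc[pick, m_cols] <- 2^(lfc / 2)
  }

  lib <- exp(stats::runif(S, log(design$library_size_range[[1]]),
                          log(design$library_size_range[[2]])))
  dos <- sim_dosage(design, annotation, metadata)
  mu <- (base * dos * de_fc) %*% diag(lib)  # genes x samples
  dimnames(mu) <- list(annotation$gene_id, metadata$sample_id)

  alpha <- design$nb_dispersion
  vals <- if (alpha > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  counts <- matrix(vals, G, S, dimnames = dimnames(mu))

  copy_state <- expand.grid(sample_id = metadata$sample_id,
                            chromosome = CHROMOSOMES,
                            stringsAsFactors = FALSE)
  copy_state$state <- "euploid"
  ev <- design$ploidy_events
  if (!is.null(ev) && nrow(ev) > 0) {
    for (k in seq_len(nrow(ev))) {
      samp <- metadata$sample_id[metadata$blastocyst_id == ev$blastocyst_id[[k]] &
        (ev$compartment[[k]] == "both" |
           metadata$compartment == ev$compartment[[k]])]
      sel <- copy_state$sample_id %in% samp &
        copy_state$chromosome == ev$chromosome[[k]]
      copy_state$state[sel] <- ev$event[[k]]
    }
  }
  list(
    counts = expression_matrix(counts, unit = "counts"),
    metadata = metadata,
    truth = list(sex = design$sex_assignment, copy_state = copy_state, de = de),
    expected_mean = mu
  )
}

#' Simulate a clinical transfer cohort
#'
#' Each case is assigned a growth-kinetics group with the given probabilities,
#' receives (hours, diameter) drawn uniformly inside that group's rule region
#' (so [classify_growth()] maps it back to the intended group), and a
#' Bernoulli gestational-sac outcome at the group's pregnancy rate.
#'
#' @param n_cases Number of transfer cases.
#' @param group_fractions Probabilities of Groups 1-3, summing to 1.
#' @param pregnancy_rates Per-group gestational-sac confirmation rates.
#' @param seed Integer seed.
#' @param config A [pipeline_config()] supplying the rule thresholds.
#' @return Data frame `case_id`, `group_assigned`, `hours_to_blastocyst`,
#'   `diameter_um`, `gs_confirmed` of class `c("transfer_cohort",
#'   "data.frame")`.
#' @export
simulate_cohort <- function(n_cases, group_fractions, pregnancy_rates,
                            seed = 1L, config = pipeline_config()) {
  stopifnot(n_cases >= 1, length(group_fractions) == 3,
            length(pregnancy_rates) == 3,
            all(pregnancy_rates >= 0), all(pregnancy_rates <= 1),
            all(group_fractions >= 0))
  if (abs(sum(group_fractions) - 1) > 1e-9) {
    stop("group_fractions must sum to 1")
  }
  set.seed(seed)
  grp <- sample.int(3, n_cases, replace = TRUE, prob = group_fractions)
  hours <- numeric(n_cases)
  diam <- numeric(n_cases)
  h1 <- config$group1_max_hours
  h2 <- config$group2_min_hours
  d1 <- config$group1_min_diameter_um
  d2 <- config$group2_max_diameter_um
  # strict inequalities: sample with a small margin so boundary values never occur
  eps <- 0.5
  g1 <- grp == 1
  hours[g1] <- stats::runif(sum(g1), h1 - 24, h1 - eps)
  diam[g1] <- stats::runif(sum(g1), d1 + eps, d1 + 40)
  g2 <- grp == 2
  hours[g2] <- stats::runif(sum(g2), h2 + eps, h2 + 30)
  diam[g2] <- stats::runif(sum(g2), d2 - 50, d2 - eps)
  # group 3: hours between the two windows -> "the rest" regardless of diameter
  g3 <- grp == 3
  hours[g3] <- stats::runif(sum(g3), h1 + eps, h2 - eps)
  diam[g3] <- stats::runif(sum(g3), d2 - 40, d2 + 40)
  gs <- stats::rbinom(n_cases, 1, pregnancy_rates[grp]) == 1
  out <- data.frame(
    case_id = sprintf("case%05d", seq_len(n_cases)),
    group_assigned = paste0("Group", grp),
    hours_to_blastocyst = hours,
    diameter_um = diam,
    gs_confirmed = gs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("transfer_cohort", "data.frame")
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.tsv`, `annotation.tsv`, `metadata.tsv`, `truth_copy_state.tsv`,
#' `truth_de.tsv` and `truth_sex.tsv` under `out_dir`.
#'
#' @param sim Output of [simulate_counts()].
#' @param annotation The matching annotation.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, annotation, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
  write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv"))
  utils::write.table(sim$truth$copy_state,
                     file.path(out_dir, "truth_copy_state.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$de, file.path(out_dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(blastocyst_id = names(sim$truth$sex), sex = unname(sim$truth$sex)),
    file.path(out_dir, "truth_sex.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
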