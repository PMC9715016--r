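#' Median-of-ratios size factors
#'
#' DESeq-style depth normalization: each sample's factor is the median of its
#' per-gene count ratios to the geometric-mean reference gene, over genes
#' with nonzero counts in every sample; factors are rescaled to geometric
#' mean 1. When no gene is positive in all samples, the reference geometric
#' mean is taken over each gene's positive samples instead (with a warning).
#'
#' @param counts A counts [expression_matrix()] or plain matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  x <- unclass(counts)
  all_pos <- rowSums(x > 0) == ncol(x)
  if (any(all_pos)) {
    logx <- log(x[all_pos, , drop = FALSE])
    ref <- rowMeans(logx)
    sf <- apply(logx, 2, function(col) exp(stats::median(col - ref)))
  } else {
    warning("no gene positive in all samples; using positive-subset reference")
    logx <- log(x)
    logx[!is.finite(logx)] <- NA
    ref <- rowMeans(logx, na.rm = TRUE)
    keep <- is.finite(ref)
    if (!any(keep)) stop("cannot compute size factors: all-zero matrix")
    sf <- apply(logx[keep, , drop = FALSE], 2, function(col) {
      exp(stats::median(col - ref[keep], na.rm = TRUE))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(x))
}

#' Define a two-group comparison
#'
#' Builds the sample grouping for one of the three published comparison
#' schemes within a compartment. The reference (baseline) group is always
#' the lower-quality one — low expectation, poor Gardner grade, or elder
#' maternal age — so a positive log2 fold change means higher expression in
#' the better-prognosis group.
#'
#' @param metadata A [sample_metadata()].
#' @param scheme `"expectation"` (H vs L; M excluded), `"age"` (young vs
#'   elder) or `"gardner"` (good vs poor).
#' @param compartment `"ICM"` or `"TE"`.
#' @param config A [pipeline_config()].
#' @return List of class `"grouping_scheme"`: `name`, `compartment`,
#'   `reference` / `treatment` labels, `ref_ids`, `trt_ids`.
#' @export
grouping_scheme <- function(metadata, scheme = c("expectation", "age", "gardner"),
                            compartment = c("ICM", "TE"),
                            config = pipeline_config()) {
  scheme <- match.arg(scheme)
  compartment <- match.arg(compartment)
  md <- metadata[metadata$compartment == compartment, , drop = FALSE]
  if (scheme == "expectation") {
    ref <- md$sample_id[md$expectation_group %in% "L"]
    trt <- md$sample_id[md$expectation_group %in% "H"]
    labels <- c("L", "H")
  } else if (scheme == "age") {
    ok <- !is.na(md$maternal_age)
    grp <- vapply(md$maternal_age[ok], age_group, character(1), config = config)
    ref <- md$sample_id[ok][grp == "elder"]
    trt <- md$sample_id[ok][grp == "young"]
    labels <- c("elder", "young")
  } else {
    ok <- !is.na(md$gardner_score)
    grp <- vapply(md$gardner_score[ok], grade_group, character(1))
    ref <- md$sample_id[ok][grp == "poor"]
    trt <- md$sample_id[ok][grp == "good"]
    labels <- c("poor", "good")
  }
  if (length(ref) < 2 || length(trt) < 2) {
    stop("each group needs >= 2 samples (", labels[[1]], ": ", length(ref),
         ", ", labels[[2]], ": ", length(trt), ")")
  }
  out <- list(name = scheme, compartment = compartment,
              reference = labels[[1]], treatment = labels[[2]],
              ref_ids = ref, trt_ids = trt)
  class(out) <- "grouping_scheme"
  out
}

# ---- vectorized NB fitting core -------------------------------------------
# Model per gene: counts_j ~ NB(mu_j, alpha), mu_j = s_j * q_group(j).
# Group means fitted by Newton on log q (expected information), vectorized
# over genes; dispersion by Cox-Reid adjusted profile ML on a log-alpha grid
# with quadratic refinement, then shrunk toward a log-linear mean-dispersion
# trend.

# Newton fit of log q for one group, all genes at once.
# Y: genes x n matrix, s: length-n size factors, alpha: per-gene dispersion.
# Returns list(eta = log q, info = expected information at the optimum).
nb_fit_group <- function(Y, s, alpha, n_iter = 25L) {
  g_mean <- pmax(rowMeans(sweep(Y, 2, s, "/")), 1e-8)
  eta <- log(g_mean)
  for (it in seq_len(n_iter)) {
    mu <- exp(eta) %o% s
    denom <- 1 + alpha * mu
    U <- rowSums((Y - mu) / denom)
    I <- pmax(rowSums(mu / denom), 1e-10)
    step <- U / I
    step <- pmin(pmax(step, -3), 3)
    eta <- pmax(eta + step, log(1e-10))
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(eta) %o% s
  list(eta = eta, info = pmax(rowSums(mu / (1 + alpha * mu)), 1e-12), mu = mu)
}

# NB log-likelihood per gene (rows), given mu matrix and per-gene alpha.
nb_loglik <- function(Y, mu, alpha) {
  a <- pmax(alpha, 1e-12)
  size <- 1 / a
  rowSums(lgamma(Y + size) - lgamma(size) - lgamma(Y + 1) +
            Y * log(mu * a / (1 + mu * a)) - size * log1p(mu * a))
}

# Cox-Reid adjusted profile log-likelihood at a common alpha for all genes.
nb_profile_ll <- function(Ya, Yb, sa, sb, alpha_vec) {
  fa <- nb_fit_group(Ya, sa, alpha_vec)
  fb <- nb_fit_group(Yb, sb, alpha_vec)
  ll <- nb_loglik(Ya, fa$mu, alpha_vec) + nb_loglik(Yb, fb$mu, alpha_vec)
  ll - 0.5 * (log(fa$info) + log(fb$info))
}

# Gene-wise dispersion: grid over log alpha + quadratic refinement.
estimate_dispersion_grid <- function(Ya, Yb, sa, sb,
                                     grid = exp(seq(log(1e-4), log(6),
                                                    length.out = 25))) {
  G <- nrow(Ya)
  ll <- matrix(NA_real_, G, length(grid))
  for (k in seq_along(grid)) {
    ll[, k] <- nb_profile_ll(Ya, Yb, sa, sb, rep(grid[[k]], G))
  }
  best <- max.col(ll, ties.method = "first")
  log_grid <- log(grid)
  alpha <- log_grid[best]
  # quadratic interpolation around the grid optimum
  interior <- best > 1 & best < length(grid)
  if (any(interior)) {
    i <- best[interior]
    idx <- which(interior)
    y1 <- ll[cbind(idx, i - 1L)]
    y2 <- ll[cbind(idx, i)]
    y3 <- ll[cbind(idx, i + 1L)]
    x1 <- log_grid[i - 1L]; x2 <- log_grid[i]; x3 <- log_grid[i + 1L]
    denom <- (y1 - 2 * y2 + y3)
    ok <- is.finite(denom) & denom < 0
    shift <- rep(0, length(idx))
    shift[ok] <- 0.5 * (y1[ok] - y3[ok]) / denom[ok] * (x3[ok] - x1[ok]) / 2
    shift <- pmin(pmax(shift, -(x2 - x1)), x3 - x2)
    alpha[interior] <- x2 + shift
  }
  exp(alpha)
}

# Shrink log dispersions toward a log-linear trend in log base mean,
# weighting by the residual variance relative to the trend scatter.
shrink_dispersion <- function(alpha_gw, base_mean, n_samples) {
  la <- log(alpha_gw)
  lm_ok <- is.finite(la) & base_mean > 0
  if (sum(lm_ok) < 10) return(alpha_gw)
  fit <- stats::lm(la[lm_ok] ~ log(base_mean[lm_ok]))
  trend <- fit$coefficients[[1]] + fit$coefficients[[2]] * log(pmax(base_mean, 1e-8))
  resid <- la - trend
  # approximate sampling variance of a log-dispersion ML estimate
  samp_var <- 2 / pmax(n_samples - 2, 1)
  prior_var <- max(stats::var(resid[lm_ok]) - samp_var, 0.04)
  w <- prior_var / (prior_var + samp_var)  # weight on the gene-wise estimate
  exp(trend + w * resid)
}

#' Negative-binomial Wald differential expression test
#'
#' Two-group NB test in the DESeq2 mold, implemented directly: counts are
#' normalized with median-of-ratios [size_factors()]; each gene's dispersion
#' is estimated by Cox-Reid adjusted profile maximum likelihood and shrunk
#' toward a log-linear mean-dispersion trend; group means are fitted by
#' maximum likelihood with size-factor offsets; and the group log2 fold
#' change is tested with a Wald statistic whose standard error comes from
#' the expected Fisher information, referred to a Student-t distribution
#' with residual degrees of freedom (n1 + n2 - 2) — the plug-in dispersion
#' makes the usual normal reference anticonservative at the sample sizes of
#' a biopsy study. Benjamini-Hochberg q-values are computed
#' across tested genes. No fold-change shrinkage is applied. Genes with zero
#' counts in every sample are excluded from testing (NA p and q).
#'
#' @param counts A counts [expression_matrix()].
#' @param scheme A [grouping_scheme()] (or list with `ref_ids`, `trt_ids`).
#' @param config A [pipeline_config()]; `deg_q_cutoff` sets the DEG call.
#' @param genes Optional character vector restricting testing to a gene panel
#'   (e.g. the expressed set); other genes are dropped from the result.
#' @param shrink_disp Shrink dispersions toward the trend (default TRUE).
#' @return Data frame of class `"de_result"`: `gene_id`, `base_mean`,
#'   `log2fc` (treatment over reference), `se`, `stat`, `p`, `q`, `is_deg`,
#'   `direction` (`"up"`/`"down"`, DEGs only), `reliable` (NA until
#'   [reliability_filter()] is applied).
#' @export
nb_wald_test <- function(counts, scheme, config = pipeline_config(),
                         genes = NULL, shrink_disp = TRUE) {
  if (matrix_unit(counts) != "counts") stop("nb_wald_test needs counts")
  ids <- c(scheme$ref_ids, scheme$trt_ids)
  missing <- setdiff(ids, colnames(counts))
  if (length(missing) > 0) stop("samples absent from counts: ",
                                paste(missing, collapse = ", "))
  if (length(scheme$ref_ids) < 2 || length(scheme$trt_ids) < 2) {
    stop("each group needs >= 2 samples")
  }
  x <- unclass(counts)[, ids, drop = FALSE]
  if (!is.null(genes)) x <- x[intersect(rownames(x), genes), , drop = FALSE]
  sf <- size_factors(x)
  sa <- sf[scheme$ref_ids]
  sb <- sf[scheme$trt_ids]

  norm <- sweep(x, 2, sf, "/")
  base_mean <- rowMeans(norm)
  testable <- rowSums(x) > 0
  Ya <- x[testable, scheme$ref_ids, drop = FALSE]
  Yb <- x[testable, scheme$trt_ids, drop = FALSE]

  alpha_gw <- estimate_dispersion_grid(Ya, Yb, sa, sb)
  alpha <- if (shrink_disp) {
    shrink_dispersion(alpha_gw, base_mean[testable], ncol(Ya) + ncol(Yb))
  } else {
    alpha_gw
  }
  fa <- nb_fit_group(Ya, sa, alpha)
  fb <- nb_fit_group(Yb, sb, alpha)
  beta <- fb$eta - fa$eta            # natural-log fold change, trt over ref
  se <- sqrt(1 / fa$info + 1 / fb$info)
  stat <- beta / se
  # t reference with residual df: the plug-in dispersion makes the normal
  # reference anticonservative at biopsy-study sample sizes
  df <- ncol(Ya) + ncol(Yb) - 2L
  p <- 2 * stats::pt(-abs(stat), df = df)
  q <- stats::p.adjust(p, method = "BH")

  out <- data.frame(
    gene_id = rownames(x),
    base_mean = base_mean,
    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
    p = NA_real_, q = NA_real_,
    dispersion = NA_real_,
    stringsAsFactors = FALSE
  )
  out$log2fc[testable] <- beta / log(2)
  out$se[testable] <- se / log(2)
  out$stat[testable] <- stat
  out$p[testable] <- p
  out$q[testable] <- q
  out$dispersion[testable] <- alpha
  out$is_deg <- !is.na(out$q) & out$q < config$deg_q_cutoff
  out$direction <- ifelse(out$is_deg,
                          ifelse(out$log2fc > 0, "up", "down"),
                          NA_character_)
  if (any(out$is_deg & out$log2fc == 0, na.rm = TRUE)) {
    warning("DEG with zero log2 fold change encountered")
  }
  out$reliable <- NA
  attr(out, "scheme") <- scheme
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Z-score reliability filter for DEGs
#'
#' Flags as reliable the DEGs whose expression is consistent across the
#' individual blastocysts within each group: per gene, TPM (on log2(TPM+1)
#' by default) is standardized to Z-scores across all samples of the
#' compartment, and the DEG is reliable when the within-group SD of those
#' Z-scores is strictly below `reliability_max_dev` (default 0.5) in both
#' groups. The alternative reading of the published filter — the gap between
#' the two group means of the Z-scores being below the threshold — is
#' available as `method = "between_gap"` but is not the default.
#'
#' @param tpm A TPM [expression_matrix()].
#' @param de A [nb_wald_test()] result.
#' @param scheme The [grouping_scheme()] used for the test.
#' @param config A [pipeline_config()].
#' @param method `"within_sd"` (default) or `"between_gap"`.
#' @param log_transform Standardize log2(TPM+1) instead of raw TPM
#'   (default TRUE).
#' @param all_sample_ids Samples defining the Z-score panel; defaults to the
#'   scheme's compartment samples present in `tpm`.
#' @return `de` with the `reliable` column filled for DEGs (FALSE when a
#'   group has fewer than 2 samples).
#' @export
reliability_filter <- function(tpm, de, scheme, config = pipeline_config(),
                               method = c("within_sd", "between_gap"),
                               log_transform = TRUE,
                               all_sample_ids = NULL) {
  method <- match.arg(method)
  if (matrix_unit(tpm) != "TPM") stop("reliability_filter needs TPM")
  if (is.null(all_sample_ids)) {
    all_sample_ids <- intersect(colnames(tpm),
                                c(scheme$ref_ids, scheme$trt_ids))
  }
  x <- unclass(tpm)[, all_sample_ids, drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  deg_ids <- de$gene_id[de$is_deg]
  missing <- setdiff(deg_ids, rownames(x))
  if (length(missing) > 0) stop("DEG absent from TPM matrix: ", missing[[1]])
  de$reliable <- NA
  if (length(deg_ids) == 0) return(de)
  if (length(scheme$ref_ids) < 2 || length(scheme$trt_ids) < 2) {
    warning("a group has < 2 samples; SD undefined, DEGs marked unreliable")
    de$reliable[de$is_deg] <- FALSE
    return(de)
  }
  sub <- x[deg_ids, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv == 0, 1, sdv)  # constant gene -> all z = 0
  za <- z[, intersect(colnames(z), scheme$ref_ids), drop = FALSE]
  zb <- z[, intersect(colnames(z), scheme$trt_ids), drop = FALSE]
  if (method == "within_sd") {
    dev_a <- apply(za, 1, stats::sd)
    dev_b <- apply(zb, 1, stats::sd)
    ok <- dev_a < config$reliability_max_dev &
      dev_b < config$reliability_max_dev
  } else {
    ok <- abs(rowMeans(za) - rowMeans(zb)) < config$reliability_max_dev
  }
  de$reliable[match(deg_ids, de$gene_id)] <- unname(ok)
  de
}

#' Split DEGs by direction
#'
#' @param de A `"de_result"` data frame.
#' @return List `up`, `down`: gene id vectors partitioning the DEGs by the
#'   sign of their log2 fold change relative to the reference group.
#' @export
direction_split <- function(de) {
  degs <- de[de$is_deg, , drop = FALSE]
  list(up = degs$gene_id[degs$log2fc > 0],
       down = degs$gene_id[degs$log2fc < 0])
}

#' Intersect two DEG sets
#'
#' Genes called DEG in both comparisons (e.g. expectation-of-pregnancy vs
#' Gardner-score regrouping of the same compartment), optionally requiring
#' the same direction in both.
#'
#' @param primary,secondary `"de_result"` data frames from the same
#'   compartment.
#' @param match_direction Require the log2 fold changes to share a sign.
#' @return Data frame `gene_id`, `direction_primary`, `direction_secondary`.
#' @export
intersect_deg_sets <- function(primary, secondary, match_direction = FALSE) {
  a <- primary[primary$is_deg, c("gene_id", "direction"), drop = FALSE]
  b <- secondary[secondary$is_deg, c("gene_id", "direction"), drop = FALSE]
  common <- merge(a, b, by = "gene_id", suffixes = c("_primary", "_secondary"))
  if (match_direction && nrow(common) > 0) {
    common <- common[common$direction_primary == common$direction_secondary, ,
                     drop = FALSE]
  }
  rownames(common) <- NULL
  names(common) <- c("gene_id", "direction_primary", "direction_secondary")
  common[order(common$gene_id), , drop = FALSE]
}
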