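#' Classify blastocysts by growth kinetics
#'
#' Group 1 (high expectation of pregnancy): fewer than 130 h post-insemination
#' to reach a diameter greater than 170 um. Group 2 (low expectation): more
#' than 140 h while still under 180 um. Everything else is Group 3
#' (intermediate). All inequalities are strict, so boundary values fall to
#' Group 3; Group 1 and Group 2 are disjoint because the time windows are.
#'
#' @param hours Hours post-insemination to reach the blastocyst stage
#'   (vectorized).
#' @param diameter Blastocyst diameter in um (vectorized).
#' @param config A [pipeline_config()].
#' @return Character vector `"Group1"`, `"Group2"` or `"Group3"`.
#' @export
classify_growth <- function(hours, diameter, config = pipeline_config()) {
  if (length(hours) != length(diameter)) stop("hours and diameter lengths differ")
  if (anyNA(hours) || anyNA(diameter)) stop("hours/diameter must not be NA")
  if (any(hours <= 0) || any(diameter <= 0)) {
    stop("hours and diameter must be strictly positive")
  }
  out <- rep("Group3", length(hours))
  out[hours < config$group1_max_hours &
        diameter > config$group1_min_diameter_um] <- "Group1"
  out[hours > config$group2_min_hours &
        diameter < config$group2_max_diameter_um] <- "Group2"
  out
}

#' Parse a Gardner score string
#'
#' A Gardner score is an expansion digit 1-6 followed, for expanded
#' blastocysts, by an ICM grade letter and a TE grade letter (A best, C
#' worst), e.g. `"4BB"`. Expansion-only strings (e.g. `"2"`) are allowed with
#' absent grades.
#'
#' @param score Score string.
#' @return List of class `"gardner_score"` with `expansion`, `icm_grade`,
#'   `te_grade` (grades NA when absent).
#' @export
parse_gardner <- function(score) {
  if (length(score) != 1 || is.na(score) || !nzchar(score)) {
    stop("gardner score must be a non-empty string")
  }
  if (grepl("^[1-6]$", score)) {
    out <- list(expansion = as.integer(score),
                icm_grade = NA_character_, te_grade = NA_character_)
  } else if (grepl("^[1-6][ABC][ABC]$", score)) {
    out <- list(expansion = as.integer(substr(score, 1, 1)),
                icm_grade = substr(score, 2, 2),
                te_grade = substr(score, 3, 3))
  } else {
    stop("malformed Gardner score: '", score, "'")
  }
  class(out) <- "gardner_score"
  out
}

#' Gardner-score quality group
#'
#' Blastocysts graded BB or better on both the ICM and TE letters form the
#' "good" group; any C grade makes the blastocyst "poor".
#'
#' @param score A `"gardner_score"` or a score string.
#' @return `"good"` or `"poor"`.
#' @export
grade_group <- function(score) {
  if (is.character(score)) score <- parse_gardner(score)
  stopifnot(inherits(score, "gardner_score"))
  if (is.na(score$icm_grade) || is.na(score$te_grade)) {
    stop("cannot grade a score without ICM/TE letters")
  }
  if (score$icm_grade %in% c("A", "B") && score$te_grade %in% c("A", "B")) {
    "good"
  } else {
    "poor"
  }
}

#' Maternal-age group
#'
#' Younger than the cutoff (default 35 years) is "young"; the cutoff itself
#' and older is "elder".
#'
#' @param age_years Maternal age at oocyte retrieval, years.
#' @param config A [pipeline_config()].
#' @return `"young"` or `"elder"`.
#' @export
age_group <- function(age_years, config = pipeline_config()) {
  if (length(age_years) != 1 || is.na(age_years)) stop("age must be a scalar")
  if (age_years < 15 || age_years > 60) {
    stop("maternal age out of plausible bounds [15, 60]: ", age_years)
  }
  if (age_years < config$age_cutoff_years) "young" else "elder"
}

#' Chi-square contingency analysis of pregnancy rates
#'
#' Builds the group-by-outcome (pregnant / not pregnant) table from a cohort
#' of transfer records classified by [classify_growth()], runs the overall
#' Pearson chi-square test (no continuity correction by default, matching the
#' plain chi-square reported clinically) and all pairwise 2x2 chi-squares
#' with a Bonferroni factor equal to the number of pairs.
#'
#' @param records A [simulate_cohort()]-style data frame with
#'   `hours_to_blastocyst`, `diameter_um`, `gs_confirmed`; or pass `table`
#'   directly.
#' @param config A [pipeline_config()]; `significance_alpha` sets the
#'   significance call.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @param table Optional pre-built counts matrix (groups x 2, columns
#'   pregnant / not pregnant) overriding `records`.
#' @return List of class `"contingency_result"`: `table`, `rates`,
#'   `overall_chi2`, `overall_df`, `overall_p`, and `pairwise` (data frame
#'   with chi2, raw p, Bonferroni-adjusted p, significance flag).
#' @export
contingency_analysis <- function(records = NULL, config = pipeline_config(),
                                 correct = FALSE, table = NULL) {
  if (is.null(table)) {
    if (is.null(records)) stop("supply records or table")
    grp <- classify_growth(records$hours_to_blastocyst, records$diameter_um,
                           config)
    preg <- as.logical(records$gs_confirmed)
    groups <- sort(unique(grp))
    table <- t(vapply(groups, function(g) {
      c(pregnant = sum(preg[grp == g]), not_pregnant = sum(!preg[grp == g]))
    }, numeric(2)))
  } else {
    table <- as.matrix(table)
    if (ncol(table) != 2) stop("table must have 2 outcome columns")
    if (any(table < 0) || any(table != round(table))) {
      stop("table counts must be non-negative integers")
    }
    if (is.null(rownames(table))) {
      rownames(table) <- paste0("Group", seq_len(nrow(table)))
    }
    colnames(table) <- c("pregnant", "not_pregnant")
  }
  empty <- rowSums(table) == 0
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(rownames(table)[empty], collapse = ", "))
    table <- table[!empty, , drop = FALSE]
  }
  if (nrow(table) < 2) stop("need at least 2 non-empty groups")

  overall <- safe_chisq(table, correct = correct)
  pairs <- utils::combn(rownames(table), 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    sub <- table[pairs[, k], , drop = FALSE]
    res <- safe_chisq(sub, correct = correct)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               chi2 = res$statistic, p = res$p,
               p_bonferroni = min(1, res$p * n_pairs),
               stringsAsFactors = FALSE)
  }))
  pw$significant <- pw$p_bonferroni < config$significance_alpha
  out <- list(
    table = table,
    rates = table[, "pregnant"] / rowSums(table),
    overall_chi2 = overall$statistic,
    overall_df = overall$df,
    overall_p = overall$p,
    significant = overall$p < config$significance_alpha,
    pairwise = pw
  )
  class(out) <- "contingency_result"
  out
}

# chisq.test wrapper handling zero-variance tables (an outcome column of all
# zeros): chi2 is degenerate there, reported as 0 with p = 1
safe_chisq <- function(tab, correct = FALSE) {
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate contingency table (zero-variance margin); p set to 1")
    return(list(statistic = 0, df = NA_real_, p = 1))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pregnancy-rate contingency analysis\n")
  tab <- cbind(x$table, rate = round(100 * x$rates, 1))
  print(tab)
  cat(sprintf("Overall chi-square = %.3f (df = %s), p = %.3g\n",
              x$overall_chi2, format(x$overall_df), x$overall_p))
  cat("Pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
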