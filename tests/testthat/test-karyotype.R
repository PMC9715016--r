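cfg <- pipeline_config()

tpm_with_markers <- function(marker_tpm, samples = "s1") {
  ann <- tiny_annotation()
  m <- matrix(10, nrow(ann), length(samples),
              dimnames = list(ann$gene_id, samples))
  m[ann$gene_id[ann$is_y_marker], ] <- marker_tpm
  m <- rbind(m, filler = 1e6 - colSums(m))
  expression_matrix(m, "TPM")
}

test_that("Y detection applies the strict summed-TPM threshold", {
  expect_true(detect_y(tpm_with_markers(c(100, 100, 60)),
                       tiny_annotation(), cfg)[[1]])   # sum 260 > 250
  expect_false(detect_y(tpm_with_markers(c(100, 100, 50)),
                        tiny_annotation(), cfg)[[1]])  # sum exactly 250
  expect_false(detect_y(tpm_with_markers(c(0, 0, 0)),
                        tiny_annotation(), cfg)[[1]])
  # a missing marker gene is a hard error naming it
  ann <- tiny_annotation()
  keep <- setdiff(ann$gene_id, "ym2")
  m <- matrix(10, length(keep), 1, dimnames = list(keep, "s1"))
  m <- rbind(m, filler = 1e6 - colSums(m))
  expect_error(detect_y(expression_matrix(m, "TPM"), ann, cfg), "ym2")
})

test_that("chromosome signal is depth-normalized and excludes PAR from X", {
  ann <- tiny_annotation()
  md <- tiny_metadata(2)
  counts <- random_counts(ann$gene_id, md$sample_id, seed = 31)
  expressed <- list(genes = ann$gene_id, min_tpm = 1, min_samples = 1L,
                    scope = "all", n_samples = 4L)
  class(expressed) <- "expressed_set"
  sig <- chromosome_signal(counts, ann, expressed)
  # direct arithmetic for one sample
  s <- md$sample_id[[1]]
  x <- unclass(counts)[, s]
  depth <- sum(x)
  expect_equal(sig[s, "1"], 1e6 * (x[["a1"]] + x[["a2"]]) / depth)
  # PAR gene xp does not contribute to X
  expect_equal(sig[s, "X"], 1e6 * (x[["x1"]] + x[["x2"]]) / depth)
  # doubling a sample's counts leaves its signal unchanged
  doubled <- unclass(counts)
  doubled[, s] <- doubled[, s] * 2L
  sig2 <- chromosome_signal(expression_matrix(doubled, "counts"), ann, expressed)
  expect_equal(sig2[s, ], sig[s, ])
  # one chromosome holding all expressed genes has signal 1e6
  only1 <- expressed
  only1$genes <- c("a1", "a2")
  expect_warning(sig3 <- chromosome_signal(counts, ann, only1),
                 "no expressed genes")
  expect_equal(unname(sig3[, "1"]), rep(1e6, 4))
})

test_that("signals and z-scores match brute-force loop oracles", {
  set.seed(41)
  for (rep in 1:5) {
    n_genes <- sample(20:50, 1)
    n_samp <- sample(c(6, 8), 1)
    chrom <- sample(c("1", "2", "3", "X"), n_genes, replace = TRUE)
    ann <- gene_annotation(data.frame(
      gene_id = paste0("g", seq_len(n_genes)), chromosome = chrom,
      length_bp = 1000L,
      is_par = chrom == "X" & stats::runif(n_genes) < 0.2,
      is_y_marker = FALSE))
    md <- tiny_metadata(n_samp / 2)
    counts <- random_counts(ann$gene_id, md$sample_id, seed = rep * 100)
    panel <- sample(ann$gene_id, round(n_genes * 0.8))
    expressed <- structure(list(genes = panel, min_tpm = 1, min_samples = 1L,
                                scope = "all", n_samples = n_samp),
                           class = "expressed_set")
    sig <- chromosome_signal(counts, ann, expressed)
    osig <- oracle_signal(unclass(counts), as.data.frame(ann), panel)
    expect_equal(sig[, colnames(osig)], osig[rownames(sig), colnames(osig)],
                 tolerance = 1e-10)
    z <- zscores_by_compartment(sig, md)
    oz <- oracle_zscores(sig, md$compartment[match(rownames(sig), md$sample_id)])
    expect_equal(z[, , drop = FALSE], oz, tolerance = 1e-10,
                 ignore_attr = "zero_variance")
  }
})

test_that("z-scores match the hand-worked example and standardize exactly", {
  md <- tiny_metadata(4)
  icm <- md$sample_id[md$compartment == "ICM"]
  sig <- matrix(0, 8, 2, dimnames = list(md$sample_id, c("1", "2")))
  sig[icm, "1"] <- c(10, 10, 10, 14)  # mean 11, sample SD 2
  sig[md$compartment == "TE", "1"] <- c(5, 6, 7, 8)
  sig[, "2"] <- 7  # constant -> zero variance
  z <- zscores_by_compartment(sig, md)
  expect_equal(unname(z[icm, "1"]), c(-0.5, -0.5, -0.5, 1.5))
  expect_equal(unname(z[, "2"]), rep(0, 8))
  expect_true(any(grepl(":2$", attr(z, "zero_variance"))))
  # standardization identity per compartment/chromosome
  expect_equal(mean(z[icm, "1"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z[icm, "1"]), 1, tolerance = 1e-12)
  expect_error(zscores_by_compartment(sig[1:5, ], md), ">= 3 samples")
})

test_that("autosome calls use strict cutoffs and warn at tiny n", {
  z <- matrix(c(2.5, -2.5, 2.0, -2.0, 1.99, 0),
              nrow = 6, ncol = 1, dimnames = list(paste0("s", 1:6), "7"))
  calls <- call_autosomes(z, cfg)
  expect_equal(calls$call, c("gain", "loss", "euploid", "euploid",
                             "euploid", "euploid"))
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:6),
    blastocyst_id = paste0("B", rep(1:3, each = 2)),
    compartment = rep(c("ICM", "TE"), 3)))
  expect_warning(call_autosomes(z, cfg, md), "unattainable")
})

test_that("sex calls follow the Y/X decision rules", {
  md <- tiny_metadata(4)
  y <- setNames(c(TRUE, TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                md$sample_id)
  xz <- setNames(c(-1, -0.9,  1.1, 0.9,  0.1, -0.2,  0.3, 0.4),
                 md$sample_id)
  calls <- call_sex(y, xz, md, cfg)
  expect_equal(calls$sex[calls$blastocyst_id == "B1"], "XY")
  expect_equal(calls$sex[calls$blastocyst_id == "B2"], "XX")
  expect_equal(calls$sex[calls$blastocyst_id == "B3"], "potential_XO")
  expect_equal(calls$sex[calls$blastocyst_id == "B4"], "discordant")
  # a blastocyst missing a compartment is skipped with a warning
  md_missing <- sample_metadata(rbind(as.data.frame(md),
    data.frame(sample_id = "B5_ICM", blastocyst_id = "B5",
               compartment = "ICM", expectation_group = NA,
               maternal_age = NA, gardner_score = NA)))
  expect_warning(call_sex(y, xz, md_missing, cfg), "B5")
})

test_that("the karyotype report aggregates events with concordance flags", {
  md <- tiny_metadata(2)
  calls <- data.frame(
    sample_id = rep(md$sample_id, each = 2),
    chromosome = rep(c("7", "16"), 4),
    z = 0, call = "euploid", stringsAsFactors = FALSE)
  # gain on chr16 in B1 TE only
  calls$call[calls$sample_id == "B1_TE" & calls$chromosome == "16"] <- "gain"
  sex <- data.frame(blastocyst_id = c("B1", "B2"),
                    sex = c("XX", "XY"), stringsAsFactors = FALSE)
  rep1 <- karyotype_report(calls, sex, md)
  expect_equal(rep1$n_events[rep1$blastocyst_id == "B1"], 1)
  expect_match(rep1$events[rep1$blastocyst_id == "B1"],
               "TE:chr16:gain\\[discordant\\]")
  expect_equal(rep1$events[rep1$blastocyst_id == "B2"], "")
  # report round-trips through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rep1, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  expect_equal(back$events, rep1$events)
  expect_equal(back$n_events, rep1$n_events)
})

test_that("z-scores are invariant to per-sample depth scaling", {
  d <- sim_design(n_blastocysts_per_group = c(H = 2L, M = 2L, L = 2L),
                  genes_per_chromosome = 20L, seed = 5L)
  ann <- make_annotation(d)
  sim <- simulate_counts(d, ann)
  tpm <- tpm_from_counts(sim$counts, ann)
  es <- expressed_gene_set(tpm, sim$metadata)
  sig1 <- chromosome_signal(sim$counts, ann, es)
  scaled <- unclass(sim$counts)
  scaled[, 3] <- scaled[, 3] * 7L
  sig2 <- chromosome_signal(expression_matrix(scaled, "counts"), ann, es)
  z1 <- zscores_by_compartment(sig1, sim$metadata)
  z2 <- zscores_by_compartment(sig2, sim$metadata)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("planted aneuploidy and sex are recovered end to end", {
  ev <- data.frame(blastocyst_id = c("H2", "L3"),
                   compartment = c("both", "both"),
                   chromosome = c("16", "9"),
                   event = c("gain", "loss"))
  d <- sim_design(genes_per_chromosome = 200L, ploidy_events = ev, seed = 77L)
  ann <- make_annotation(d)
  sim <- simulate_counts(d, ann)
  tpm <- tpm_from_counts(sim$counts, ann)
  k <- digital_karyotype(sim$counts, tpm, ann, sim$metadata)
  gains <- k$calls[k$calls$call == "gain", ]
  losses <- k$calls[k$calls$call == "loss", ]
  h2 <- sim$metadata$sample_id[sim$metadata$blastocyst_id == "H2"]
  l3 <- sim$metadata$sample_id[sim$metadata$blastocyst_id == "L3"]
  expect_true(all(h2 %in% gains$sample_id[gains$chromosome == "16"]))
  expect_true(all(l3 %in% losses$sample_id[losses$chromosome == "9"]))
  sex_truth <- sim$truth$sex[k$sex$blastocyst_id]
  called <- k$sex$sex
  expect_equal(called[sex_truth == "XY"],
               rep("XY", sum(sex_truth == "XY")))
  expect_equal(called[sex_truth == "XX"],
               rep("XX", sum(sex_truth == "XX")))
  expect_equal(called[sex_truth == "XO"], "potential_XO")
})
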