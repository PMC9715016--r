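cfg <- pipeline_config()

two_group_scheme <- function(n_ref = 4, n_trt = 5) {
  list(name = "expectation", compartment = "ICM",
       reference = "L", treatment = "H",
       ref_ids = paste0("L", seq_len(n_ref)),
       trt_ids = paste0("H", seq_len(n_trt)))
}

sim_two_group <- function(G = 500, n_ref = 4, n_trt = 5, seed = 1,
                          lfc_genes = integer(0), lfc = 0, size = 10) {
  set.seed(seed)
  mu <- 2^rnorm(G, 5, 1.5)
  M <- matrix(rep(mu, n_ref + n_trt), G, n_ref + n_trt)
  if (length(lfc_genes) > 0) {
    M[lfc_genes, n_ref + seq_len(n_trt)] <-
      M[lfc_genes, n_ref + seq_len(n_trt)] * 2^lfc
  }
  x <- matrix(rnbinom(length(M), mu = M, size = size), G, n_ref + n_trt,
              dimnames = list(paste0("g", seq_len(G)),
                              c(paste0("L", seq_len(n_ref)),
                                paste0("H", seq_len(n_trt)))))
  expression_matrix(x, "counts")
}

test_that("size factors obey the median-of-ratios contract", {
  x <- matrix(c(10, 100, 4, 20, 200, 8), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(expression_matrix(x, "counts"))
  # all per-gene ratios are 2 -> factors in ratio 1:2
  expect_equal(unname(sf[["s2"]] / sf[["s1"]]), 2)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  same <- matrix(rep(c(5, 9, 30), 3), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(expression_matrix(same, "counts"))),
               rep(1, 3))

  counts <- random_counts(paste0("g", 1:50), paste0("s", 1:4), seed = 2)
  doubled <- unclass(counts)
  doubled[, 2] <- doubled[, 2] * 2L
  sf2 <- size_factors(expression_matrix(doubled, "counts"))
  base <- size_factors(counts)
  expect_equal(unname(sf2[["s2"]] / sf2[["s1"]]),
               unname(2 * base[["s2"]] / base[["s1"]]), tolerance = 1e-10)
  # gene-order invariance
  perm <- sample(50)
  expect_equal(size_factors(expression_matrix(unclass(counts)[perm, ], "counts")),
               base)
  # no all-positive gene: fall back with warning
  sparse <- unclass(counts)
  sparse[cbind(seq_len(50), rep_len(1:4, 50))] <- 0L
  expect_warning(size_factors(expression_matrix(sparse, "counts")),
                 "positive-subset")
})

test_that("BH q-values match the brute-force oracle exactly", {
  set.seed(12)
  for (m in c(1, 10, 1000)) {
    p <- runif(m)
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  # and inside the test output
  counts <- sim_two_group(G = 200, seed = 3)
  de <- nb_wald_test(counts, two_group_scheme(), cfg)
  tested <- !is.na(de$p)
  expect_equal(de$q[tested], oracle_bh(de$p[tested]))
})

test_that("the NB Wald test is calibrated under the null", {
  fracs <- numeric(5)
  for (s in 1:5) {
    counts <- sim_two_group(G = 2000, seed = 100 + s)
    de <- nb_wald_test(counts, two_group_scheme(), cfg)
    fracs[s] <- mean(de$q < cfg$deg_q_cutoff, na.rm = TRUE)
  }
  expect_lte(mean(fracs), 0.02)
})

test_that("raw null p-values are close to uniform", {
  ks <- numeric(8)
  for (s in 1:8) {
    counts <- sim_two_group(G = 2000, seed = 300 + s)
    de <- nb_wald_test(counts, two_group_scheme(), cfg)
    p <- de$p[!is.na(de$p)]
    ks[s] <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  }
  expect_lt(stats::median(ks), 0.05)
})

test_that("planted fold changes are recovered and scale monotonically", {
  planted <- 1:100
  counts <- sim_two_group(G = 2000, seed = 9, lfc_genes = planted, lfc = 2)
  de <- nb_wald_test(counts, two_group_scheme(), cfg)
  expect_lt(abs(stats::median(de$log2fc[planted]) - 2), 0.3)
  expect_gt(stats::median(abs(de$stat[planted]), na.rm = TRUE),
            stats::median(abs(de$stat[-planted]), na.rm = TRUE))
  # discoveries never decrease (in mean) as the planted effect grows
  n_disc <- vapply(c(1, 2, 4), function(l) {
    hits <- 0
    for (s in 1:3) {
      cm <- sim_two_group(G = 1000, seed = 40 + s, lfc_genes = 1:80, lfc = l)
      d <- nb_wald_test(cm, two_group_scheme(), cfg)
      hits <- hits + sum(d$is_deg, na.rm = TRUE)
    }
    hits / 3
  }, numeric(1))
  expect_true(all(diff(n_disc) >= 0))
  # all-zero genes are excluded from testing
  x <- unclass(counts)
  x[1:5, ] <- 0L
  de0 <- nb_wald_test(expression_matrix(x, "counts"), two_group_scheme(), cfg)
  expect_true(all(is.na(de0$p[1:5])))
  expect_true(all(is.na(de0$q[1:5])))
})

test_that("the NB test tracks DESeq2 on a shared dataset", {
  skip_if_not_installed("DESeq2")
  planted <- 1:40
  counts <- sim_two_group(G = 400, seed = 21, lfc_genes = planted, lfc = 2)
  sch <- two_group_scheme()
  de <- nb_wald_test(counts, sch, cfg)
  coldata <- data.frame(group = factor(rep(c("L", "H"), c(4, 5)),
                                       levels = c("L", "H")))
  dds <- DESeq2::DESeqDataSetFromMatrix(unclass(counts), coldata, ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(de$log2fc) & !is.na(res$log2FoldChange) & de$base_mean > 5
  expect_gt(stats::cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.95)
  expect_gt(stats::cor(rank(de$p[ok]), rank(res$pvalue[ok])), 0.9)
  expect_lt(stats::median(abs(de$log2fc[planted] -
                                res$log2FoldChange[planted])), 0.5)
})

test_that("the reliability filter measures within-group z-score spread", {
  # 9 samples: 4 reference (L), 5 treatment (H)
  samples <- c(paste0("L", 1:4), paste0("H", 1:5))
  sch <- two_group_scheme()
  build_tpm <- function(gene_vals) {
    m <- rbind(gene_vals, matrix(100, 3, 9))
    rownames(m) <- c("focus", paste0("f", 1:3))
    colnames(m) <- samples
    m <- rbind(m, rest = 1e6 - colSums(m))
    expression_matrix(m, "TPM")
  }
  fake_de <- function() {
    data.frame(gene_id = "focus", base_mean = 100, log2fc = 2, se = 0.1,
               stat = 5, p = 1e-6, q = 1e-5, dispersion = 0.1,
               is_deg = TRUE, direction = "up", reliable = NA,
               stringsAsFactors = FALSE)
  }
  # constant within each group: within-group SDs are 0 -> reliable
  tpm <- build_tpm(c(rep(10, 4), rep(40, 5)))
  out <- reliability_filter(tpm, fake_de(), sch, cfg)
  expect_true(out$reliable[[1]])

  # constructed gene with large within-group spread -> unreliable;
  # oracle: hand-computed z-scores of log2(TPM+1) across the 9 samples
  vals <- c(5, 300, 10, 150, 30, 35, 500, 8, 60)
  lt <- log2(vals + 1)
  z <- (lt - mean(lt)) / stats::sd(lt)
  expect_gt(stats::sd(z[1:4]), 1)  # group A deviation clearly above 1
  out2 <- reliability_filter(build_tpm(vals), fake_de(), sch, cfg)
  expect_false(out2$reliable[[1]])

  # SD exactly at the threshold is unreliable (strict <): construct a gene
  # whose group-H z-scores have SD exactly 0.5 by solving on the z scale
  target <- function(spread) {
    lt <- c(rep(1, 4), 8 + spread * c(-2, -1, 0, 1, 2))
    vals <- 2^lt - 1
    tpm <- build_tpm(vals)
    zz <- scale(log2(vals + 1))[, 1]
    list(tpm = tpm, sd_h = stats::sd(zz[5:9]))
  }
  f <- function(s) target(s)$sd_h - 0.5
  s_star <- stats::uniroot(f, c(0.01, 3), tol = 1e-12)$root
  at <- target(s_star)
  expect_equal(at$sd_h, 0.5, tolerance = 1e-9)
  out3 <- reliability_filter(at$tpm, fake_de(), sch, cfg)
  expect_false(out3$reliable[[1]])
})

test_that("direction split partitions DEGs and intersections respect direction", {
  de <- data.frame(
    gene_id = paste0("g", 1:6),
    base_mean = 10, log2fc = c(1.3, -0.8, 2, -2, 0.5, -0.1),
    se = 1, stat = 1, p = 0.001, q = c(0.001, 0.001, 0.001, 0.001, 0.5, 0.5),
    dispersion = 0.1, stringsAsFactors = FALSE)
  de$is_deg <- de$q < 0.01
  de$direction <- ifelse(de$is_deg, ifelse(de$log2fc > 0, "up", "down"), NA)
  de$reliable <- NA
  split <- direction_split(de)
  expect_setequal(split$up, c("g1", "g3"))
  expect_setequal(split$down, c("g2", "g4"))
  expect_setequal(c(split$up, split$down), de$gene_id[de$is_deg])

  other <- de
  other$log2fc <- -other$log2fc
  other$direction <- ifelse(other$is_deg,
                            ifelse(other$log2fc > 0, "up", "down"), NA)
  expect_equal(nrow(intersect_deg_sets(de, other, match_direction = TRUE)), 0)
  expect_equal(intersect_deg_sets(de, other, match_direction = FALSE)$gene_id,
               sort(de$gene_id[de$is_deg]))
  expect_equal(intersect_deg_sets(de, de, match_direction = TRUE)$gene_id,
               sort(de$gene_id[de$is_deg]))
  none <- de
  none$is_deg <- FALSE
  expect_equal(nrow(intersect_deg_sets(de, none)), 0)
})

test_that("grouping schemes pick the published group memberships", {
  md <- table1_samples()
  sch <- grouping_scheme(md, "expectation", "ICM")
  expect_setequal(sch$trt_ids, paste0("H", 1:5, "_ICM"))
  expect_setequal(sch$ref_ids, paste0("L", 1:4, "_ICM"))
  ga <- grouping_scheme(md, "gardner", "TE")
  expect_setequal(ga$trt_ids,
                  paste0(c("H1", "H2", "H3", "H4", "H5", "M4"), "_TE"))
  ag <- grouping_scheme(md, "age", "TE")
  expect_setequal(ag$trt_ids,
                  paste0(c("H1", "H4", "H5", "M2"), "_TE"))
  expect_error(grouping_scheme(md[md$compartment == "ICM" &
                                    md$expectation_group == "H", ],
                               "expectation", "ICM"),
               ">= 2 samples")
})
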