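cfg <- pipeline_config()

test_that("growth-kinetics classification follows the strict rules", {
  expect_equal(classify_growth(125, 175, cfg), "Group1")
  expect_equal(classify_growth(150, 170, cfg), "Group2")
  # boundaries fall to Group 3 because every inequality is strict
  expect_equal(classify_growth(130, 175, cfg), "Group3")
  expect_equal(classify_growth(125, 170, cfg), "Group3")
  expect_equal(classify_growth(140, 170, cfg), "Group3")
  # between the two time windows
  expect_equal(classify_growth(135, 200, cfg), "Group3")
  expect_error(classify_growth(-1, 100, cfg), "positive")
})

test_that("growth classification partitions the plane", {
  set.seed(42)
  n <- 1e5
  hours <- runif(n, 1, 300)
  diam <- runif(n, 1, 300)
  grp <- classify_growth(hours, diam, cfg)
  expect_true(all(grp %in% c("Group1", "Group2", "Group3")))
  # Group 1 and Group 2 regions are disjoint: no point satisfies both rules
  both <- (hours < 130 & diam > 170) & (hours > 140 & diam < 180)
  expect_false(any(both))
  # rule regions agree with the vectorized classifier
  expect_equal(grp == "Group1", hours < 130 & diam > 170)
  expect_equal(grp == "Group2", hours > 140 & diam < 180)
})

test_that("Gardner scores parse and malformed scores are rejected", {
  s <- parse_gardner("4AB")
  expect_equal(s$expansion, 4L)
  expect_equal(s$icm_grade, "A")
  expect_equal(s$te_grade, "B")
  expect_equal(parse_gardner("4CB")$icm_grade, "C")
  only <- parse_gardner("2")
  expect_true(is.na(only$icm_grade))
  expect_error(parse_gardner("9AA"), "malformed.*9AA")
  expect_error(parse_gardner("4BD"), "malformed")
  expect_error(parse_gardner(""), "non-empty")
})

test_that("grade and age groups reproduce the 13-blastocyst study design", {
  expect_equal(grade_group("4BB"), "good")
  expect_equal(grade_group("4CB"), "poor")
  expect_error(grade_group("2"), "without ICM/TE letters")

  b <- table1_blastocysts()
  good <- b$blastocyst_id[vapply(b$gardner_score, grade_group, "") == "good"]
  expect_setequal(good, c("H1", "H2", "H3", "H4", "H5", "M4"))

  expect_equal(age_group(31, cfg), "young")
  expect_equal(age_group(42, cfg), "elder")
  expect_equal(age_group(35, cfg), "elder")  # cutoff itself is elder
  expect_error(age_group(12, cfg), "bounds")
  young <- b$blastocyst_id[vapply(b$maternal_age, age_group, "",
                                  config = cfg) == "young"]
  expect_setequal(young, c("H1", "H4", "H5", "M2"))
})

test_that("contingency analysis matches the brute-force chi-square oracle", {
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 80) + 1, 3, 2)
    res <- contingency_analysis(table = tab, config = cfg)
    expect_equal(res$overall_chi2, oracle_chisq(tab), tolerance = 1e-10)
    expect_equal(res$overall_p,
                 stats::pchisq(oracle_chisq(tab), df = 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("pairwise tests are Bonferroni-adjusted over the three pairs", {
  tab <- matrix(c(40, 40, 10, 60, 60, 90), 3, 2)
  res <- contingency_analysis(table = tab, config = cfg)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p * 3))
  # two identical groups: independence, chi2 = 0, p = 1
  eq <- res$pairwise[res$pairwise$group_a == "Group1" &
                       res$pairwise$group_b == "Group2", ]
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
})

test_that("degenerate and empty groups are handled", {
  all_pos <- matrix(c(10, 20, 30, 0, 0, 0), 3, 2)
  expect_warning(res <- contingency_analysis(table = all_pos, config = cfg),
                 "degenerate")
  expect_equal(res$overall_p, 1)
  with_empty <- matrix(c(10, 0, 30, 5, 0, 10), 3, 2)
  expect_warning(res2 <- contingency_analysis(table = with_empty, config = cfg),
                 "empty group")
  expect_equal(nrow(res2$table), 2)
  one_left <- matrix(c(10, 0, 5, 0), 2, 2)
  expect_warning(expect_error(
    contingency_analysis(table = one_left, config = cfg), "2 non-empty"))
})

test_that("cohort simulation lands in the intended rule regions", {
  co <- simulate_cohort(100, c(1, 0, 0), c(1, 0, 0), seed = 11, config = cfg)
  expect_true(all(classify_growth(co$hours_to_blastocyst, co$diameter_um,
                                  cfg) == "Group1"))
  expect_true(all(co$gs_confirmed))  # rate 1 in Group 1

  co3 <- simulate_cohort(500, c(0.3, 0.2, 0.5), c(0.6, 0.2, 0.3), seed = 2,
                         config = cfg)
  expect_equal(classify_growth(co3$hours_to_blastocyst, co3$diameter_um, cfg),
               co3$group_assigned)
  expect_error(simulate_cohort(10, c(0.5, 0.2, 0.2), c(1, 1, 1)), "sum to 1")
})

test_that("cohort empirical rates track design rates at study scale", {
  co <- simulate_cohort(1890, c(676, 158, 1056) / 1890,
                        c(0.590, 0.165, 0.342), seed = 5, config = cfg)
  grp <- classify_growth(co$hours_to_blastocyst, co$diameter_um, cfg)
  rates <- tapply(co$gs_confirmed, grp, mean)
  expect_lt(abs(rates[["Group1"]] - 0.590), 0.04)
  expect_lt(abs(rates[["Group2"]] - 0.165), 0.04)
  expect_lt(abs(rates[["Group3"]] - 0.342), 0.04)
})

test_that("group-rate recovery stays within binomial error across seeds", {
  fr <- c(676, 158, 1056) / 1890
  rates <- c(0.590, 0.165, 0.342)
  ok <- 0L
  n_seeds <- 500L
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(1890, fr, rates, seed = s, config = cfg)
    grp <- classify_growth(co$hours_to_blastocyst, co$diameter_um, cfg)
    est <- tapply(co$gs_confirmed, grp, mean)[paste0("Group", 1:3)]
    n_g <- table(grp)[paste0("Group", 1:3)]
    se <- sqrt(rates * (1 - rates) / as.numeric(n_g))
    if (all(abs(est - rates) <= 3 * se)) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.99)
})
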