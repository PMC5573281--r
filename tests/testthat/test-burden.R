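test_that("the chisq method reproduces the classical equal-proportions test exactly", {
  set.seed(1)
  for (i in 1:200) {
    n1 <- sample(20:5000, 1)
    n2 <- sample(1e4:1e5, 1)
    x1 <- rbinom(1, n1, runif(1, 0, 0.1))
    x2 <- rbinom(1, n2, runif(1, 0, 0.01))
    if (x1 + x2 == 0 || x1 == n1) next
    expect_equal(
      two_proportion_test(x1, n1, x2, n2),
      suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2),
                         alternative = "greater")$p.value),
      tolerance = 1e-12)
  }
})

test_that("the flagship burden case matches its frozen values and oracles", {
  # 4 qualifying variants in 38 exomes vs 158 in 60000 reference exomes
  p_chisq <- two_proportion_test(4, 38, 158, 60000)
  expect_equal(p_chisq, suppressWarnings(
    stats::prop.test(c(4, 158), c(38, 60000), alternative = "greater")$p.value))
  expect_equal(p_chisq, 1.109e-26, tolerance = 1e-3)

  # exact binomial tails at the pooled and at the reference rate
  p_exact <- two_proportion_test(4, 38, 158, 60000, method = "exact")
  expect_equal(p_exact, pbinom(3, 38, 162 / 60038, lower.tail = FALSE))
  expect_equal(p_exact, 3.639e-06, tolerance = 1e-3)
  expect_equal(pbinom(3, 38, 158 / 60000, lower.tail = FALSE),
               3.304e-06, tolerance = 1e-3)
})

test_that("degenerate and null configurations behave by convention", {
  expect_equal(two_proportion_test(0, 38, 0, 60000), 1)
  expect_equal(two_proportion_test(0, 38, 0, 60000, method = "exact"), 1)
  # equal underlying proportions: p near one half (continuity shifts above)
  expect_lt(abs(two_proportion_test(50, 1000, 3000, 60000) - 0.5), 0.05)
  # enrichment in the wrong direction: p near 1
  expect_gt(two_proportion_test(0, 1000, 3000, 60000), 0.9)
})

test_that("input validation rejects impossible counts", {
  expect_error(two_proportion_test(-1, 38, 0, 100), "non-negative")
  expect_error(two_proportion_test(1, 0, 0, 100), "positive")
  expect_error(two_proportion_test(40, 38, 0, 100), "exceeds")
  expect_error(two_proportion_test(NA, 38, 0, 100), "finite")
})

test_that("p is monotone non-increasing in the cohort count", {
  for (method in c("chisq", "exact")) {
    p <- two_proportion_test(0:10, 38, 30, 60000, method = method)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("the chisq approximation is anti-conservative at cohort scale", {
  # at 38 exomes and ultra-rare reference rates the normal approximation
  # understates p by far more than the documented 3x regime bound; this is
  # the motivation for method = "exact"
  p_chisq <- two_proportion_test(1, 38, 30, 60000)
  p_exact <- two_proportion_test(1, 38, 30, 60000, method = "exact")
  expect_lt(p_chisq, p_exact / 3)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- switch(sample(3, 1),
                runif(m),
                rbeta(m, 0.3, 1),
                round(runif(m), 2))  # ties
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && max(q) <= 1)
  }
})

test_that("run_burden emits one record per hit gene-group with joined reference", {
  counts <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G4"),
    group = c("restricted", "binge", "restricted", "binge"),
    count = c(4L, 1L, 2L, 3L))
  reference <- tibble::tibble(
    gene = c("G1", "G2", "G3"),
    count = c(158L, 10L, 5L),
    n_individuals = c(60000L, 55000L, 58000L))
  scan <- run_burden(counts, reference)

  rec <- tidy(scan)
  expect_equal(nrow(rec), 4)          # G3 never hit: not tested
  expect_false("G3" %in% rec$gene)
  g4 <- rec[rec$gene == "G4", ]       # missing from reference
  expect_true(g4$ref_missing)
  expect_equal(g4$x_ref, 0)
  expect_equal(g4$n_ref, 60000)
  expect_equal(rec$n_cohort[rec$group == "restricted"], c(38L, 38L))

  expect_equal(
    rec$p_value[rec$gene == "G1" & rec$group == "restricted"],
    two_proportion_test(4, 38, 158, 60000))
  # q-values recompute from within-group BH
  for (g in c("restricted", "binge")) {
    sub <- rec[rec$group == g, ]
    expect_equal(sub$q_value, bh_brute_force(sub$p_value))
  }
  expect_true(all(rec$q_value >= rec$p_value - 1e-15))
  expect_setequal(scan$significant$union,
                  union(scan$significant$restricted, scan$significant$binge))
})

test_that("pooled adjustment mode spans both groups", {
  counts <- tibble::tibble(gene = c("G1", "G2"),
                           group = c("restricted", "binge"),
                           count = c(3L, 2L))
  reference <- tibble::tibble(gene = c("G1", "G2"), count = c(20L, 20L),
                              n_individuals = c(60000L, 60000L))
  pooled <- run_burden(counts, reference, pool_groups = TRUE)
  expect_equal(tidy(pooled)$q_value,
               bh_brute_force(tidy(pooled)$p_value))
  g <- glance(pooled)
  expect_equal(g$n_tested, 2L)
})

test_that("burden scan methods produce tidy output and a plot", {
  ds <- simulate_dataset(small_config(baseline_rate = 2e-3, seed = 12))
  fr <- filter_variants(ds$variants)
  scan <- run_burden(fr$counts, ds$reference)
  expect_s3_class(tidy(scan), "tbl_df")
  expect_equal(glance(scan)$n_tested, nrow(tidy(scan)))
  expect_s3_class(autoplot(scan), "ggplot")
})
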