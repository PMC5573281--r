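test_that("published fixture rows classify as reported", {
  v <- load_table1_fixture()
  cl <- classify_variants(v)

  nts <- cl[cl$gene == "NTS", ]
  expect_true(all(nts$kept))

  pomc <- cl[cl$gene == "POMC", ]
  expect_false(pomc$kept)
  expect_equal(pomc$reasons, "known_variant")

  ucn <- cl[cl$gene == "UCN", ]
  expect_false(ucn$kept)
  expect_match(ucn$reasons, "known_variant")

  # frameshift deletion with no CADD score is retained
  ntsr1 <- cl[cl$gene == "NTSR1", ]
  expect_true(ntsr1$kept)
})

test_that("the CADD threshold is a sharp boundary and unscored handling is rule-based", {
  just_under <- toy_variant(cadd_phred = 14.99)
  at <- toy_variant(cadd_phred = 15)
  cl <- classify_variants(dplyr::bind_rows(just_under, at))
  expect_equal(cl$kept, c(FALSE, TRUE))
  expect_equal(cl$reasons[1], "cadd_below_threshold")

  unscored_fs <- toy_variant(cadd_phred = NA_real_, consequence = "frameshift")
  unscored_mis <- toy_variant(cadd_phred = NA_real_, consequence = "missense")
  cl <- classify_variants(dplyr::bind_rows(unscored_fs, unscored_mis))
  expect_equal(cl$kept, c(TRUE, FALSE))
  expect_equal(cl$reasons[2], "cadd_unscored")

  cfg_off <- filter_config(keep_unscored_truncating = FALSE)
  expect_false(classify_variants(unscored_fs, cfg_off)$kept)
})

test_that("every failed rule is enumerated and kept implies no reasons", {
  v <- toy_variant(region_class = "other", caller_filters = "QD",
                   known_in = "dbSNP", cadd_phred = 3)
  cl <- classify_variants(v)
  expect_false(cl$kept)
  expect_equal(strsplit(cl$reasons, ",")[[1]],
               c("outside_region", "caller_filter", "known_variant",
                 "cadd_below_threshold"))

  sim <- simulate_cohort(small_config(baseline_rate = 5e-3, seed = 2))
  cl <- classify_variants(sim$variants)
  expect_identical(cl$kept, cl$reasons == "")
})

test_that("missing region annotation is an error", {
  v <- toy_variant(region_class = NA_character_)
  expect_error(classify_variants(v), "annotation incomplete")
})

test_that("filtering is idempotent and the audit reconciles", {
  sim <- simulate_cohort(small_config(baseline_rate = 5e-3, seed = 8))
  fr <- filter_variants(sim$variants)
  expect_equal(fr$audit$n_input, fr$audit$n_kept + fr$audit$n_dropped)
  expect_equal(fr$audit$n_input, nrow(sim$variants))

  fr2 <- filter_variants(fr$kept)
  expect_equal(fr2$kept, fr$kept)
  expect_equal(fr2$audit$n_dropped, 0)
  expect_equal(fr2$counts, fr$counts)
})

test_that("per-rule drop proportions match the generator's mixture fractions", {
  cfg <- sim_config(n_genes = 800, n_positive_training = 40,
                    n_negative_training = 120, baseline_rate = 0.01, seed = 21)
  sim <- simulate_cohort(cfg)
  n <- nrow(sim$variants)
  expect_gt(n, 2000)
  fr <- filter_variants(sim$variants)
  by_rule <- fr$audit$dropped_by_rule

  tol <- function(p) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(by_rule$known_variant / n - cfg$known_fraction),
            tol(cfg$known_fraction))
  expect_lt(abs(by_rule$caller_filter / n - cfg$flagged_fraction),
            tol(cfg$flagged_fraction))
  expect_lt(abs(by_rule$outside_region / n - cfg$region_probs[["other"]]),
            tol(cfg$region_probs[["other"]]))
  cadd_fail <- (by_rule$cadd_below_threshold + by_rule$cadd_unscored) / n
  expect_lt(abs(cadd_fail - (1 - cfg$damaging_fraction)),
            tol(1 - cfg$damaging_fraction))
  expect_lt(abs(fr$audit$n_kept / n - qualifying_fraction(cfg)),
            tol(qualifying_fraction(cfg)))
})

test_that("toggling one rule only changes decisions that cite that rule", {
  sim <- simulate_cohort(small_config(baseline_rate = 5e-3, seed = 4))
  base <- classify_variants(sim$variants, filter_config())
  stricter <- classify_variants(sim$variants, filter_config(cadd_threshold = 25))
  changed <- base$kept != stricter$kept
  cites_cadd <- grepl("cadd", base$reasons) | grepl("cadd", stricter$reasons)
  expect_true(all(cites_cadd[changed]))
  same_rules <- base$reasons == stricter$reasons
  expect_true(all(base$kept[same_rules] == stricter$kept[same_rules]))
})

test_that("burden counts are variant-carrier events and multi-gene rows count per gene", {
  v <- dplyr::bind_rows(
    toy_variant(carriers = "S01,S02"),
    toy_variant(pos = 2000L, gene = "GENE1,GENE2"))
  fr <- filter_variants(v)
  counts <- fr$counts
  expect_equal(counts$count[counts$gene == "GENE1"], 3L)  # 2 carriers + 1
  expect_equal(counts$count[counts$gene == "GENE2"], 1L)
  expect_equal(fr$audit$n_multi_gene, 1)
})

test_that("pathway carrier counts are distinct individuals within one group", {
  fr <- filter_variants(load_table1_fixture())
  expect_equal(count_pathway_carriers(fr$kept, c("NTS", "NTSR1"), "restricted"), 5)
  expect_equal(count_pathway_carriers(fr$kept, c("GCG", "GLP1R"), "binge"), 4)
  expect_equal(count_pathway_carriers(fr$kept, "NOSUCHGENE", "binge"), 0)
  expect_error(count_pathway_carriers(fr$kept, character(0), "binge"), "non-empty")
  expect_error(count_pathway_carriers(fr$kept, "NTS", "purging"), "unknown group")

  sim <- simulate_cohort(small_config(baseline_rate = 5e-3, seed = 6))
  kept <- filter_variants(sim$variants)$kept
  expect_lte(count_pathway_carriers(kept, unique(kept$gene), "restricted"), 38)
  expect_lte(count_pathway_carriers(kept, unique(kept$gene), "binge"), 55)
})

test_that("empty input gives empty outputs with zero counts", {
  fr <- filter_variants(load_table1_fixture()[0, ])
  expect_equal(nrow(fr$kept), 0)
  expect_equal(nrow(fr$counts), 0)
  expect_equal(fr$audit$n_input, 0)
})
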