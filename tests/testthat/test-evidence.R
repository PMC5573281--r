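test_that("training classes follow the citation rules with deterministic ties", {
  cit <- tibble::tibble(
    gene = c("POS1", "POS2", "MID", "NEGA", "NEGB", "NEGC", "LOW"),
    topical_citations = c(3L, 7L, 2L, 0L, 0L, 0L, 0L),
    total_citations = c(10L, 40L, 100000L, 500L, 500L, 400L, 10L))
  ts <- build_training_set(cit, min_topical = 3, n_negatives = 2)
  expect_setequal(ts$positives, c("POS1", "POS2"))
  # MID has huge total citations but 2 topical ones: excluded from training
  expect_false("MID" %in% c(ts$positives, ts$negatives))
  # tie at 500 broken lexicographically
  expect_equal(ts$negatives, c("NEGA", "NEGB"))

  expect_error(build_training_set(cit, n_negatives = 10), "only 4")
  expect_error(build_training_set(cit[0, ]), "non-empty")
})

test_that("training positives are recovered exactly from generated citations", {
  cfg <- small_config(seed = 31)
  truth <- simulate_cohort(cfg)$truth
  feats <- simulate_features(cfg, truth)
  ts <- build_training_set(feats$citations, min_topical = 3,
                           n_negatives = cfg$n_negative_training)
  expect_identical(ts$positives, truth$training_positives)
  expect_length(ts$negatives, cfg$n_negative_training)
  expect_length(intersect(ts$positives, ts$negatives), 0)
})

test_that("scores are vote proportions: bounded, seeded, feature-determined", {
  cfg <- small_config(seed = 17)
  truth <- simulate_cohort(cfg)$truth
  feats <- simulate_features(cfg, truth)
  ts <- build_training_set(feats$citations, n_negatives = cfg$n_negative_training)

  s1 <- score_genes(feats$expression, ts, seed = 7)
  s2 <- score_genes(feats$expression, ts, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
  expect_setequal(s1$gene, rownames(feats$expression))
  expect_identical(s1$oob, s1$is_training)

  # identical feature rows outside training score identically
  X <- feats$expression
  free <- setdiff(rownames(X), c(ts$positives, ts$negatives))
  X[free[2], ] <- X[free[1], ]
  s <- score_genes(X, ts, seed = 7)
  expect_equal(s$score[s$gene == free[1]], s$score[s$gene == free[2]])

  expect_error(score_genes(X[-match(ts$positives[1], rownames(X)), ], ts),
               ts$positives[1])
})

test_that("training scores come from out-of-bag votes only", {
  set.seed(123)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  y <- factor(rep(c("negative", "positive"), each = 30),
              levels = c("negative", "positive"))
  set.seed(42)
  fit <- randomForest::randomForest(X, y, ntree = 50, keep.inbag = TRUE)
  per_tree <- predict(fit, X, predict.all = TRUE)$individual
  manual_oob <- vapply(1:60, function(i) {
    oob_trees <- fit$inbag[i, ] == 0
    mean(per_tree[i, oob_trees] == "positive")
  }, numeric(1))
  expect_equal(unname(fit$votes[, "positive"]), manual_oob, tolerance = 1e-12)

  # and score_genes reports exactly those OOB vote fractions for training genes
  ts <- list(positives = sprintf("g%02d", 31:60),
             negatives = sprintf("g%02d", 1:30))
  s <- score_genes(X, ts, n_trees = 50, seed = 42)
  set.seed(42)
  refit <- randomForest::randomForest(
    X[c(ts$positives, ts$negatives), ], y[c(31:60, 1:30)], ntree = 50)
  expect_equal(s$score[match(ts$positives, s$gene)],
               unname(refit$votes[ts$positives, "positive"]))
})

test_that("separable features give high held-out AUC, null features do not", {
  held_auc <- function(seed, signal) {
    cfg <- sim_config(n_genes = 1000, n_positive_training = 80,
                      n_negative_training = 240, signal_strength = signal,
                      seed = seed)
    truth <- simulate_cohort(cfg)$truth
    feats <- simulate_features(cfg, truth)
    ts_all <- build_training_set(feats$citations,
                                 n_negatives = cfg$n_negative_training)
    train <- list(positives = ts_all$positives[1:40],
                  negatives = ts_all$negatives[1:120])
    held_pos <- ts_all$positives[41:80]
    held_neg <- ts_all$negatives[121:240]
    s <- score_genes(feats$expression, train, seed = seed)
    rank_auc(s$score[match(held_pos, s$gene)],
             s$score[match(held_neg, s$gene)])
  }

  expect_gt(held_auc(1, signal = 3), 0.9)
  null_aucs <- vapply(1:5, held_auc, numeric(1), signal = 0)
  expect_lt(abs(mean(null_aucs) - 0.5), 0.05)
})

test_that("permuting training labels collapses the class separation", {
  cfg <- small_config(seed = 23)
  truth <- simulate_cohort(cfg)$truth
  feats <- simulate_features(cfg, truth)
  ts <- build_training_set(feats$citations, n_negatives = cfg$n_negative_training)

  set.seed(5)
  pool <- sample(c(ts$positives, ts$negatives))
  permuted <- list(positives = pool[seq_along(ts$positives)],
                   negatives = pool[-seq_along(ts$positives)])
  s <- score_genes(feats$expression, permuted, seed = 5)
  gap <- mean(s$score[s$gene %in% ts$positives]) -
    mean(s$score[s$gene %in% ts$negatives])
  expect_lt(abs(gap), 0.1)
})

test_that("evidence combination is the elementwise maximum with flags", {
  e <- tibble::tibble(gene = c("A", "B", "C"), score = c(0.2, 0.5, 0.7),
                      is_training = c(TRUE, FALSE, FALSE),
                      oob = c(TRUE, FALSE, FALSE))
  g <- tibble::tibble(gene = c("A", "B"), score = c(0.8, 0.5),
                      is_training = c(TRUE, FALSE), oob = c(TRUE, FALSE))
  comb <- combine_evidence(e, g)
  expect_equal(comb$combined_score[comb$gene == "A"], 0.8)
  expect_equal(comb$combined_score[comb$gene == "B"], 0.5)
  # missing one evidence type: carry the other, flagged
  expect_equal(comb$combined_score[comb$gene == "C"], 0.7)
  expect_true(comb$missing_evidence[comb$gene == "C"])
  expect_false(any(comb$missing_evidence[comb$gene != "C"]))
  expect_true(comb$is_training[comb$gene == "A"])

  expect_warning(combine_evidence(e, g, universe = c("A", "B", "C", "D")),
                 "no evidence")
})
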