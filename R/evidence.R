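#' Build literature-anchored training classes from a citation table
#'
#' Positives are genes cited in at least `min_topical` papers on the topic;
#' negatives are the `n_negatives` most highly cited genes that have never
#' been cited on the topic. Ties in total citations are broken
#' lexicographically by gene symbol, so the set is deterministic.
#'
#' @param citations Tibble with columns `gene`, `topical_citations`,
#'   `total_citations`.
#' @param min_topical Minimum topical citation count for the positive class.
#' @param n_negatives Size of the negative class.
#' @return A list of class `training_set` with `positives`, `negatives`
#'   (character vectors) and `provenance` (rule string).
#' @examples
#' cit <- tibble::tibble(gene = sprintf("G%02d", 1:30),
#'                       topical_citations = rep(c(4, 0, 1), 10),
#'                       total_citations = 1:30 * 10)
#' build_training_set(cit, n_negatives = 5)
#' @export
build_training_set <- function(citations, min_topical = 3, n_negatives = 1000) {
  citations <- tibble::as_tibble(citations)
  if (nrow(citations) == 0) abort("`citations` must be non-empty")
  positives <- c_sort(citations$gene[citations$topical_citations >= min_topical])
  eligible <- dplyr::filter(citations, .data$topical_citations == 0)
  if (nrow(eligible) < n_negatives) {
    abort(sprintf(
      "only %d genes with zero topical citations are eligible as negatives (need %d)",
      nrow(eligible), n_negatives))
  }
  ord <- order(-eligible$total_citations, eligible$gene, method = "radix")
  negatives <- eligible$gene[ord][seq_len(n_negatives)]
  if (length(positives) == 0) abort("no gene meets the positive-class rule")
  structure(list(
    positives = positives,
    negatives = negatives,
    provenance = sprintf(
      "positives: topical_citations >= %d; negatives: top %d total_citations among topical_citations == 0",
      min_topical, n_negatives)),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d positives, %d negatives\n",
              length(x$positives), length(x$negatives)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Score genes by similarity to the positive training class
#'
#' Fits a random forest (`n_trees` trees, library defaults otherwise) to
#' discriminate training positives from negatives on the supplied feature
#' matrix, then scores every gene with the fraction of trees voting for the
#' positive class. Non-training genes are scored by the full forest;
#' training genes receive their out-of-bag vote fraction, so no gene is
#' scored by a tree that saw it during fitting.
#'
#' @param features Numeric matrix (or data frame) with gene symbols as row
#'   names; rows must cover every training gene.
#' @param training A [build_training_set()] result, or any list with
#'   `positives` and `negatives` character vectors.
#' @param n_trees Number of trees in the ensemble.
#' @param seed Integer seed making the ensemble (and so the scores)
#'   reproducible.
#' @return Tibble with columns `gene`, `score` (vote proportion in \[0, 1\]),
#'   `is_training`, `oob` (TRUE when the score is an out-of-bag estimate).
#' @examples
#' cfg <- sim_config(n_genes = 1200, seed = 2)
#' sim <- simulate_cohort(cfg)
#' feats <- simulate_features(cfg, sim$truth)
#' ts <- build_training_set(feats$citations)
#' scores <- score_genes(feats$expression, ts, seed = 2)
#' range(scores$score)
#' @export
score_genes <- function(features, training, n_trees = 100, seed = 1L) {
  features <- as.matrix(features)
  if (is.null(rownames(features)) || ncol(features) < 1) {
    abort("`features` must have gene row names and at least one column")
  }
  train_genes <- c(training$positives, training$negatives)
  missing <- setdiff(train_genes, rownames(features))
  if (length(missing)) {
    abort(sprintf("training gene(s) missing from feature matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (length(intersect(training$positives, training$negatives))) {
    abort("training classes overlap")
  }

  y <- factor(rep(c("positive", "negative"),
                  c(length(training$positives), length(training$negatives))),
              levels = c("negative", "positive"))
  set.seed(seed)
  fit <- randomForest::randomForest(x = features[train_genes, , drop = FALSE],
                                    y = y, ntree = n_trees)

  oob_scores <- fit$votes[, "positive"]
  rest <- setdiff(rownames(features), train_genes)
  rest_scores <- if (length(rest)) {
    predict(fit, features[rest, , drop = FALSE], type = "vote")[, "positive"]
  } else {
    double(0)
  }

  out <- tibble::tibble(
    gene = c(train_genes, rest),
    score = unname(c(oob_scores, rest_scores)),
    is_training = c(rep(TRUE, length(train_genes)), rep(FALSE, length(rest))))
  out$oob <- out$is_training
  dplyr::arrange(out, .data$gene)
}

#' Combine expression and annotation evidence scores
#'
#' The combined evidence score is the elementwise maximum of the two
#' classifier vote proportions. Genes carrying only one score inherit it as
#' the combined score and are flagged; genes in neither input are omitted
#' with a warning when a `universe` is supplied.
#'
#' @param expression_scores,go_scores Tibbles from [score_genes()].
#' @param universe Optional gene universe used to detect genes with no
#'   evidence at all.
#' @return Tibble with columns `gene`, `expression_score`, `go_score`,
#'   `combined_score`, `is_training`, `oob`, `missing_evidence`.
#' @examples
#' e <- tibble::tibble(gene = c("A", "B"), score = c(0.2, 0.7),
#'                     is_training = FALSE, oob = FALSE)
#' g <- tibble::tibble(gene = "A", score = 0.8,
#'                     is_training = FALSE, oob = FALSE)
#' combine_evidence(e, g)
#' @export
combine_evidence <- function(expression_scores, go_scores, universe = NULL) {
  e <- dplyr::select(tibble::as_tibble(expression_scores),
                     "gene", expression_score = "score",
                     e_train = "is_training", e_oob = "oob")
  g <- dplyr::select(tibble::as_tibble(go_scores),
                     "gene", go_score = "score",
                     g_train = "is_training", g_oob = "oob")
  out <- dplyr::full_join(e, g, by = "gene")
  out <- dplyr::mutate(
    out,
    combined_score = pmax(.data$expression_score, .data$go_score, na.rm = TRUE),
    is_training = dplyr::coalesce(.data$e_train, .data$g_train),
    oob = dplyr::coalesce(.data$e_oob, .data$g_oob),
    missing_evidence = is.na(.data$expression_score) | is.na(.data$go_score))
  out <- dplyr::select(out, "gene", "expression_score", "go_score",
                       "combined_score", "is_training", "oob",
                       "missing_evidence")
  if (!is.null(universe)) {
    orphans <- setdiff(universe, out$gene)
    if (length(orphans)) {
      warn(sprintf("%d gene(s) carry no evidence score and are omitted (e.g. %s)",
                   length(orphans), paste(head(orphans, 3), collapse = ", ")))
    }
  }
  dplyr::arrange(out, .data$gene)
}
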