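#' Simulate an annotated cohort variant table with known ground truth
#'
#' Draws qualifying-variant occurrences per gene and individual from a
#' Poisson model at `baseline_rate`, elevated `rate_multiplier`-fold in the
#' spiked risk genes, then decorates each emitted variant with the
#' annotations the filter consumes: region class, consequence, CADD phred
#' (unscored for indel consequences), known-database membership and caller
#' FILTER flags, at the mixture fractions in the configuration. Because
#' decorations are independent of risk status, filtering thins both risk and
#' non-risk genes equally and the post-filter qualifying rate equals
#' `baseline_rate` in expectation (see [qualifying_fraction()]).
#'
#' Every variant site is unique (one carrier per site), reflecting the
#' ultra-rare regime where recurrent sites are negligible.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (tibble, one row per variant site with
#'   columns chrom, pos, ref, alt, gene, region_class, consequence,
#'   cadd_phred, known_in, caller_filters, carriers, group) and `truth`
#'   (list: risk_genes_restricted, risk_genes_binge, training_positives,
#'   seed).
#' @examples
#' sim <- simulate_cohort(sim_config(n_genes = 300, seed = 7))
#' head(sim$variants)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  genes <- gene_universe(config)

  set.seed(sub_seed(config$seed, 2L))
  emit_rate <- config$baseline_rate / qualifying_fraction(config)
  risk <- genes %in% truth$risk_genes_restricted
  gene_rate <- emit_rate * ifelse(risk, config$rate_multiplier, 1)

  groups <- list(
    restricted = sprintf("R%03d", seq_len(config$n_restricted)),
    binge      = sprintf("B%03d", seq_len(config$n_binge))
  )

  rows <- purrr::imap(groups, function(ids, grp) {
    counts <- matrix(rpois(config$n_genes * length(ids), gene_rate),
                     nrow = config$n_genes)
    hit <- which(counts > 0, arr.ind = TRUE)
    if (nrow(hit) == 0) {
      return(tibble::tibble(gene_idx = integer(), carrier = character(),
                            group = character()))
    }
    k <- counts[hit]
    tibble::tibble(
      gene_idx = rep(hit[, 1], k),
      carrier  = rep(ids[hit[, 2]], k),
      group    = grp
    )
  })
  rows <- dplyr::bind_rows(rows)
  rows <- dplyr::arrange(rows, .data$group, .data$gene_idx, .data$carrier)

  n <- nrow(rows)
  if (n == 0) {
    return(list(variants = empty_variants(), truth = truth))
  }

  region <- sample(names(config$region_probs), n, replace = TRUE,
                   prob = config$region_probs)
  consequence <- sample(names(consequence_probs), n, replace = TRUE,
                        prob = consequence_probs)
  scored <- !consequence %in% c("frameshift", "nonframeshift_indel")
  # P(CADD >= threshold | scored) chosen so the overall damaging-rule pass
  # rate (scored high-CADD plus unscored frameshift) is damaging_fraction.
  p_pass <- (config$damaging_fraction - consequence_probs[["frameshift"]]) /
    (1 - consequence_probs[["frameshift"]] - consequence_probs[["nonframeshift_indel"]])
  p_pass <- min(max(p_pass, 0), 1)
  high <- runif(n) < p_pass
  cadd <- ifelse(high, 15 + rexp(n, rate = 1 / 7), runif(n, 0, 15))
  cadd <- round(ifelse(scored, cadd, NA_real_), 2)

  known <- runif(n) < config$known_fraction
  known_in <- ifelse(known, sample(c("1000G", "dbSNP", "EVS"), n, replace = TRUE), "")
  flagged <- runif(n) < config$flagged_fraction
  caller_filters <- ifelse(
    flagged, sample(c("QD", "Q20", "badReads", "alleleBias"), n, replace = TRUE), "")

  bases <- c("A", "C", "G", "T")
  ref1 <- sample(bases, n, replace = TRUE)
  alt1 <- vapply(ref1, function(b) sample(setdiff(bases, b), 1), character(1))
  ref <- ref1
  alt <- alt1
  fs <- consequence == "frameshift"
  nf <- consequence == "nonframeshift_indel"
  ref[fs] <- paste0(ref1[fs], "AC")    # 2-bp deletion: frameshifting
  alt[fs] <- ref1[fs]
  ref[nf] <- paste0(ref1[nf], "ACG")   # 3-bp deletion: in-frame
  alt[nf] <- ref1[nf]

  offset <- stats::ave(rows$gene_idx, rows$gene_idx, FUN = seq_along)
  variants <- tibble::tibble(
    chrom = as.character((rows$gene_idx - 1L) %% 22L + 1L),
    pos = 1000000L + rows$gene_idx * 10000L + as.integer(offset),
    ref = ref,
    alt = alt,
    gene = genes[rows$gene_idx],
    region_class = region,
    consequence = consequence,
    cadd_phred = cadd,
    known_in = known_in,
    caller_filters = caller_filters,
    carriers = rows$carrier,
    group = rows$group
  )
  list(variants = variants, truth = truth)
}

empty_variants <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(),
                 region_class = character(), consequence = character(),
                 cadd_phred = double(), known_in = character(),
                 caller_filters = character(), carriers = character(),
                 group = character())
}

# Ground truth behind a simulated dataset: one shared risk-gene set for both
# phenotype groups, drawn preferentially from the training positives.
simulate_truth <- function(config) {
  genes <- gene_universe(config)
  set.seed(sub_seed(config$seed, 1L))
  positives <- sample(genes, config$n_positive_training)
  n_risk <- max(1L, round(config$risk_gene_fraction * config$n_genes))
  n_from_pos <- min(round(n_risk * config$risk_positive_overlap),
                    length(positives), n_risk)
  risk <- c(sample(positives, n_from_pos),
            sample(setdiff(genes, positives), n_risk - n_from_pos))
  risk <- c_sort(risk)
  list(risk_genes_restricted = risk,
       risk_genes_binge = risk,
       training_positives = c_sort(positives),
       seed = config$seed)
}

#' Simulate per-gene reference-population counts
#'
#' Emulates a large reference exome database summarised as, per gene, the
#' number of qualifying (novel, predicted-damaging) variants and the number
#' of individuals contributing to that count. Counts are Poisson at the
#' baseline rate — the reference population is never enriched — and the
#' contributing-individual count varies uniformly in
#' `[0.8, 1.0] * n_reference` to emulate coverage variation.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene`, `count`, `n_individuals`.
#' @examples
#' head(simulate_reference(sim_config(n_genes = 100)))
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reference <= 0) abort("`n_reference` must be positive")
  set.seed(sub_seed(config$seed, 3L))
  n <- config$n_genes
  tibble::tibble(
    gene = gene_universe(config),
    count = rpois(n, config$n_reference * config$baseline_rate),
    n_individuals = as.integer(round(runif(n, 0.8, 1) * config$n_reference))
  )
}

#' Simulate expression and annotation feature matrices plus a citation table
#'
#' Emulates the three prioritization inputs: a genes-by-samples expression
#' matrix in which training positives share a latent factor shifted by
#' `signal_strength` SDs (loaded on the first five samples), a binary
#' genes-by-terms annotation matrix in which positives have a
#' logistic-shifted annotation probability on a reserved block of terms, and
#' a citation table in which positives carry >= 3 topical citations while a
#' designated negative pool carries zero topical citations but the highest
#' total citation counts in the universe.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_cohort()]; its gene sets must lie
#'   within the configured universe.
#' @return A list with `expression` (numeric matrix), `annotation` (0/1
#'   matrix) and `citations` (tibble: gene, topical_citations,
#'   total_citations).
#' @examples
#' cfg <- sim_config(n_genes = 1200, seed = 3)
#' sim <- simulate_cohort(cfg)
#' feats <- simulate_features(cfg, sim$truth)
#' dim(feats$expression)
#' @export
simulate_features <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_universe(config)
  if (!all(truth$training_positives %in% genes)) {
    abort("truth gene sets must lie within the configured gene universe")
  }
  set.seed(sub_seed(config$seed, 4L))
  n <- config$n_genes
  pos_idx <- match(truth$training_positives, genes)

  d <- config$n_expression_samples
  k_info <- min(5L, d)
  latent <- rnorm(n)
  latent[pos_idx] <- latent[pos_idx] + config$signal_strength
  expression <- matrix(rnorm(n * d), n, d,
                       dimnames = list(genes, sprintf("S%02d", seq_len(d))))
  expression[, seq_len(k_info)] <- expression[, seq_len(k_info)] + latent

  d2 <- config$n_go_terms
  p0 <- 0.05
  p1 <- stats::plogis(stats::qlogis(p0) + config$signal_strength)
  block <- min(20L, d2)
  annotation <- matrix(rbinom(n * d2, 1, p0), n, d2,
                       dimnames = list(genes, sprintf("GO%04d", seq_len(d2))))
  annotation[pos_idx, seq_len(block)] <-
    rbinom(length(pos_idx) * block, 1, p1)

  is_pos <- genes %in% truth$training_positives
  negatives <- sample(genes[!is_pos], config$n_negative_training)
  is_neg <- genes %in% negatives
  topical <- integer(n)
  total <- integer(n)
  topical[is_pos] <- 3L + rpois(sum(is_pos), 2)
  total[is_pos] <- topical[is_pos] + rpois(sum(is_pos), 300)
  total[is_neg] <- 10000L + sample.int(40000L, sum(is_neg), replace = TRUE)
  other <- !is_pos & !is_neg
  topical[other] <- sample(0:2, sum(other), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  total[other] <- topical[other] + rpois(sum(other), 500)

  list(expression = expression,
       annotation = annotation,
       citations = tibble::tibble(gene = genes,
                                  topical_citations = topical,
                                  total_citations = total))
}

#' Simulate a weighted gene-interaction edge list
#'
#' Builds a preferential-attachment background network over the gene
#' universe plus a planted module: a ring through the training positives and
#' extra random positive-positive pairs (probability `positive_edge_prob`),
#' all at high confidence scores (850-999) so the module survives the usual
#' high-confidence edge threshold. Background scores are uniform on 150-999.
#' Edges are undirected, deduplicated under canonical node ordering, with no
#' self-loops — the dialect of a STRING-style `protein1 protein2
#' combined_score` table.
#'
#' @inheritParams simulate_features
#' @return A tibble with columns `protein1`, `protein2`, `combined_score`.
#' @examples
#' cfg <- sim_config(n_genes = 1200, seed = 3)
#' sim <- simulate_cohort(cfg)
#' edges <- simulate_network(cfg, sim$truth)
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_universe(config)
  if (!all(truth$training_positives %in% genes)) {
    abort("truth gene sets must lie within the configured gene universe")
  }
  set.seed(sub_seed(config$seed, 5L))

  background <- NULL
  if (config$edge_density > 0) {
    g <- igraph::sample_pa(config$n_genes, power = 1, m = config$edge_density,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    background <- tibble::tibble(
      a = genes[el[, 1]], b = genes[el[, 2]],
      combined_score = sample(150:999, nrow(el), replace = TRUE)
    )
  }

  pos <- truth$training_positives
  planted <- NULL
  if (length(pos) >= 2) {
    ring <- cbind(pos, c(pos[-1], pos[1]))
    pairs <- t(utils::combn(pos, 2))
    pairs <- pairs[runif(nrow(pairs)) < config$positive_edge_prob, , drop = FALSE]
    pp <- rbind(ring, pairs)
    planted <- tibble::tibble(
      a = pp[, 1], b = pp[, 2],
      combined_score = sample(850:999, nrow(pp), replace = TRUE)
    )
  }

  edges <- dplyr::bind_rows(background, planted)
  edges <- dplyr::mutate(edges,
                         protein1 = pmin(.data$a, .data$b),
                         protein2 = pmax(.data$a, .data$b))
  edges <- dplyr::filter(edges, .data$protein1 != .data$protein2)
  edges <- dplyr::arrange(edges, .data$protein1, .data$protein2,
                          dplyr::desc(.data$combined_score))
  edges <- dplyr::distinct(edges, .data$protein1, .data$protein2,
                           .keep_all = TRUE)
  dplyr::select(edges, "protein1", "protein2", "combined_score")
}

#' Simulate every pipeline input in one call
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_reference()],
#' [simulate_features()] and [simulate_network()] under per-table sub-streams
#' of one master seed; identical configurations give byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `truth`, `variants`, `reference`, `expression`,
#'   `annotation`, `citations`, `edges`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 1200, seed = 11))
#' names(ds)
#' @export
simulate_dataset <- function(config) {
  cohort <- simulate_cohort(config)
  feats <- simulate_features(config, cohort$truth)
  list(config = config,
       truth = cohort$truth,
       variants = cohort$variants,
       reference = simulate_reference(config),
       expression = feats$expression,
       annotation = feats$annotation,
       citations = feats$citations,
       edges = simulate_network(config, cohort$truth))
}
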