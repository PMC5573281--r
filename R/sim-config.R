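#' Simulation configuration for synthetic cohort studies
#'
#' Bundles every tunable of the synthetic-data generator into one validated
#' list. The defaults define the reference study conditions used throughout
#' the package's tests: two phenotype groups of 38 (restricted-eating) and 55
#' (binge-eating) individuals compared against a 60,000-exome reference
#' population, a small per-gene per-individual rate of qualifying (novel,
#' predicted-damaging) variants, and a minority of "risk" genes whose rate is
#' elevated by a fold multiplier.
#'
#' `baseline_rate` is the rate of *qualifying* variants, i.e. variants that
#' survive the default [filter_config()] rules. On top of these the cohort
#' generator emits decoy variants that fail each filter branch at the
#' configured mixture fractions (`known_fraction`, `flagged_fraction`,
#' `region_probs`, `damaging_fraction`), so that after filtering the cohort
#' rate matches the reference rate — mirroring a real analysis where the same
#' filter criteria are applied to both the cohort and the reference database.
#'
#' @param n_genes Number of genes in the simulated universe. Must exceed
#'   `n_positive_training + n_negative_training`.
#' @param n_restricted,n_binge Cohort sizes of the two phenotype groups.
#' @param n_reference Number of individuals in the reference population.
#' @param baseline_rate Expected qualifying variants per gene per individual
#'   in non-risk genes (ultra-rare scale; default gives an expected per-gene
#'   reference count of 48).
#' @param risk_gene_fraction Fraction of genes spiked as risk genes. One
#'   shared risk set is used for both phenotype groups.
#' @param rate_multiplier Fold elevation of `baseline_rate` in risk genes
#'   (>= 1; 1 gives a null simulation).
#' @param risk_positive_overlap Probability that a risk gene is drawn from
#'   the training positives rather than the remaining universe. Drives the
#'   expected enrichment of burden hits for known genes.
#' @param n_positive_training,n_negative_training Sizes of the
#'   literature-anchored training classes emulated by the citation table.
#' @param n_expression_samples,n_go_terms Feature-matrix dimensions
#'   (expression samples; binary annotation terms).
#' @param signal_strength Latent-factor shift (in factor SDs) separating
#'   training positives from the rest in feature space; 0 removes all signal.
#' @param edge_density Preferential-attachment edges added per node in the
#'   background network (0 = planted positive edges only).
#' @param positive_edge_prob Probability of an extra high-confidence edge for
#'   each pair of training positives (the planted module).
#' @param known_fraction,flagged_fraction Fractions of emitted variants
#'   carrying a known-database record, resp. a blacklisted caller FILTER flag.
#' @param region_probs Named mixture over region classes
#'   (exonic/UTR/splicing/other).
#' @param damaging_fraction Fraction of emitted, clean, in-region variants
#'   that pass the damaging rule (CADD >= 15 or unscored protein-truncating).
#' @param seed Master integer seed; every generator derives per-table
#'   sub-streams from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_dataset()] for one-call generation of all five inputs.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' cfg$baseline_rate
#' @export
sim_config <- function(n_genes = 2500,
                       n_restricted = 38,
                       n_binge = 55,
                       n_reference = 60000,
                       baseline_rate = 8e-4,
                       risk_gene_fraction = 0.02,
                       rate_multiplier = 25,
                       risk_positive_overlap = 0.7,
                       n_positive_training = 100,
                       n_negative_training = 1000,
                       n_expression_samples = 40,
                       n_go_terms = 150,
                       signal_strength = 3,
                       edge_density = 2,
                       positive_edge_prob = 0.2,
                       known_fraction = 0.30,
                       flagged_fraction = 0.05,
                       region_probs = c(exonic = 0.70, UTR = 0.15,
                                        splicing = 0.10, other = 0.05),
                       damaging_fraction = 0.80,
                       seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_restricted, "n_restricted")
  assert_count(n_binge, "n_binge")
  assert_count(n_reference, "n_reference")
  if (!is.finite(baseline_rate)) abort("`baseline_rate` must be finite")
  assert_prob(baseline_rate, "baseline_rate", hi_open = TRUE)
  assert_prob(risk_gene_fraction, "risk_gene_fraction", lo_open = TRUE, hi_open = TRUE)
  if (!is.finite(rate_multiplier) || rate_multiplier < 1) {
    abort("`rate_multiplier` must be finite and >= 1")
  }
  assert_prob(risk_positive_overlap, "risk_positive_overlap")
  assert_count(n_positive_training, "n_positive_training")
  assert_count(n_negative_training, "n_negative_training")
  assert_count(n_expression_samples, "n_expression_samples")
  assert_count(n_go_terms, "n_go_terms")
  if (!is.finite(signal_strength) || signal_strength < 0) {
    abort("`signal_strength` must be finite and >= 0")
  }
  assert_count(edge_density, "edge_density", allow_zero = TRUE)
  assert_prob(positive_edge_prob, "positive_edge_prob")
  assert_prob(known_fraction, "known_fraction", hi_open = TRUE)
  assert_prob(flagged_fraction, "flagged_fraction", hi_open = TRUE)
  if (!setequal(names(region_probs), c("exonic", "UTR", "splicing", "other")) ||
      any(region_probs < 0) || abs(sum(region_probs) - 1) > 1e-8) {
    abort("`region_probs` must be a probability vector over exonic/UTR/splicing/other")
  }
  assert_prob(damaging_fraction, "damaging_fraction", lo_open = TRUE)
  assert_count(seed, "seed", allow_zero = TRUE)
  if (n_genes <= n_positive_training + n_negative_training) {
    abort("`n_genes` must exceed n_positive_training + n_negative_training")
  }

  structure(
    list(n_genes = as.integer(n_genes),
         n_restricted = as.integer(n_restricted),
         n_binge = as.integer(n_binge),
         n_reference = as.integer(n_reference),
         baseline_rate = baseline_rate,
         risk_gene_fraction = risk_gene_fraction,
         rate_multiplier = rate_multiplier,
         risk_positive_overlap = risk_positive_overlap,
         n_positive_training = as.integer(n_positive_training),
         n_negative_training = as.integer(n_negative_training),
         n_expression_samples = as.integer(n_expression_samples),
         n_go_terms = as.integer(n_go_terms),
         signal_strength = signal_strength,
         edge_density = as.integer(edge_density),
         positive_edge_prob = positive_edge_prob,
         known_fraction = known_fraction,
         flagged_fraction = flagged_fraction,
         region_probs = region_probs[c("exonic", "UTR", "splicing", "other")],
         damaging_fraction = damaging_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Consequence mixture of emitted variants. Frameshift and in-frame indels are
# unscored (CADD NA); the rest carry a CADD draw.
consequence_probs <- c(missense = 0.80, stopgain = 0.05, frameshift = 0.05,
                       nonframeshift_indel = 0.05, synonymous = 0.05)

#' Analytic fraction of emitted variants that qualify under default filters
#'
#' The cohort generator decorates emitted variants independently (region
#' class, known-database flag, caller FILTER flag, CADD/consequence), so the
#' probability that an emitted variant survives the default [filter_config()]
#' is a product of the configured mixture fractions. The generator divides
#' `baseline_rate` by this value when emitting, making the post-filter
#' qualifying rate equal `baseline_rate` exactly in expectation.
#'
#' @param config A [sim_config()].
#' @return A single probability.
#' @examples
#' qualifying_fraction(sim_config())
#' @export
qualifying_fraction <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p_region <- sum(config$region_probs[c("exonic", "UTR", "splicing")])
  p_region * (1 - config$known_fraction) * (1 - config$flagged_fraction) *
    config$damaging_fraction
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d  cohorts: %d restricted / %d binge  reference: %d\n",
              x$n_genes, x$n_restricted, x$n_binge, x$n_reference))
  cat(sprintf("  baseline_rate: %g  risk fraction: %g  multiplier: %g\n",
              x$baseline_rate, x$risk_gene_fraction, x$rate_multiplier))
  cat(sprintf("  training: %d positives / %d negatives  signal: %g\n",
              x$n_positive_training, x$n_negative_training, x$signal_strength))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

gene_universe <- function(config) sprintf("G%06d", seq_len(config$n_genes))
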