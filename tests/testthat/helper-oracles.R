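# Shared independent oracles and small builders for the suite.

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min over j >= i of min(1, p_(j) * m / j), mapped to input order.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Rank-based AUC (probability a positive outscores a negative).
rank_auc <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores))
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Two-sided exact hypergeometric p-value by enumeration: total probability
# of all tables as or less likely than the observed one.
hyper_two_sided <- function(a, n_hits, n_pos, n_universe) {
  k <- 0:min(n_hits, n_pos)
  d <- stats::dhyper(k, n_pos, n_universe - n_pos, n_hits)
  sum(d[d <= stats::dhyper(a, n_pos, n_universe - n_pos, n_hits) * (1 + 1e-7)])
}

# A single annotated variant row with overridable fields.
toy_variant <- function(...) {
  base <- tibble::tibble(
    chrom = "1", pos = 1000L, ref = "G", alt = "A", gene = "GENE1",
    region_class = "exonic", consequence = "missense", cadd_phred = 20,
    known_in = "", caller_filters = "", carriers = "S01", group = "restricted")
  dplyr::mutate(base, ...)
}

# The generator's documented gene naming, re-derived independently.
gene_universe_of <- function(cfg) sprintf("G%06d", seq_len(cfg$n_genes))

# Small, fast simulation settings used where the full defaults are overkill.
small_config <- function(...) {
  sim_config(n_genes = 500, n_positive_training = 40,
             n_negative_training = 120, ...)
}
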