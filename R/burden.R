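#' One-sided two-proportion burden test
#'
#' Tests H1: x1/n1 > x2/n2. The default `"chisq"` method is the classical
#' two-sample test for equal proportions — the signed square root of the
#' continuity-corrected chi-square statistic referred to the standard normal
#' upper tail, numerically identical to
#' `prop.test(alternative = "greater")`. The `"exact"` method returns the
#' binomial tail P(X >= x1) for X ~ Binomial(n1, (x1+x2)/(n1+n2)), the
#' pooled-rate oracle, which remains valid where the chi-square
#' approximation is anti-conservative (expected cohort counts well below
#' one, as with a 38-exome cohort against a 60,000-exome reference).
#'
#' When `x1 = x2 = 0` the p-value is 1 by convention. All arguments are
#' vectorized.
#'
#' @param x1,n1 Qualifying count and size of the cohort sample.
#' @param x2,n2 Qualifying count and contributing-individual count of the
#'   reference sample.
#' @param correct Apply the continuity correction (chisq method).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return Vector of one-sided p-values in \[0, 1\].
#' @examples
#' two_proportion_test(4, 38, 158, 60000)
#' two_proportion_test(4, 38, 158, 60000, method = "exact")
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = TRUE,
                                method = c("chisq", "exact")) {
  method <- match.arg(method)
  k <- max(length(x1), length(n1), length(x2), length(n2))
  x1 <- rep_len(x1, k); n1 <- rep_len(n1, k)
  x2 <- rep_len(x2, k); n2 <- rep_len(n2, k)
  if (any(!is.finite(x1) | !is.finite(n1) | !is.finite(x2) | !is.finite(n2))) {
    abort("all counts must be finite")
  }
  if (any(x1 < 0 | x2 < 0)) abort("counts must be non-negative")
  if (any(n1 <= 0 | n2 <= 0)) abort("sample sizes must be positive")
  if (any(x1 > n1)) abort("`x1` exceeds `n1`: carrier counts cannot exceed cohort size")
  if (any(x2 > n2)) abort("`x2` exceeds `n2`")

  pooled <- (x1 + x2) / (n1 + n2)
  if (method == "exact") {
    p <- pbinom(x1 - 1, n1, pooled, lower.tail = FALSE)
    p[x1 + x2 == 0] <- 1
    return(p)
  }

  p1 <- x1 / n1
  p2 <- x2 / n2
  delta <- p1 - p2
  yates <- if (correct) pmin(0.5, abs(delta) / (1 / n1 + 1 / n2)) else 0
  e11 <- n1 * pooled; e12 <- n1 * (1 - pooled)
  e21 <- n2 * pooled; e22 <- n2 * (1 - pooled)
  stat <- (abs(x1 - e11) - yates)^2 / e11 +
    (abs(n1 - x1 - e12) - yates)^2 / e12 +
    (abs(x2 - e21) - yates)^2 / e21 +
    (abs(n2 - x2 - e22) - yates)^2 / e22
  p <- pnorm(sign(delta) * sqrt(stat), lower.tail = FALSE)
  # degenerate tables (pooled rate 0 or 1): no evidence either way
  p[x1 + x2 == 0 | (x1 == n1 & x2 == n2)] <- 1
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up q-values: `q_(i) = min over j >= i of min(1, p_(j) m/j)`
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, elementwise >= `p`, order-preserving in `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene burden scan against a reference population
#'
#' One test per (gene, group) pair with a positive cohort count, comparing
#' the cohort's qualifying variant-carrier rate with the per-gene reference
#' rate via [two_proportion_test()]. Genes never hit in the cohort are not
#' tested. Genes absent from the reference table are tested against a
#' reference count of zero with the full reference cohort size, and flagged.
#' Benjamini-Hochberg adjustment is applied within each phenotype group by
#' default (`pool_groups = TRUE` adjusts across both lists jointly).
#'
#' @param counts Tibble (gene, group, count) as produced by
#'   [filter_variants()].
#' @param reference Tibble (gene, count, n_individuals) as produced by
#'   [simulate_reference()] or loaded from a reference database extract.
#' @param group_sizes Named vector of cohort sizes, e.g.
#'   `c(restricted = 38, binge = 55)`.
#' @param fdr FDR threshold defining the significant gene sets.
#' @param method Test form passed to [two_proportion_test()].
#' @param pool_groups Adjust p-values across groups jointly instead of
#'   within group.
#' @param ref_cohort_size Reference cohort size imputed for genes missing
#'   from `reference`; defaults to the maximum observed `n_individuals`.
#' @return An object of class `burden_scan`: a list with `records` (tibble:
#'   gene, group, x_cohort, n_cohort, x_ref, n_ref, p_value, q_value,
#'   ref_missing) and `significant` (list: one gene vector per group plus
#'   `union`). Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 1200, seed = 5))
#' fr <- filter_variants(ds$variants)
#' scan <- run_burden(fr$counts, ds$reference,
#'                    group_sizes = c(restricted = 38, binge = 55))
#' glance(scan)
#' @export
run_burden <- function(counts, reference,
                       group_sizes = c(restricted = 38, binge = 55),
                       fdr = 0.1,
                       method = c("chisq", "exact"),
                       pool_groups = FALSE,
                       ref_cohort_size = NULL) {
  method <- match.arg(method)
  assert_prob(fdr, "fdr", lo_open = TRUE, hi_open = TRUE)
  counts <- tibble::as_tibble(counts)
  reference <- tibble::as_tibble(reference)
  if (is.null(ref_cohort_size)) {
    ref_cohort_size <- if (nrow(reference)) max(reference$n_individuals) else 1L
  }
  if (!all(counts$group %in% names(group_sizes))) {
    abort("every group in `counts` needs an entry in `group_sizes`")
  }

  records <- dplyr::filter(counts, .data$count > 0)
  records <- dplyr::left_join(
    records,
    dplyr::select(reference, "gene", x_ref = "count", n_ref = "n_individuals"),
    by = "gene")
  records <- dplyr::mutate(
    records,
    ref_missing = is.na(.data$x_ref),
    x_ref = ifelse(.data$ref_missing, 0L, .data$x_ref),
    n_ref = ifelse(.data$ref_missing, ref_cohort_size, .data$n_ref),
    x_cohort = .data$count,
    n_cohort = as.integer(group_sizes[.data$group]),
    p_value = two_proportion_test(.data$x_cohort, .data$n_cohort,
                                  .data$x_ref, .data$n_ref, method = method))
  records <- dplyr::select(records, "gene", "group", "x_cohort", "n_cohort",
                           "x_ref", "n_ref", "p_value", "ref_missing")

  if (nrow(records) == 0) {
    records$q_value <- double(0)
  } else if (pool_groups) {
    records$q_value <- bh_adjust(records$p_value)
  } else {
    records <- dplyr::mutate(dplyr::group_by(records, .data$group),
                             q_value = bh_adjust(.data$p_value))
    records <- dplyr::ungroup(records)
  }
  records <- dplyr::relocate(records, "q_value", .after = "p_value")
  records <- dplyr::arrange(records, .data$group, .data$p_value, .data$gene)

  sig <- lapply(split(records, records$group),
                function(d) c_sort(unique(d$gene[d$q_value < fdr])))
  for (g in names(group_sizes)) if (is.null(sig[[g]])) sig[[g]] <- character(0)
  sig <- sig[names(group_sizes)]
  sig$union <- c_sort(unique(unlist(sig)))

  structure(list(records = records, significant = sig, fdr = fdr,
                 method = method, pool_groups = pool_groups),
            class = "burden_scan")
}

#' @export
print.burden_scan <- function(x, ...) {
  cat(sprintf("<burden_scan> %d gene-group tests, method=%s, FDR<%g\n",
              nrow(x$records), x$method, x$fdr))
  for (g in setdiff(names(x$significant), "union")) {
    cat(sprintf("  %s: %d significant genes\n", g, length(x$significant[[g]])))
  }
  cat(sprintf("  union: %d genes\n", length(x$significant$union)))
  invisible(x)
}

#' @rdname run_burden
#' @param x A `burden_scan`.
#' @param ... Unused.
#' @method tidy burden_scan
#' @export
tidy.burden_scan <- function(x, ...) x$records

#' @rdname run_burden
#' @method glance burden_scan
#' @export
glance.burden_scan <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$records),
    n_sig_restricted = length(x$significant$restricted %||% character(0)),
    n_sig_binge = length(x$significant$binge %||% character(0)),
    n_sig_union = length(x$significant$union),
    fdr = x$fdr,
    method = x$method)
}

#' @rdname run_burden
#' @param object A `burden_scan`.
#' @method autoplot burden_scan
#' @export
autoplot.burden_scan <- function(object, ...) {
  d <- dplyr::mutate(object$records,
                     fold = (.data$x_cohort / .data$n_cohort) /
                       pmax(.data$x_ref / .data$n_ref, 1e-12),
                     significant = .data$q_value < object$fdr)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold),
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "log2 fold enrichment vs reference",
                  y = "-log10 p", colour = sprintf("q < %g", object$fdr)) +
    ggplot2::theme_minimal()
}
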