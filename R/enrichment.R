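#' Enrichment of burden hits for a known gene set
#'
#' Builds the 2x2 table of hit/non-hit by positive/non-positive over a
#' stated gene universe, reports the sample odds ratio
#' `(a d) / (b c)` (a = hits that are positives, b = hits that are not,
#' c = positives not hit, d = the rest) and a two-sided exact p-value on the
#' hypergeometric null from [stats::fisher.test()]. A zero `b` or `c` cell
#' makes the sample OR infinite (flagged `or_defined = FALSE` when 0/0).
#'
#' @param hits Gene set called significant (must lie within `universe`).
#' @param positives Known gene set (must lie within `universe`).
#' @param universe Non-empty gene universe over which the table is built.
#' @return An object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `odds_ratio`, `p_value`, `universe_size`, `or_defined`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' u <- sprintf("G%03d", 1:1000)
#' overlap_enrichment(u[1:20], u[c(1:5, 21:65)], u)
#' @export
overlap_enrichment <- function(hits, positives, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  hits <- unique(hits)
  positives <- unique(positives)
  if (!all(hits %in% universe)) abort("`hits` must lie within `universe`")
  if (!all(positives %in% universe)) abort("`positives` must lie within `universe`")

  a <- length(intersect(hits, positives))
  b <- length(hits) - a
  c_ <- length(positives) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(hit = c("hit", "non_hit"),
                                positive = c("positive", "non_positive")))

  or <- (a * d) / (b * c_)
  or_defined <- is.finite(or) || ((b * c_ == 0) && (a * d > 0))
  p <- fisher.test(tab)$p.value

  structure(list(table = tab, odds_ratio = or, p_value = p,
                 universe_size = length(universe), or_defined = or_defined),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> OR = %s, p = %.3g (universe %d)\n",
              format(x$odds_ratio, digits = 3), x$p_value, x$universe_size))
  print(x$table)
  invisible(x)
}

#' @rdname overlap_enrichment
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    hit = rep(rownames(x$table), 2),
    positive = rep(colnames(x$table), each = 2),
    n = as.vector(x$table))
}

#' @rdname overlap_enrichment
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
                 universe_size = x$universe_size, or_defined = x$or_defined)
}
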