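#' Filter configuration for the novel, predicted-damaging variant set
#'
#' Four rules reduce an annotated cohort variant table to the analysis set:
#' region class must be exonic/UTR/splicing, no blacklisted caller FILTER
#' flag, no record in any known-variant database (novelty), and predicted
#' damaging — CADD phred at or above the threshold, or, when CADD is
#' unscored (typical for indel calls), a protein-truncating consequence when
#' `keep_unscored_truncating` is set.
#'
#' @param cadd_threshold Minimum CADD phred score (default 15, the
#'   creators' suggested damaging cutoff).
#' @param filter_blacklist Caller FILTER flags that disqualify a call.
#' @param allowed_regions Region classes retained.
#' @param known_databases Database labels whose membership marks a variant
#'   as previously observed (not novel).
#' @param keep_unscored_truncating Keep CADD-missing variants whose
#'   consequence is stopgain or frameshift.
#' @return A list of class `filter_config`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(cadd_threshold = 15,
                          filter_blacklist = c("QD", "Q20", "badReads", "alleleBias"),
                          allowed_regions = c("exonic", "UTR", "splicing"),
                          known_databases = c("1000G", "dbSNP", "EVS"),
                          keep_unscored_truncating = TRUE) {
  if (!is.finite(cadd_threshold) || cadd_threshold < 0) {
    abort("`cadd_threshold` must be finite and >= 0")
  }
  structure(list(cadd_threshold = cadd_threshold,
                 filter_blacklist = filter_blacklist,
                 allowed_regions = allowed_regions,
                 known_databases = known_databases,
                 keep_unscored_truncating = isTRUE(keep_unscored_truncating)),
            class = "filter_config")
}

truncating_consequences <- c("stopgain", "frameshift")

#' Classify variants against the filter rules
#'
#' Applies every rule to every variant and records each failed rule, so a
#' variant dropped for several reasons lists them all. A variant is kept if
#' and only if its reason list is empty.
#'
#' @param variants Tibble of annotated variants (see [simulate_cohort()] for
#'   the column contract). `region_class` must be present and non-missing.
#' @param config A [filter_config()].
#' @return The input with logical `kept` and comma-joined `reasons` columns
#'   appended (`reasons` is `""` for kept variants).
#' @examples
#' v <- load_table1_fixture()
#' dplyr::count(classify_variants(v, filter_config()), kept, reasons)
#' @export
classify_variants <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, kept = logical(0), reasons = character(0)))
  }
  if (!"region_class" %in% names(variants) || anyNA(variants$region_class)) {
    abort("annotation incomplete: `region_class` is required for every variant")
  }

  fail_region <- !variants$region_class %in% config$allowed_regions
  fail_flag <- flags_intersect(variants$caller_filters, config$filter_blacklist)
  fail_known <- flags_intersect(variants$known_in, config$known_databases)
  cadd <- variants$cadd_phred
  scored_pass <- !is.na(cadd) & cadd >= config$cadd_threshold
  unscored_pass <- is.na(cadd) & config$keep_unscored_truncating &
    variants$consequence %in% truncating_consequences
  fail_cadd <- !(scored_pass | unscored_pass)
  cadd_reason <- ifelse(is.na(cadd), "cadd_unscored", "cadd_below_threshold")

  reasons <- mapply(function(r, f, k, cd, cr) {
    paste(c(if (r) "outside_region", if (f) "caller_filter",
            if (k) "known_variant", if (cd) cr), collapse = ",")
  }, fail_region, fail_flag, fail_known, fail_cadd, cadd_reason,
  USE.NAMES = FALSE)

  dplyr::mutate(variants, kept = reasons == "", reasons = reasons)
}

#' Filter a cohort to qualifying variants with per-gene counts and an audit
#'
#' Runs [classify_variants()], splits multi-gene annotations (comma-joined
#' gene symbols) into one counting event per gene, and tallies qualifying
#' variant-carrier events per gene and phenotype group. The burden count
#' unit is the variant-carrier event: a site carried by k individuals
#' contributes k, and for novel ultra-rare sites this reduces to one per
#' variant row.
#'
#' @inheritParams classify_variants
#' @return A list of class `filter_result`:
#'   * `kept` — qualifying variant rows;
#'   * `counts` — tibble (gene, group, count) of qualifying variant-carrier
#'     events;
#'   * `audit` — list with `n_input`, `n_kept`, `n_dropped`,
#'     `dropped_by_rule` (each rule counts every variant that failed it, so
#'     the rule counts can exceed `n_dropped`), and `n_multi_gene`.
#' @examples
#' fr <- filter_variants(load_table1_fixture())
#' fr$counts
#' @export
filter_variants <- function(variants, config = filter_config()) {
  classified <- classify_variants(variants, config)
  kept <- dplyr::select(dplyr::filter(classified, .data$kept), -"kept", -"reasons")

  all_reasons <- unlist(split_flags(classified$reasons))
  rule_levels <- c("outside_region", "caller_filter", "known_variant",
                   "cadd_below_threshold", "cadd_unscored")
  dropped_by_rule <- table(factor(all_reasons, levels = rule_levels))

  events <- tidyr::separate_rows(kept, "gene", sep = ",")
  events <- dplyr::mutate(events, n_carriers = lengths(split_flags(.data$carriers)))
  counts <- dplyr::summarise(
    dplyr::group_by(events, .data$gene, .data$group),
    count = as.integer(sum(.data$n_carriers)), .groups = "drop")
  counts <- dplyr::arrange(counts, .data$gene, .data$group)

  structure(list(
    kept = kept,
    counts = counts,
    audit = list(
      n_input = nrow(classified),
      n_kept = nrow(kept),
      n_dropped = nrow(classified) - nrow(kept),
      dropped_by_rule = as.list(dropped_by_rule),
      n_multi_gene = sum(grepl(",", kept$gene, fixed = TRUE))
    )),
    class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d input, %d kept, %d dropped\n",
              x$audit$n_input, x$audit$n_kept, x$audit$n_dropped))
  by_rule <- unlist(x$audit$dropped_by_rule)
  by_rule <- by_rule[by_rule > 0]
  if (length(by_rule)) {
    cat("  failures by rule:",
        paste(sprintf("%s=%d", names(by_rule), by_rule), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count distinct carriers of qualifying variants across a gene set
#'
#' @param kept Tibble of qualifying variants (the `kept` element of a
#'   [filter_variants()] result).
#' @param gene_set Non-empty character vector of gene symbols.
#' @param group Phenotype group label present in the data contract
#'   (`"restricted"` or `"binge"`).
#' @return Number of distinct sample IDs in `group` carrying at least one
#'   qualifying variant in any gene of `gene_set`.
#' @examples
#' fr <- filter_variants(load_table1_fixture())
#' count_pathway_carriers(fr$kept, c("NTS", "NTSR1"), "restricted")
#' @export
count_pathway_carriers <- function(kept, gene_set, group) {
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty")
  if (!group %in% c("restricted", "binge")) {
    abort(sprintf("unknown group label: %s", group))
  }
  rows <- tidyr::separate_rows(tibble::as_tibble(kept), "gene", sep = ",")
  rows <- dplyr::filter(rows, .data$gene %in% gene_set, .data$group == !!group)
  length(unique(unlist(split_flags(rows$carriers))))
}
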