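#' Read and write the package's tab-separated interchange formats
#'
#' Thin readr wrappers fixing column types for the annotated-variant,
#' reference-count and citation tables, with `NA` written literally so
#' unscored CADD values round-trip.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a tibble.
#' @name burdenscope-io
NULL

#' @rdname burdenscope-io
#' @export
write_variants_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' @rdname burdenscope-io
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    cadd_phred = readr::col_double(),
    known_in = readr::col_character(),
    caller_filters = readr::col_character(),
    .default = readr::col_character()))  |>
    dplyr::mutate(known_in = dplyr::coalesce(.data$known_in, ""),
                  caller_filters = dplyr::coalesce(.data$caller_filters, ""))
}

#' @rdname burdenscope-io
#' @export
write_reference_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname burdenscope-io
#' @export
read_reference_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    count = readr::col_integer(),
    n_individuals = readr::col_integer()))
}

#' Write a cohort variant table as VCF v4.2
#'
#' Serializes the annotated-variant table to VCF with INFO keys `GENE`,
#' `CADD`, `REGION`, `CSQ`, `KNOWN` (pipe-separated database labels) and
#' `GROUP`, caller flags in the FILTER column (`PASS` when clean), and one
#' GT sample column per carrier observed in the table.
#'
#' @param variants Annotated-variant tibble.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @seealso [read_cohort_vcf()] for the inverse.
#' @export
write_cohort_vcf <- function(variants, path) {
  variants <- tibble::as_tibble(variants)
  samples <- c_sort(unique(unlist(split_flags(variants$carriers))))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=burdenscope",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="Region class">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=KNOWN,Number=1,Type=String,Description="Known-database labels, pipe-separated">',
    '##INFO=<ID=GROUP,Number=1,Type=String,Description="Phenotype group of the carriers">',
    paste0('##FILTER=<ID=', c("QD", "Q20", "badReads", "alleleBias"),
           ',Description="Caller flag">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  info <- sprintf(
    "GENE=%s;REGION=%s;CSQ=%s;GROUP=%s%s%s",
    variants$gene, variants$region_class, variants$consequence, variants$group,
    ifelse(is.na(variants$cadd_phred), "",
           sprintf(";CADD=%s", format(variants$cadd_phred, trim = TRUE))),
    ifelse(variants$known_in == "", "",
           sprintf(";KNOWN=%s", gsub(",", "|", variants$known_in, fixed = TRUE))))
  filt <- ifelse(variants$caller_filters == "", "PASS",
                 gsub(",", ";", variants$caller_filters, fixed = TRUE))
  gt <- vapply(seq_len(nrow(variants)), function(i) {
    carr <- split_flags(variants$carriers[i])[[1]]
    paste(ifelse(samples %in% carr, "0/1", "0/0"), collapse = "\t")
  }, character(1))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", filt, info, "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cohort VCF back into the annotated-variant table
#'
#' Parses a VCF written by [write_cohort_vcf()] (or any VCF carrying the
#' same INFO keys) with the vcfR package.
#'
#' @param path VCF file path.
#' @return Annotated-variant tibble.
#' @export
read_cohort_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(v, element = key)
  gt <- vcfR::extract.gt(v)
  carriers <- apply(gt, 1, function(row) {
    paste(colnames(gt)[!is.na(row) & row %in% c("0/1", "1/1", "0|1", "1|0", "1|1")],
          collapse = ",")
  })
  cadd <- suppressWarnings(as.numeric(info_get("CADD")))
  known <- info_get("KNOWN")
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_get("GENE"),
    region_class = info_get("REGION"),
    consequence = info_get("CSQ"),
    cadd_phred = cadd,
    known_in = ifelse(is.na(known), "", gsub("|", ",", known, fixed = TRUE)),
    caller_filters = ifelse(is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."),
                            "", gsub(";", ",", fix$FILTER, fixed = TRUE)),
    carriers = unname(carriers),
    group = info_get("GROUP"))
}

#' Write or read simulation ground truth as JSON
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path File path.
#' @return `write_truth_json()` returns `path` invisibly;
#'   `read_truth_json()` returns the truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$seed <- as.integer(out$seed)
  out
}
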