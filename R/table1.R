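#' Neuropeptide-pathway variant fixture
#'
#' The 25 published neuropeptide-pathway variant calls from the
#' eating-disorder exome cohorts, transcribed as printed (coordinates,
#' alleles, CADD phred, reference-database MAF and rs identifiers), with one
#' distinct synthetic carrier per row and group labels matching the table
#' sections (8 restricted-eating rows, 16 binge-eating rows, and the
#' additional POMC row carried by a binge-group individual). Rows the caller
#' represented as indels or multi-nucleotide substitutions lack a CADD score
#' and are labelled `frameshift` so the unscored-truncating filter rule
#' applies to them; rows with an rs identifier carry `dbSNP` membership and
#' are therefore not novel.
#'
#' @return Tibble in the annotated-variant column contract (see
#'   [simulate_cohort()]) plus `exac_maf` and `rsid` annotation columns.
#' @examples
#' v <- load_table1_fixture()
#' nrow(v)
#' @export
load_table1_fixture <- function() {
  rows <- tibble::tribble(
    ~gene,   ~chrom, ~pos,       ~ref,        ~alt,        ~cadd_phred, ~exac_maf, ~rsid,          ~group,
    "NTS",    "12",  86270438L,  "G",         "A",         15.89,       NA,        NA,             "restricted",
    "NTS",    "12",  86272301L,  "A",         "G",         16.85,       NA,        NA,             "restricted",
    "NTS",    "12",  86272345L,  "G",         "A",         23.3,        NA,        NA,             "restricted",
    "NTS",    "12",  86276089L,  "G",         "A",         29.9,        NA,        NA,             "restricted",
    "NTSR1",  "20",  61386033L,  "GCAGGT",    "G",         NA,          NA,        NA,             "restricted",
    "UCN",    "10",  5416075L,   "T",         "C",         21.3,        5.03e-05,  "rs142836326",  "restricted",
    "VIP",    "6",   153075342L, "A",         "G",         22.5,        NA,        NA,             "restricted",
    "VIP",    "6",   153077340L, "G",         "A",         19.39,       NA,        NA,             "restricted",
    "GCG",    "2",   163003908L, "C",         "T",         18.38,       NA,        NA,             "binge",
    "GCG",    "2",   163003961L, "GC",        "AA",        NA,          NA,        NA,             "binge",
    "GLP1R",  "6",   39033595L,  "GAGGGGAA",  "AAGGGGAG",  NA,          NA,        NA,             "binge",
    "GLP1R",  "6",   39046934L,  "A",         "G",         28.7,        NA,        NA,             "binge",
    "BDNF",   "11",  27680107L,  "G",         "T",         20.557,      NA,        NA,             "binge",
    "NTRK2",  "9",   87325623L,  "C",         "A",         18.764,      NA,        NA,             "binge",
    "NTRK2",  "9",   87549182L,  "AG",        "CC",        NA,          NA,        NA,             "binge",
    "QRFPR",  "4",   122301595L, "CCA",       "ACC",       NA,          NA,        NA,             "binge",
    "UNC80",  "2",   210682673L, "G",         "A",         27.5,        NA,        NA,             "binge",
    "UNC80",  "2",   210690770L, "G",         "A",         15.64,       NA,        NA,             "binge",
    "UNC80",  "2",   210699658L, "G",         "A",         24.6,        NA,        NA,             "binge",
    "UNC80",  "2",   210737632L, "G",         "A",         23.6,        NA,        NA,             "binge",
    "UNC80",  "2",   210745728L, "G",         "C",         18.51,       NA,        NA,             "binge",
    "UNC80",  "2",   210778652L, "G",         "A",         32,          NA,        NA,             "binge",
    "UNC80",  "2",   210809854L, "C",         "A",         27.3,        NA,        NA,             "binge",
    "AVP",    "20",  3063808L,   "G",         "A",         21.8,        NA,        NA,             "binge",
    "POMC",   "2",   25384048L,  "G",         "C",         21.6,        0.00231,   "rs28932472",   "binge"
  )
  carriers <- c(sprintf("R%02d", 1:8), sprintf("B%02d", 1:17))
  dplyr::mutate(
    rows,
    region_class = "exonic",
    consequence = dplyr::case_when(
      gene == "NTSR1" ~ "frameshift",
      is.na(cadd_phred) ~ "frameshift",  # caller-indel records, unscored
      TRUE ~ "missense"),
    known_in = ifelse(is.na(rsid), "", "dbSNP"),
    caller_filters = "",
    carriers = carriers,
    .after = "alt")
}
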