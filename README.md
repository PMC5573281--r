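# burdenscope

Case-only rare-variant burden analysis and candidate-gene prioritization
for small, phenotype-stratified exome cohorts.

## The problem

Cohorts of a few dozen cases per behavioral stratum — here 38
restricted-eating and 55 binge-eating individuals — are too small for
common-variant association, but each carries *novel, predicted-damaging*
variants whose per-gene burden can be compared against a large reference
population (~60,000 exomes) instead of sequenced controls. burdenscope
packages that design as a tested pipeline for statistical geneticists and
psychiatric-genomics analysts:

1. **Filter** annotated calls to the novel damaging set: region class in
   {exonic, UTR, splicing}, no blacklisted caller FILTER flag (`QD`,
   `Q20`, `badReads`, `alleleBias`), no record in 1000 Genomes / dbSNP /
   EVS, and CADD phred ≥ 15 (unscored protein-truncating indel calls are
   retained).
2. **Burden-test** each hit gene per group: with cohort count x₁ of n₁
   individuals and reference count x₂ of n₂, the one-sided two-proportion
   test p = 1 − Φ(sign(p̂₁−p̂₂)·√X²_Yates) (identical to
   `prop.test(alternative = "greater")`), Benjamini–Hochberg control
   within group, hits at FDR < 0.1. An exact binomial mode
   (`method = "exact"`) is provided for the ultra-rare regime where the
   chi-square approximation is anti-conservative.
3. **Score evidence** per gene: random-forest vote proportions (100
   trees, out-of-bag for training genes) against literature-anchored
   training classes — positives cited ≥ 3 times on-topic, negatives the
   1,000 most-cited never-on-topic genes — on expression and on GO-style
   annotation features; combined score = max of the two.
4. **Quantify enrichment** of hits for the known-gene class: 2×2 sample
   odds ratio (ad)/(bc) with an exact hypergeometric p-value.
5. **Extract the network module**: project hits onto a STRING-dialect
   weighted network (edge confidence ≥ 700) and keep the connected
   components anchored by training positives and their neighbors.

A synthetic-data generator (`simulate_dataset()`) emulates every input —
cohort variants, reference counts, feature matrices, citation table,
network — with known ground truth, so the whole pipeline is testable
without any download. The published table of neuropeptide-pathway
variants ships as `load_table1_fixture()`.

## Worked example

```r
library(burdenscope)

variants <- load_table1_fixture()      # 25 published variant calls
fr <- filter_variants(variants)
fr
#> <filter_result> 25 input, 23 kept, 2 dropped
#>   failures by rule: known_variant=2

count_pathway_carriers(fr$kept, c("NTS", "NTSR1"), "restricted")
#> [1] 5
count_pathway_carriers(fr$kept, c("GCG", "GLP1R"), "binge")
#> [1] 4
```

The two dropped rows (UCN, POMC) carry dbSNP records, so they are not
novel. Five of 38 restricted-eating individuals carry qualifying variants
in the neurotensin pathway (NTS or its receptor), and four of 55
binge-eating individuals in the GLP-1 pathway — the pipeline's
recomputation of the published carrier counts.

Burden-testing the fixture counts against illustrative reference counts
(NTS: 158/60,000, i.e. ~0.1 expected in 38 exomes; UNC80: 1,745/60,000,
~1.6 expected in 55):

```r
ref <- tibble::tibble(gene = c("NTS", "UNC80"),
                      count = c(158L, 1745L),
                      n_individuals = c(60000L, 60000L))
scan <- run_burden(fr$counts, ref)
dplyr::filter(tidy(scan), gene %in% c("NTS", "UNC80"))
#> # A tibble: 2 × 9
#>   gene  group      x_cohort n_cohort x_ref n_ref  p_value  q_value ref_missing
#>   <chr> <chr>         <int>    <int> <int> <int>    <dbl>    <dbl> <lgl>
#> 1 UNC80 binge             7       55  1745 60000 4.35e- 5 4.35e- 5 FALSE
#> 2 NTS   restricted        4       38   158 60000 1.11e-26 1.11e-26 FALSE
```

NTS — 4 observed qualifying variants against ~0.1 expected — is the
strongest restricted-group signal, as in the published analysis. The full
synthetic pipeline, end to end:

```r
run <- run_pipeline(sim_config(seed = 7))
run$summary
#> # A tibble: 1 × 9
#>   n_variants n_kept n_tested n_sig_union risk_recall null_call_rate
#>        <int>  <int>    <int>       <int>       <dbl>          <dbl>
#> 1        548    287      242         218         0.9         0.0706
#>   enrichment_or enrichment_p module_size
#>           <dbl>        <dbl>       <int>
#> 1          6.86     6.91e-15          38
```

At the default study conditions the scan recovers 90% of the spiked risk
genes, falsely calls 7% of the non-risk universe (the structural behavior
of a test-only-the-hits design — see the methods vignette), and the hit
list is ~7-fold enriched for training positives. `autoplot(run$module)`
draws the anchored module with nodes shaded by evidence score and square
glyphs for training genes; `tidy()`/`glance()` work on burden scans and
enrichment results.

## Documentation

The methods vignette (`vignettes/burdenscope-methods.Rmd`) describes the
model and its assumptions, the approximation regime of the burden test,
the calibration caveats of testing only hit genes, every generator
default and why, and known limitations.
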