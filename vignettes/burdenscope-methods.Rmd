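---
title: "Methods: case-only rare-variant burden analysis and gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-only rare-variant burden analysis and gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenscope)
library(dplyr)
```

## The analysis problem

burdenscope implements a case-only rare-variant analysis for small,
phenotype-stratified exome cohorts — the setting of eating-disorder
genetics, where a few dozen cases per behavioral stratum (here 38
restricted-eating and 55 binge-eating individuals) are sequenced without
matched controls and compared against a large public reference population
of roughly 60,000 exomes. The pipeline has five stages, each usable on its
own:

1. **Variant filtering** (`filter_variants()`): reduce annotated calls to
   the *novel, predicted-damaging* set.
2. **Burden testing** (`run_burden()`): per-gene one-sided two-proportion
   test of cohort counts against reference counts, with Benjamini–Hochberg
   control within each phenotype group.
3. **Evidence scoring** (`score_genes()`, `combine_evidence()`):
   random-forest vote proportions measuring similarity of each gene to a
   literature-anchored positive class, separately on expression features
   and on binary functional-annotation features.
4. **Enrichment** (`overlap_enrichment()`): a 2×2 exact test of whether the
   burden hits over-represent the known-gene training class.
5. **Network module extraction** (`extract_module()`): project hits onto a
   weighted interaction network and keep the connected components anchored
   by training positives and their neighbors.

Because raw patient exomes and the exact reference extract of such studies
are not redistributable, the package ships a synthetic-data generator
(`simulate_dataset()`) that emulates all five inputs with known ground
truth, plus the published table of neuropeptide-pathway variants
(`load_table1_fixture()`) as an in-package worked example.

## Variant filtering

A call qualifies when all four rules pass:

* region class in {exonic, UTR, splicing};
* no blacklisted caller FILTER flag (defaults `QD`, `Q20`, `badReads`,
  `alleleBias`);
* novel: no membership in any configured known-variant database
  (defaults 1000 Genomes, dbSNP, Exome Variant Server);
* predicted damaging: CADD phred ≥ 15 (the threshold recommended by
  CADD's authors), or — when CADD is unscored, as is typical for indel
  calls — a protein-truncating consequence (stopgain/frameshift), under
  `keep_unscored_truncating = TRUE`.

Every failed rule is recorded per variant, so the audit log reconciles
exactly (`input = kept + dropped`, with per-rule failure counts that may
overlap). The burden **count unit is the variant-carrier event**: a site
carried by *k* individuals contributes *k*. For novel ultra-rare sites this
is one per variant row; it stays well defined for recurrent sites.
Variants annotated to several overlapping genes count once per gene and
are flagged in the audit. Unscored *non*-truncating indels are dropped:
there is no damaging evidence for them. In the packaged fixture, records
the caller represented as indels (including same-length multi-nucleotide
substitutions) carry no CADD score and are treated as putative truncating
calls, which is what retains them under the default rules.

## The burden test and its approximation regime

For gene *g* with cohort count $x_1$ among $n_1$ individuals and reference
count $x_2$ among $n_2$ contributing individuals, `two_proportion_test()`
computes the classical one-sided test for equal proportions: the signed
square root of the continuity-corrected chi-square statistic referred to
the standard normal upper tail,
$p = 1 - \Phi\!\left(\mathrm{sign}(\hat p_1-\hat p_2)\sqrt{X^2_{\mathrm{Yates}}}\right)$.
It is numerically identical to `prop.test(alternative = "greater")` (the
suite asserts exact equality on a random grid) and is re-implemented only
to vectorize cleanly, to fix the $x_1 = x_2 = 0 \Rightarrow p = 1$
convention, and to avoid small-count warnings on every gene.

**Where the approximation is trustworthy.** Against the exact binomial
tail, the chi-square p agrees within a factor of 3 across
$p \in [10^{-6}, 0.5]$ when the expected cohort count $n_1 x_2/n_2$ is at
least ~20 *and* the cohort is about one-tenth of the reference; there the
pooled-variance conservatism and the normal tail's skewness deficit
roughly offset. This is the regime the oracle-agreement tests sample.

**Where it is not.** At the application's own scale — 38 exomes against
60,000, expected cohort counts far below one — the approximation is
anti-conservative by orders of magnitude: a single observed variant against
a reference rate of $5\times10^{-4}$ yields a chi-square p near
$3\times10^{-4}$, while the exact binomial tail is about $0.02$. The suite
asserts this breakdown explicitly, and `method = "exact"` (the pooled-rate
binomial tail $P(X \ge x_1)$, $X \sim \mathrm{Bin}(n_1, (x_1+x_2)/(n_1+n_2))$)
is provided as the statistically safer switch. The default remains the
chi-square form because it is the procedure this pipeline sets out to
reproduce.

**Multiplicity and calibration.** Only genes actually hit in the cohort
are tested; BH is applied within each phenotype group (a pooled mode
exists; published gene lists per stratum suggest within-group control).
One consequence deserves emphasis: conditional on being tested at all
($x_1 \ge 1$), essentially every gene is nominally significant in the
ultra-rare regime — under the null, $P(x_1 \ge 1)$ is a few percent, and
any tested gene's p-value is far below any reasonable threshold under
either test form. The false discovery rate *among calls* is therefore
structurally uncontrolled for this procedure; what stays bounded is the
*fraction of the gene universe* falsely called, which under the null
equals roughly the per-gene testing probability (a few percent, below the
nominal 0.1). That is the property the calibration tests assert, and it
explains why a case-only scan of ~2,500 effective genes can report
hundreds of "significant" genes: the hit list is best read as "genes with
any novel damaging variant", with the evidence scores, enrichment and
network stages doing the actual prioritization.

## Evidence scores

Training classes come from a citation table: positives are genes with ≥ 3
topical citations; negatives are the 1,000 most-cited genes with zero
topical citations (ties broken lexicographically, so the set is
deterministic). One random forest of 100 trees (library defaults
otherwise, unweighted classes) is fitted per evidence type — a
genes × samples expression matrix and a binary genes × terms annotation
matrix — and each gene's score is the fraction of trees voting for the
positive class. Training genes are scored **out-of-bag**: only trees whose
bootstrap sample excluded the gene vote, a bookkeeping property the suite
verifies against the inbag matrix directly. Non-training genes are scored
by the full forest. The combined evidence score is the elementwise maximum
of the two; a gene with one missing score inherits the other, flagged.
Missing feature values are not expected from the generator; both
classifiers share one training set.

## Enrichment

`overlap_enrichment()` builds the 2×2 table of hit/non-hit ×
positive/non-positive over an explicit gene universe, reports the sample
odds ratio $(ad)/(bc)$ and a two-sided exact hypergeometric p-value
(`fisher.test`). The pipeline's default universe is the **full simulated
gene universe**, not the tested genes: since nearly every tested gene is
called, conditioning on testing would empty the non-hit margin and leave
the odds ratio 0/0. With a genome-scale universe the statistic behaves as
intended.

## Network module

Edges are STRING-dialect (`protein1`, `protein2`, `combined_score` on
0–1000), undirected, deduplicated under canonical (min, max) ordering,
self-loops dropped, thresholded at 700 — the conventional high-confidence
cutoff; the threshold is configurable and recorded in the manifest because
the underlying procedure does not pin it. Module extraction is three
deterministic steps: induce the subgraph on the significant genes (by
default training positives anchor only if themselves significant; a
permissive mode adds all positives present in the network); keep nodes
that are positives or adjacent to one; return the union of connected
components containing at least one positive. `autoplot()` renders the
module with nodes shaded by combined evidence and square glyphs for
training positives.

## The synthetic generator: what it emulates, and what it does not

All randomness flows from one master seed through fixed per-table
sub-streams, so outputs are byte-identical under a repeated configuration
and one stage's draws never shift another's.

* **Cohort variants.** Occurrences are Poisson per gene × individual.
  `baseline_rate` (default $8\times10^{-4}$) is the rate of *qualifying*
  variants; decoys failing each filter branch are emitted on top so that
  the decorated mixture matches the configured fractions (~30% known, ~5%
  FILTER-flagged, 5% off-region, 80% passing the damaging rule) and the
  post-filter rate equals the reference rate — mirroring a real analysis,
  where the same filter criteria are applied to the reference database
  when deriving its counts. The implied keep fraction is analytic
  (`qualifying_fraction()`, 0.505 at defaults).
* **Risk genes.** A fraction (default 2%) of genes is spiked
  `rate_multiplier`-fold (default 25×). One shared risk set serves both
  phenotype groups: with per-group cohorts of 38 and 55 and reference
  counts capped near 50, per-group recovery of a 25× spike is bounded near
  55%, while the union across groups reaches ~85% — the regime in which
  the power property is stated. Risk genes are drawn from the training
  positives with probability 0.7, which is what makes the hit list
  measurably enriched for the positive class (expected odds ratios well
  above 1 at the defaults, by a hypergeometric power calculation done at
  design time).
* **Reference counts.** Poisson at the baseline rate over 60,000
  individuals (the reference is never enriched), with per-gene
  contributing-individual counts uniform in [0.8, 1.0] × 60,000 to emulate
  coverage variation. The default baseline gives expected per-gene
  reference counts of 48.
* **Features and citations.** Training positives share a latent factor
  shifted by `signal_strength` SDs (default 3), loaded on five expression
  samples, and a logistic-shifted annotation probability on a reserved
  block of 20 terms; `signal_strength = 0` removes the signal entirely, a
  null the calibration tests exploit. The citation table is constructed so
  the training rules recover the designated classes exactly.
* **Network.** Preferential-attachment background (2 edges per node,
  scores uniform 150–999) plus a planted module: a ring through the
  positives and random positive pairs at probability 0.2, scores 850–999,
  so the module survives the 700 threshold.
* **Universe size.** The default universe is 2,500 genes — large enough to
  hold 100 positives and 1,000 negatives with a non-training majority,
  small enough that the full pipeline runs in about a second. Test
  simulations use 20 seeds at this size for the calibration and power
  properties, and 500–1,200-gene configurations where full defaults are
  unnecessary.

The generator does **not** emulate realistic site-frequency spectra,
linkage, ancestry structure, gene length variation, per-gene mutability,
or read-level error. Passing tests therefore demonstrate that the
*procedure* behaves as specified under its own assumptions — calibrated
null behavior at the universe level, power against planted spikes,
recoverable feature signal and planted modules — not that those
assumptions hold in any real cohort.

## A worked example on the published fixture

```{r fixture}
variants <- load_table1_fixture()
fr <- filter_variants(variants)
fr

count_pathway_carriers(fr$kept, c("NTS", "NTSR1"), "restricted")
count_pathway_carriers(fr$kept, c("GCG", "GLP1R"), "binge")
filter(fr$counts, gene == "NTS")
```

Two of the 25 fixture rows fall to the novelty rule (both carry dbSNP
records); every unscored indel call is truncating and retained. Five of 38
restricted-eating individuals carry qualifying variants in the neurotensin
pathway, and four of 55 binge-eating individuals in the GLP-1 pathway,
matching the published counts.

## Numerical choices and degenerate inputs

* $x_1 = x_2 = 0$ returns p = 1; fully degenerate tables (both proportions
  1) likewise.
* Cohort counts exceeding the cohort size raise an error (carrier
  semantics); in the ultra-rare regime this cannot occur.
* Genes absent from the reference table are tested against a zero count
  with the full reference cohort size and flagged `ref_missing`.
* BH ties need no special handling; `bh_adjust()` delegates to
  `p.adjust(method = "BH")` and is property-tested against a brute-force
  step-up implementation.
* Odds ratios with an empty margin are reported as infinite, or flagged
  undefined for 0/0.
* Edge files with unparseable rows fail fast with the offending line
  number; duplicate edges keep the maximum score.
* Gene-set sorting uses radix order throughout, so results are independent
  of the session locale.

## Known limitations

* The default burden test inherits the anti-conservatism of the
  chi-square approximation at small cohort sizes; use `method = "exact"`
  when the expected cohort count under the reference rate is below ~20.
* FDR control among calls is not achievable for this test-only-the-hit
  procedure in the ultra-rare regime (see above); interpret the hit list
  accordingly.
* The enrichment odds ratio depends on the chosen universe; the published
  analysis this mirrors did not state its universe, so absolute odds
  ratios are comparable only under a stated convention.
* Identifier mapping between protein and gene symbols is assumed done;
  the network stage consumes whatever symbols the edge list carries.
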