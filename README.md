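# cystirep

Dual-phenotype drug screening and transcriptomic signature-reversal
analysis for cystinosis drug repurposing.

## The problem

Nephropathic cystinosis is a rare lysosomal storage disease: loss of the
cystinosin transporter (*CTNS*) causes lysosomal cystine accumulation,
renal Fanconi syndrome, and an increased propensity of proximal tubular
cells to undergo apoptosis. Drug repurposing is an attractive route to new
therapy — screen a library of approved compounds for ones that (a) deplete
cellular cystine and (b) protect cells from apoptosis, then ask *in
silico* which of the disease's transcriptional changes those compounds are
predicted to reverse.

cystirep is an R package for exactly that integrative analysis. It is
aimed at screening groups and computational biologists who have plate-level
screen tables, a count matrix (or a precomputed differential-expression
table), and per-compound ranked gene lists, and who want a reproducible,
fully testable pipeline from raw wells to enriched pathways.

## What it computes

- **Z-factor assay QC**, plain and replicate-adjusted:
  `Z = 1 − 3(σ_p + σ_n)/|μ_p − μ_n|`, with the replicate variant dividing
  the spread term by √r. Per-plate verdicts and pooled assay-level values.
- **Cystine screen**: nmol cystine / mg protein, percent of the plate's
  vehicle mean, hits at ≥ 50% reduction (boundary inclusive).
- **Apoptosis screen**: caspase-3/7-positive nuclei / total nuclei,
  percent of the plate's induced-untreated mean, hits at ≥ 40% reduction.
- **Lead selection**: intersection of the two hit sets, user-supplied
  toxicity exclusions, four-parameter logistic dose-response fits
  `y = d + (a − d)/(1 + (x/c)^b)`, one-way ANOVA + Bonferroni follow-up.
- **Disease signature**: median-of-ratios normalization, a simplified
  negative-binomial Wald test with moderated method-of-moments dispersion,
  Benjamini-Hochberg FDR, and direction labels (up: FDR < 0.05 and
  log2FC ≥ 1; down: FDR < 0.05 and log2FC ≤ −1).
- **Signature reversal**: a disease-up gene is a candidate when ≥ k of n
  compound ranked lists have it in their downregulated tail (default
  k = 4, n = 5, tail 250), and vice versa.
- **Over-representation analysis**: one-sided hypergeometric test of the
  candidates against GMT gene sets, with greedy Jaccard clustering of
  redundant terms.

A seeded synthetic-study generator (`default_study()`) emulates every
input with planted ground truth — 1200 compounds with 24 planted cystine
depleters and 27 apoptosis protectors (6 overlapping), 10,000 genes with
200 planted regulated genes, and 5 ranked lists with a planted reversal
structure — so the whole pipeline is testable end to end with no external
data. See `vignettes/cystirep-methods.Rmd` for the models, parameter
choices, and limitations.

## Worked example

```r
library(cystirep)

# assay quality from control wells
ctrl <- summarize_controls(positive = c(0.9, 1.4, 1.1, 1.0),
                           negative = c(11.8, 12.3, 12.1, 11.9))
z_factor(ctrl)
#> [1] 0.8797912

# call hits on a simulated 96-compound plate set with two planted depleters
sim <- simulate_screen(screen_sim_config(
  "cystine", n_compounds = 96, noise_sd = 0.03,
  planted_hits = data.frame(compound_id = c("CPD0007", "CPD0061"), effect = 0.8),
  seed = 42))
hits <- call_cystine_hits(screen_cystine(sim$wells), threshold_reduction = 50)
subset(hits, hit)
#>    compound_id phenotype activity reduction  hit
#> 7      CPD0007   cystine 19.23060  80.76940 TRUE
#> 61     CPD0061   cystine 21.75952  78.24048 TRUE
```

Both planted compounds — and nothing else — come back: their measured
activity is ~20% of vehicle (the planted 80% depletion), well past the 50%
cut. The full pipeline on the default synthetic study:

```r
manifest <- run_pipeline(pipeline_config(tempdir(), seed = 1))
unlist(manifest$screens)
#>   n_cystine_hits n_apoptosis_hits
#>               24               27
manifest$cross$n_crossed
#> [1] 6
unlist(manifest$reversal)
#>   disease_up_reversed disease_down_reversed
#>                    23                    16
manifest$enrichment$top_set
#> [1] "SET_REVERSAL"
```

The manifest counts equal the planted truth: 24 cystine hits, 27 apoptosis
hits, 6 crossed leads, 23 disease-up genes opposed by ≥ 4 compounds, 16
disease-down genes likewise, and the gene set seeded with reversal genes
ranks first in the enrichment. Per-stage tables (`cystine_hits.tsv`,
`deg.tsv`, `reversal_candidates.tsv`, `enrichment.tsv`, ...) and
`manifest.json` are written to the output directory.

A thin command-line front end with per-stage subcommands lives at
`inst/scripts/cystirep-cli.R`:

```sh
Rscript inst/scripts/cystirep-cli.R simulate --out study --seed 1
Rscript inst/scripts/cystirep-cli.R screen-cystine --plates study/cystine_plates.csv --out hits.tsv
Rscript inst/scripts/cystirep-cli.R run-all --out run --seed 1
```

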