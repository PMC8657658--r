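---
title: "Methods: dual-phenotype screening and signature-reversal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-phenotype screening and signature-reversal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystirep)
```

# The analysis

cystirep implements an integrative drug-repurposing analysis for
nephropathic cystinosis, a lysosomal storage disease in which loss of the
cystinosin transporter (CTNS) causes lysosomal cystine accumulation and an
increased propensity of proximal tubular cells to undergo apoptosis. The
pipeline chains seven stages:

1. **Assay quality control** with the Z-factor statistic, per plate and per
   assay.
2. **Cystine-depletion hit calling**: per-well cystine (nmol) normalized to
   protein (mg), expressed as percent of the same plate's vehicle (DMSO)
   mean, hits at >= 50% reduction.
3. **Apoptosis-protection hit calling**: caspase-3/7-positive nuclei over
   total nuclei, normalized to the plate's induced-untreated mean, hits at
   >= 40% reduction.
4. **Hit intersection** and four-parameter logistic (4PL) dose-response
   confirmation, with one-way ANOVA / Bonferroni follow-up statistics.
5. **Disease signature**: a simplified negative-binomial two-group test on a
   gene x sample count matrix (knockout vs wild-type), Benjamini-Hochberg
   FDR, and direction labels (up: FDR < 0.05 and log2FC >= 1; down: FDR <
   0.05 and log2FC <= -1).
6. **Signature-reversal voting**: a disease-up gene is a candidate when at
   least k of n compound signatures downregulate it (and vice versa).
7. **Over-representation analysis** of the candidates against a GMT
   collection by the one-sided hypergeometric test.

Every stage consumes and produces plain-text tables, and a seeded synthetic
study (`default_study()`) emulates all inputs with planted ground truth.

# Assay quality control

For positive/negative control wells with means $\mu_p, \mu_n$ and sample
standard deviations $\sigma_p, \sigma_n$ (n-1 denominator, the assay-QC
convention), the Z-factor is

$$Z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}.$$

$Z = 1$ is a perfect assay; $Z \ge 0.5$ is the conventional "excellent"
band and $0 < Z < 0.5$ "marginal but usable". For imaging assays read in
$r$ replicates the package also provides a replicate-adjusted variant. The
phrase "the same formula divided by the square root of the replicate
number" is ambiguous; `z_factor_replicate_adjusted()` defaults to dividing
the *spread term* by $\sqrt r$,

$$Z_r = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|\sqrt r},$$

because that is the standard error of replicate-averaged wells and keeps a
perfect assay at $Z_r = 1$; dividing the whole expression would score a
perfect assay $1/\sqrt r$, which is incompatible with treating values near
0.55 as good for a high-content assay. The literal whole-expression reading
remains available via `mode = "whole"`.

**Plate gate.** `plate_qc()` defaults to the 0.5 "excellent" threshold for
standalone use, but the pipeline's per-plate gate (`qc_threshold` in
`pipeline_config()`) defaults to 0. Two reasons. First, a high-content
assay whose replicate-adjusted Z is ~0.55 at $r = 3$ has a *plain* Z of
~0.22, so a 0.5 plain-Z plate gate would discard every valid plate of a
perfectly usable screen. Second, per-plate control panels are small (8
wells per side on the 48-well plates), so the plate-level Z estimate is
noisy; the gate is meant to catch broken plates (contaminated controls,
failed dispensing), which sit far below 0, not to re-litigate assay
quality, which the pooled assay-level Z reports.

# Screen normalization and hit calling

Both screens normalize plate-wise: controls live on every plate and each
well is referenced to its own plate, which removes plate-to-plate level
shifts. Replicate wells of a compound are normalized within their own plate
first and then averaged on the percent scale (a `min`/`max` policy is
available for more conservative calling). Hit thresholds are
boundary-inclusive (>= 50% cystine reduction, >= 40% apoptosis reduction),
matching the ">=" convention of the screen design; both are configurable.
The apoptosis screen's non-induced vehicle wells do not enter hit calling —
they are the Z-factor positive controls.

Toxicity exclusion before dose-response confirmation is a user-supplied
compound list (`exclude`), not an automated rule: the screens define no
viability readout from which such a rule could be derived.

# The synthetic study

`default_study()` generates the full input suite under explicit seeds:

* **Cystine HTS**: 1200 compounds on 48-well plates (8 vehicle + 8
  cysteamine-like positive control wells per plate, 32 compounds per plate,
  38 plates), 24 planted depleters at effect 0.8 (expected activity 20% of
  vehicle). The per-plate control count is a simulation choice, selected so
  the plate-level Z estimate is stable.
* **Apoptosis HCS**: 384-well plates with 32 + 32 controls, triplicate
  plate sets, 27 planted protectors at effect 0.7, six compounds shared
  with the depleters.
* **Counts**: 10,000 genes x 3 + 3 samples, NB with baseline mean 100 and
  dispersion 0.05 (typical for a clonal cell-line comparison), 200 planted
  regulated genes — the 39 reversal genes at log2 effect +/-3 and the rest
  at magnitudes uniform in [1, 3].
* **Ranked lists**: 5 compound PRLs over the same genome; 23 disease-up
  genes planted in the bottom tail of >= 4 lists and 16 disease-down genes
  in the top tail of >= 4 lists — the support structure whose voting
  outcome the published analysis reports — plus distractors with support 3
  (below the k = 4 cut), same-direction support, and support on genes that
  are not differentially expressed.

Readout noise is gaussian with SD proportional to the negative-control
mean, censored at physical bounds (0, and 1 for fractions). The noise
fractions (0.0255 for HTS, 0.119 for HCS) are calibrated so that the
simulated assays reproduce the reported assay quality — plain Z = 0.83 for
the HTS and replicate-adjusted Z = 0.55 for the HCS — treating those
published values as design inputs of the generator; the HCS calibration
accounts for the censoring of near-zero non-induced control fractions.

What the generator deliberately does *not* emulate: plate-position
(edge/drift) effects, plate-to-plate batch shifts, compound-specific
toxicity or autofluorescence artifacts, protein-content variation between
wells, mean-dependent dispersion trends, correlated genes, or library-size
imbalance beyond what NB sampling produces. Passing the planted-truth tests
therefore shows the *logic* of the pipeline is right, not that the
thresholds would perform identically on real plates.

# The negative-binomial test

`nb_wald_test()` is a deliberately simple reimplementation of the standard
NB differential-expression machinery:

* **Size factors** by median-of-ratios: per-sample median of the ratios to
  the per-gene geometric-mean pseudo-reference, over genes expressed in all
  samples.
* **Dispersion** by pooled method of moments on normalized counts,
  $\hat\alpha_g = \max\{(\hat v_g - \bar m_g \overline{1/s})/\bar m_g^2,\ 0\}$,
  then **moderated** toward the genome-wide median:
  $\tilde\alpha_g = (d_g \hat\alpha_g + d_0 \bar\alpha)/(d_g + d_0)$ with
  residual df $d_g = n_1 + n_2 - 2$ and prior df $d_0 = 10$.
* **Wald statistic** on the log2 ratio of group means (pseudo-count 0.5 on
  each mean), with a delta-method standard error floored at the Poisson
  variance, referred to a t distribution on $d_g + d_0$ df.

The moderation deserves a word. With triplicates, a purely gene-wise
dispersion leaves 4 residual df; a t reference on 4 df has such heavy tails
that even enormous Wald statistics cannot produce p-values below ~1e-5, and
genome-wide BH across 10,000 genes then recovers almost nothing (we
measured sensitivity 0.025 on the planted benchmark). Sharing dispersion
information across genes is how every NB differential-expression framework
solves this; the median-targeted shrinkage here is the simplest version of
it. With $d_0 = 10$ the test is calibrated (null type-I error 0.047-0.053
at the 0.05 level across seeds) and recovers planted signal (sensitivity
~0.92 at observed FDR ~0.01 on the default benchmark). The cost is that
genes whose true dispersion is far from the genome-wide typical value get a
slightly wrong reference — acceptable in the homogeneous-dispersion
simulation, and a documented approximation for real data, where a
mean-dispersion trend would be the next refinement.

Known boundary behaviour: a gene with a true |log2FC| exactly at the
fold-change cut of 1 is called "up"/"down" only when its *estimated* fold
change lands at or beyond the cut, i.e. roughly half the time — sensitivity
statements therefore depend on the planted effect-size distribution, which
is why the benchmark plants magnitudes in [1, 3]. Exact reproduction of any
particular study's DEG totals additionally depends on package internals
(shrinkage, filtering) that this simplified test intentionally omits.

`bh_adjust()` delegates to the stock step-up implementation after
validation; the test suite checks it against an independently written
brute-force step-up oracle. The direction labels use a strict FDR
inequality (< 0.05) and boundary-inclusive fold-change cuts (>= 1, <= -1);
the "downregulated" cut is the symmetric negative of the upregulated one.

# Dose-response confirmation

The 4PL model is $y = d + (a - d)/(1 + (x/c)^b)$ with top $a$ (zero-dose
asymptote), bottom $d$, EC50 $c > 0$ and Hill slope $b$; at $x = c$ the
curve passes through $(a + d)/2$. Fitting is least squares via
Levenberg-Marquardt with $a, d$ initialized from the responses at the
extreme doses, $c$ from the geometric mid-dose, $b = 1$, and up to five
bounded restarts from perturbed starts. Flat response vectors and fits with
$|a - d|$ at numerical zero are flagged `converged = FALSE` with parameters
withheld — with no response range the EC50 is unidentifiable. Four distinct
doses are the minimum (the model has four parameters); recovering all four
parameters to high precision additionally needs doses bracketing both
asymptotes, which is why the recovery benchmarks add anchor doses (0.1 and
100 uM) around the tested 1-10 uM grid. No extrapolation beyond the fitted
dose range is performed.

Confirmation statistics follow the screen's convention: one-way ANOVA
across conditions; only when the overall p < 0.05 are pairwise
pooled-variance t tests computed, Bonferroni-adjusted by multiplying each
raw p by the number of comparisons and capping at 1.

# Reversal voting

Compound signatures are the two tails of each prototype ranked list (rank 1
= most upregulated by the compound). The default tail of 250 genes per side
is common connectivity-map practice; the value is a configurable stand-in,
not an inference — when explicit per-compound up/down gene-list files
exist, they are used verbatim via `compound_signature()`. Rank ties are
rejected at parse time: a PRL is a total order. `aggregate_ranked_lists()`
offers mean-rank (Borda) consensus with deterministic lexicographic
tie-breaks for users who need to merge replicate rankings.

Voting selects a disease-up gene iff it sits in the down-tail of at least
k of the n signatures (symmetrically for disease-down genes); k = 4 of n =
5 by default. Non-significant genes never enter, and same-direction support
never counts. The implementation is checked against an exhaustive
brute-force enumeration on random instances, and is monotone: lowering k or
widening tails can only add candidates.

# Enrichment

`hypergeom_enrich()` computes the one-sided upper-tail hypergeometric
probability $P(X \ge x)$ for overlap $x$ between the query and each set,
with population the declared universe — the standard over-representation
test. The universe defaults (in the pipeline) to the genes of the DEG
table; the background choice materially changes p-values and is therefore
explicit, with set and query genes outside the universe dropped and
counted. `summarize_clusters()` groups redundant significant sets greedily
by Jaccard similarity of member genes (representative = lowest-p member),
a deterministic, simple stand-in for kappa-statistic term clustering.

# Problem sizes and determinism

The packaged benchmarks run the default study at full size (1200 compounds,
10,000 genes, 5 ranked lists; a few seconds end to end), a 10,000-gene null
simulation for test calibration, 10,000 simulated null ANOVA datasets, 200
noisy 4PL replicates, and a complete hypergeometric enumeration sweep over
universes up to 30 genes — sizes chosen to make the statistical checks
tight while keeping a full run comfortably interactive. All generators take
explicit mandatory seeds and restore the caller's RNG state; identical
seeds give byte-identical outputs, and `run_pipeline()` is a pure function
of its declared inputs. Gene identifiers are matched as exact
case-sensitive strings across DEG, ranked-list, and GMT inputs, with
dropped/unmatched identifiers counted rather than silently folded.

# Limitations

* The NB test has no mean-dispersion trend, no fold-change shrinkage, and
  no independent filtering; it is a transparent baseline, not a replacement
  for a full differential-expression framework on real data.
* The tail-size convention for "a compound up/downregulates a gene" is an
  explicit default, and reversal results depend on it; supplying curated
  up/down lists sidesteps the choice.
* The enrichment stage tests over-representation only; it has no notion of
  term hierarchy or ontology structure.
* The synthetic study's realism limits are listed above; in particular
  plate-position artifacts and batch effects, which dominate many real
  screens, are out of scope by design.
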