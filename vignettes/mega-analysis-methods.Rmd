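---
title: "Gene-wise mega-analysis of multi-study case/control expression data"
author: "megaexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise mega-analysis of multi-study case/control expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaexpr)
```

## The problem

When a disease has been profiled by many small public case/control
expression studies, no single study has the power to pin down modest
transcriptional changes, and published summary statistics are rarely
comparable across platforms. The *mega-analysis* approach sidesteps both
problems: every gene's effect size is re-estimated from each study's
**original expression matrix** under one common definition, and the
per-study estimates are then combined with standard meta-analytic
machinery. `megaexpr` implements this for collections like the sixteen
public thyroid-cancer case/control array studies bundled as
`default_study_registry()` (783 cases and 439 controls across Poland,
Belgium, the USA, Portugal, Singapore and France), together with the
screening stages that surround it in practice: literature gene-list
overlap, study-level moderator regression, and gene-set
over-representation.

## The model

### Per-study effect size

For gene $g$ in study $s$ the effect size is the log2 fold change (LFC)
of cases over controls. With case samples $x_{1},\dots,x_{n_T}$ and
control samples $y_{1},\dots,y_{n_C}$ on the linear scale, the default
estimator is

$$\hat\theta_{gs} \;=\; \frac{1}{n_T}\sum_i \log_2 x_i \;-\;
  \frac{1}{n_C}\sum_j \log_2 y_j,$$

i.e. the mean per-case log2 ratio to the control *geometric* mean, with
within-study variance

$$\widehat{\mathrm{var}}(\hat\theta_{gs}) \;=\;
  \frac{s^2_{\log x}}{n_T} + \frac{s^2_{\log y}}{n_C}.$$

A second variant, `control_mean = "arithmetic"`, takes per-case log2
ratios to the control arithmetic mean and adds a delta-method term
$s^2_y / (n_C\,\bar y^2 \ln^2 2)$ for the uncertainty of that mean. The
two variants agree as within-group variability vanishes, but they are
not interchangeable under multiplicative noise: because the arithmetic
mean of a log-normal variable exceeds its geometric mean, the
arithmetic-reference estimator converges to
$\theta_{gs} - \sigma^2 \ln 2 / 2$ rather than to $\theta_{gs}$ — a
Jensen-gap offset of about $0.35\,\sigma^2$ log2 units that no sample
size removes, and that would shift *every* gene of a study by the same
amount. Since the package's simulator (and, plausibly, array data in
general) is multiplicative-noise-shaped, the geometric reference is the
default: it is the unique internally consistent choice (log-scale
difference of log-scale means), it keeps the combined test calibrated,
and it leaves the arithmetic variant available for users who want the
literal ratio-to-the-mean reading. Genes with non-positive values or
fewer than two usable samples per group in a study are excluded from
that study only.

### Heterogeneity and model choice

For each gene the $k$ per-study estimates $(\hat\theta_i, v_i)$ are
first combined with inverse-variance (fixed-effect) weights
$w_i = 1/v_i$. Cochran's statistic

$$Q \;=\; \sum_i w_i\,(\hat\theta_i - \bar\theta_w)^2, \qquad
  \mathrm{df} = k - 1,$$

measures total dispersion; its upper-tail $\chi^2_{\mathrm{df}}$
probability (`q_p`) is the chance that the observed spread comes from
within-study sampling alone. The heterogeneity percentage is

$$I^2 \;=\; \begin{cases} 0 & Q \le \mathrm{df} \\
  100\,(Q-\mathrm{df})/Q & Q > \mathrm{df}, \end{cases}$$

clamped at the boundary $Q = \mathrm{df}$ inclusive. The same threshold
drives model selection per gene: when $Q \le \mathrm{df}$ the
fixed-effect result is reported; otherwise the DerSimonian–Laird
random-effects model is used, with moment estimator

$$\hat\tau^2 = \max\!\Big(0,\; \frac{Q-\mathrm{df}}{\sum w_i - \sum
  w_i^2/\sum w_i}\Big)$$

and re-weighting $w_i^* = 1/(v_i + \hat\tau^2)$. Both models' results
are retained in every row (`fixed_*` / `random_*` columns) so they can
be compared after the fact. The combined p-value is the two-sided Wald
test of effect/SE against the standard Normal. Note the consequence of
the selection rule: `model == "fixed"` if and only if $I^2 = 0$.

### Significance screen

`select_significant()` applies the strict screen $p < 10^{-7}$ **and**
$|\mathrm{LFC}| > 1$ and sorts by $|\mathrm{LFC}|$. No multiplicity
adjustment is applied at this stage — the screen is deliberately a raw-p
threshold several orders below any BH cut-off at transcriptome scale —
but `add_bh = TRUE` appends a BH-adjusted column for inspection.

## Surrounding stages

**Literature overlap** (`filter_relations()`, `gene_sets()`,
`overlap_analysis()`). Relation records are kept when they carry at
least three supporting references and a specific positive/negative
polarity. The overlap of two diseases' gene sets is tested with the
right-tail hypergeometric (Fisher) probability. The gene universe is a
*required explicit argument*: literature-mining databases never state
it, printed overlap p-values are therefore irreproducible in principle,
and silently assuming a universe would launder that ambiguity into an
apparently exact number. The percentage overlap, by contrast, is
universe-free and is what the package treats as checkable.

**Dataset selection** (`select_datasets()`): the four registry
predicates — human, RNA expression, total n at least 10, case vs
healthy-control design.

**Moderator regression** (`moderator_mlr()`): per gene, OLS of the
per-study LFC on total sample size, study age (years) and country.
Country is a multi-level factor, so it is reported as a single
partial-F p-value from comparing the models with and without the
country block; continuous moderators get slope t-tests and 95% CIs.
The fit is unweighted by default (plain MLR), with
`weighted = TRUE` switching to $1/v_i$ weights. A response with zero
variance across studies is reported as "no effect" (slopes 0, p 1)
rather than dividing by a zero residual. With sixteen studies and six
countries the partial F has 5 numerator and about 8 residual degrees of
freedom — enough to detect a half-log2 country shift well above the
nominal rate, but power simulations under the package's own generative
model put it near 40–70% rather than high power; moderator results at
this scale are screening diagnostics, not confirmatory tests.

**Enrichment** (`read_gmt()`, `enrich()`): the query lists here are a
handful of unranked genes, so "GSEA" is implemented as hypergeometric
over-representation with BH-FDR across the collection (rank-based GSEA
has no meaningful input at $n = 14$). The universe defaults to the
distinct genes of the GMT collection and is overridable; FDR ties are
broken by set id so output order is deterministic.
`shared_pathway_matrix()` builds the gene-by-gene shared-set count
matrix (diagonal = sets containing the gene), and
`distinct_overlap_genes()` counts the union of genes in the top sets.

## The simulator and what it does (not) emulate

`mega_sim_config()` + `generate_collection()` produce collections whose
defaults **are** the registry conditions: 16 studies with the
registry's case/control sizes, countries and study ages. Log2
expression of a sample is Normal(baseline + group shift, `sigma2`) and
is anti-logged; the study-level shift is
`true_lfc + country/age/size moderator shifts + Normal(0, tau2)`, the
standard additive random-effects generative model. Platform coverage is
Bernoulli per gene and study (`coverage_prob`), reproducing the
"present in 15 of 16 studies" pattern of real multi-platform
collections.

Defaults chosen once and held fixed: `sigma2 = 0.25` (within-group sd
0.5 on log2, typical of array data), `tau2 = 0`, `coverage_prob = 1`,
per-gene baselines spanning log2 4–12. Everything is a deterministic
function of `seed`; each study and stage derives its own sub-seed so
studies can be regenerated independently yet reproducibly.

What it does **not** emulate: probe-level artifacts, normalization
pipelines, within-study batch effects, correlated genes, or
platform-specific dynamic ranges. Passing tests therefore demonstrate
that the estimator and pipeline are correct *under the stated model* —
calibrated type-I error, unbiased effect recovery, correct planted-gene
screening — not that any particular real collection satisfies that
model.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from `phyper`, $\chi^2$ tails from
  `pchisq`, BH from `p.adjust`, OLS from `lm` — standard library
  routines; the meta-analytic layer itself is written out explicitly
  and is cross-checked in the tests against straight-loop oracles (to
  $10^{-10}$) and against an independent meta-analysis package.
* $I^2$ clamps at $Q \le \mathrm{df}$ inclusive; $\hat\tau^2$ clamps at
  0; when $\hat\tau^2 = 0$ the random-effects result equals the
  fixed-effect result exactly.
* Odds ratios use a Haldane 0.5 correction only when a 2×2 cell is 0.
* A gene missing from a study is an absent-marker (`NULL` from
  `gene_lfc()`), not an error; a gene *present* but with an undefined
  ratio (non-positive control reference) is an error at the single-gene
  level and a logged exclusion at the collection level. Genes observed
  in fewer than `min_studies` (default 2) studies are reported in the
  fit's `skipped` table.
* Matrices are written with 17 significant digits so that
  write → read → write round-trips to identical bytes; pipeline reports
  are written atomically (temp file + rename) and stamped with the
  config hash.

## Worked example

```{r example}
cfg <- mega_sim_config(n_genes = 300,
                       true_lfc = c(rep(-1.8, 3), rep(0, 297)),
                       tau2 = 0.05, seed = 20200728)
collection <- generate_collection(cfg)
fit <- mega_analysis(collection$studies)
summary(fit)
moderator_scan(fit, genes = select_significant(fit)$gene)[1:3, ]
```

The problem sizes used throughout the test suite are of this order:
single collections of 300–2,000 genes for calibration checks, 50–200
replicate collections for recovery and screening checks — large enough
for the binomial/Monte-Carlo margins asserted, small enough to run
routinely.

## Known limitations

* The moderator regression is not a mixed-effects meta-regression; it
  ignores the differing precisions of the per-study LFCs unless
  `weighted = TRUE`, and fits no interactions.
* The literature-overlap stage can only ever be as good as the relation
  tables fed to it; the package performs no text mining and treats
  polarity/reference counts as given.
* Published overlap and enrichment p-values that depend on an unstated
  gene universe cannot be reproduced exactly by any implementation;
  the package exposes the universe as a parameter instead of guessing.
* The fixed/random choice by the $Q \le \mathrm{df}$ rule is a
  per-gene pre-test; like all pre-test estimators it can understate
  uncertainty for genes near the boundary.
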