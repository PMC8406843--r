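---
title: "Models and methods: SCFA-synthesis function analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SCFA-synthesis function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfaflow)
```

# The problem

Short-chain fatty acids (acetate, propionate, butyrate and their
branched-chain relatives) are fermentation products of the gut microbiota
with documented anti-inflammatory and cardioprotective roles. In a shotgun
metagenome case-control study one asks: does the *genetic capacity* of the
microbiome to synthesize SCFAs differ between patients (here, atrial
fibrillation, "AF") and controls ("CTR")? scfaflow implements the full
desk-scale analysis chain for that question: feature catalogs, abundance
normalization, differential testing, a group-enrichment odds ratio, sparse
biomarker scores, taxonomic attribution of enzyme genes, and mediation
analysis linking microbial function to clinical endpoints.

# Abundance model

Per sample, a gene with `r_i` mapped reads and length `L_i` (bp) gets

$$G_i = \frac{r_i / L_i}{\sum_j r_j / L_j},$$

computed **after** removing genes with `r_i < 2` (the minimum-read filter is
applied per sample, before normalization, so low-evidence genes contribute
no mass). `G` is unitless, closed to 1, and invariant to rescaling all read
counts. Feature abundances (KO, enzyme, species) are sums of their genes'
`G_i`; mass of unannotated genes is reported separately so that
`sum(features) + unmapped = 1` exactly (tested to 1e-12).

# Differential testing

Each feature is compared between groups with a two-sided Wilcoxon rank-sum
test. Numerical choices:

- exact p-values from the null rank-sum distribution when
  `min(n_x, n_y) <= 12` and the pooled data are tie-free (at the default
  cohort size of 50 + 50 the normal path is always taken);
- otherwise a tie-corrected normal approximation *without* continuity
  correction, so the p-value matches the closed-form statistic that the test
  suite evaluates independently;
- an all-constant feature yields p = 1 with a warning rather than an error.

Benjamini–Hochberg q-values use the step-up formula
`q_(i) = min_{j >= i} m p_(j) / j` capped at 1; the implementation is
order-invariant and checked element-wise against an independent
implementation. Fold change is `log2((mean_AF + c)/(mean_CTR + c))` with
pseudo-count `c` equal to half the smallest nonzero matrix entry — the zero
safe default; a median-based variant is available via `center = "median"`
because mean-vs-median is a genuinely open choice for skewed compositions.

# The OR(k) enrichment statistic

$$OR(k) = \frac{\sum_{s \in CTR} A_{sk} \big/ \sum_{s \in CTR}\sum_{i \ne k} A_{si}}
               {\sum_{s \in AF} A_{sk} \big/ \sum_{s \in AF}\sum_{i \ne k} A_{si}}.$$

Taken literally, the control group sits in the numerator, so `OR > 1` means
the feature carries relatively more pooled mass in controls. Reports in this
area are inconsistent about the sign convention (the same analysis is
sometimes described with `log2 OR > 0` meaning AF-enriched), so the
labelling is exposed as `convention = c("formula", "af-positive")` with the
literal formula as default. A pseudo-count (default 1e-12) is added **only**
to pooled sums that are exactly zero, preserving exactness on nonzero data;
the statistic is antisymmetric under label swap (`OR -> 1/OR`, exact) and
invariant to renormalized per-sample rescaling.

# Score models

`lasso_select` fits an L1-penalized logistic regression (glmnet) of group on
feature abundances. Choices that matter:

- **Penalty**: 10-fold stratified CV; the 1-SE rule by default because it
  produces the sparse models (a handful of features) this analysis style
  reports; `lambda = "min"` or a fixed numeric penalty are available.
- **Scale**: features enter raw (no standardization) by default. Published
  coefficients of such models are on the order of 10^2–10^3, which is what
  raw fractional abundances produce; `standardize = TRUE` is a flag.
- **Evaluation**: a score is plain linear arithmetic
  `intercept + sum(coef * abundance)`; model features missing from a profile
  are treated as zero abundance with a warning.

ROC AUC is the Mann–Whitney statistic (ties count 1/2) and is tested against
a brute-force all-pairs oracle. The 95 % CI uses DeLong's placement-value
variance on the natural scale; its empirical coverage in the test suite's
simulation (n = 50 + 50, true AUC 0.76) is ~0.947. Nagelkerke R² uses the
likelihood-ratio formula with probabilities clipped at the boundary (a
perfect-separation warning caps R² at 1).

**Optimism correction** follows the standard bootstrap recipe: the full
selection-plus-fit procedure is repeated on each of B case resamples
(single-class resamples are redrawn and counted); optimism is the bootstrap
model's performance on its own resample minus its performance on the
original cohort, and the mean over B is subtracted from the apparent AUC and
R². Two caveats a user should know: with hard CV selection the corrected
AUC on pure-noise data is only approximately centered on 0.5 (empty models
make the apparent AUC exactly 0.5 while bootstrap refits still measure
positive optimism, giving mild over-correction), and at small n the result
is dominated by whether CV happens to select anything at all. The acceptance
check therefore validates the correction at a cohort size (n = 400) where
the expected behavior, not selection luck, drives the outcome.

# Taxonomic assignment and harboring species

For each gene, hits within a factor 10 of the best (lowest) e-value are
retained — the boundary is inclusive, the top hit always survives, and the
operation is idempotent — and the gene is placed at the lowest common
ancestor (LCA) of the retained taxa. Ties in the top e-value need no
tie-break because the minimum is taken over all hits. The LCA implementation
is tested against a path-intersection oracle on hundreds of random trees.
E-values alone drive retention; bit scores are carried but unused, since
using them as a secondary criterion is an undocumented variant.

A species "harbors" an enzyme when at least one gene maps to both. Genes
whose LCA resolves above species rank are excluded from species-level
outputs and listed in an exclusion report — conservative and auditable,
since species-level claims should not borrow evidence from genus-level
placements.

# Mediation and VAF

With one indicator per construct, the PLS path algorithm's outer estimation
is degenerate and the inner model reduces exactly to ordinary least squares
on standardized variables: `a` from `M ~ X`, `(b, c')` from `Y ~ M + X`.
Then `indirect = a·b`, `total = c' + a·b` (an exact OLS identity — also the
slope of `Y ~ X` — tested to 1e-10 on every fit), and `VAF = indirect/total`.
VAF is invariant to affine rescaling of any variable; values outside [0, 1]
are flagged as *inconsistent mediation* rather than clamped, because
clamping would hide sign conflicts between the direct and indirect paths.
A binary outcome enters as numeric 0/1, as PLS path modeling does.
Bootstrap inference is case-resampling with percentile CIs and sign-based
two-sided p-values; degenerate resamples are skipped and counted.

# The synthetic cohort: what it emulates, what it does not

`generate_cohort` states a world mirroring the motivating study design:
50 + 50 samples, 200 candidate KOs with 10 planted at log2FC = 1, 20 species
carrying 7 SCFA-synthesis enzyme genes, and a diversity → hsCRP →
left-atrial-diameter mediation triple with paths a = 0.8, b = 0.7, c' = 0.1
and residual sd 0.5.

- Base abundances are log-normal (feature-level meanlog ~ N(0,1), sdlog
  0.5) closed to the simplex — heavy-tailed, compositional, controllable.
- Planted KOs are scaled in the AF group so the **raw** group-mean ratio is
  exactly `2^log2fc` before closure; closure then shrinks observed fold
  changes slightly (planted-KO estimates average ~0.9 rather than 1.0) and
  pushes a small compensating negative shift into all other features. That
  spillover is a real property of compositional data; it is why the
  differential false-discovery check allows (and observes) a nonzero but
  bounded FDR, and why compositional-aware tests are explicitly out of
  scope.
- Enzyme abundances are induced, not drawn: sample enzyme abundance equals
  species abundance × copy number summed over species, so the harboring
  matrix is exactly recoverable.
- The clinical path model uses plain structural equations on a standardized
  exposure with residual sd `noise_sd`; the mediator and outcome are
  standardized *at fit time*, not at generation. This keeps the closed-form
  limit `VAF = a·b/(a·b + c')` exact at every noise level, which a
  theoretical pre-standardization would break. The truth record carries both
  the structural paths and their closed-form standardized equivalents
  (`a/s_m`, `b·s_m/s_y`, `c'/s_y`); parameter-recovery tests compare
  estimates against the standardized truth, which is what a standardized
  path analysis can estimate.
- One integer seed drives a single RNG stream, so all fixtures are
  byte-reproducible.

Not emulated: sequencing error, assembly artifacts, real taxonomic
correlation structure between KO and species tables, covariate confounding,
and zero inflation beyond what log-normal closure produces. A green test on
this generator establishes correctness of the statistics on their stated
assumptions — not robustness to the messiness of real metagenomes.

# Catalog fixtures

KO membership per compound depends on the KEGG release and on whether
"participates" means reaction- or pathway-level membership; published counts
are therefore not reproducible from a frozen fixture. The packaged
compound-to-KO map (`compound_ko_map_synthetic.tsv`) uses the 13 real
compound accessions with synthetic KO identifiers and a `class` column
(SCFA/BCFA); it is explicitly labelled synthetic and is replaceable by any
TSV with the same columns. All catalog counts in tests are fixture-relative.

# Pipeline reproducibility

`run_pipeline` executes eight stages in dependency order, logs row counts,
and writes a manifest with MD5 checksums of every artifact; identical config
and seed reproduce identical checksums. A missing taxonomy degrades
gracefully (taxa stage skipped with a warning); any other failure aborts
with the stage name. On small demo cohorts the 1-SE penalty occasionally
selects nothing; the score stage then refits at `lambda.min` so downstream
stages receive a usable, non-constant score — flagged here because it is a
pipeline-level convenience, not part of the statistical method.

# Known limitations

- Wilcoxon + BH on closed compositions inherits compositional spillover
  (see above); effect directions near the detection boundary can flip.
- The optimism bootstrap at B = 100–500 with CV selection remains noisy for
  small n; treat corrected AUCs within ±0.05 of each other as
  indistinguishable.
- DeLong CIs are natural-scale and can touch [0, 1]; they are clipped, not
  logit-transformed.
- The mediation module is the single-indicator special case of PLS-SEM;
  multi-indicator measurement models and fit indices are out of scope.
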