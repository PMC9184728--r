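---
title: "Methods: extracting and characterizing decreased intragenic cohesin sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and characterizing decreased intragenic cohesin sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesintools)
```

# The problem

Cohesin (assayed through its Rad21 subunit) binds tens of thousands of sites
in a mammalian genome. After a transcriptional stimulus, a small subset of
peaks *inside the bodies of responding genes* loses intensity. Isolating
that subset — decreased intragenic cohesin sites, DICs — and separating its
enhancer-like (low-CTCF, LC) from its architectural (high-CTCF, HC)
behaviour requires a chain of quantitative steps: cross-condition peak
normalization, careful intragenic-region definitions, responsive-gene
calling, density-based subtyping, contact-map metrics and, finally,
supervised models that ask which genomic features mark a DIC. This vignette
documents how each step is modelled, which parameters matter, and what the
accompanying synthetic scenes can and cannot demonstrate.

# Differential binding: the MA model

For a peak with per-condition read densities $c_1$ (control) and $c_2$
(stimulated), scaled per million library reads and offset by a pseudocount
(default 1, so zero-count peaks stay defined):

$$A = \tfrac12(\log_2 c_1 + \log_2 c_2), \qquad M_{raw} = \log_2 (c_2/c_1).$$

Genome-wide efficiency and library effects show up as a trend of $M_{raw}$
against $A$ over peaks present in both conditions. We fit
$M_{raw} = a + b\,A$ on the matched common peaks and define the normalized
$M = M_{raw} - (a + b A)$, so the common-peak median of $M$ is ~0 and a
planted global factor $s$ on condition 2 moves only the intercept (by
$\log_2 s$), not the change calls. Classification is strict:
increased iff $M > \tau$, decreased iff $M < -\tau$, with $\tau = 0.5$.

Choices worth recording:

* **Robust fit.** Theil–Sen (median of pairwise slopes) by default, OLS as an
  option. The fit must not be dragged by the very peaks we want to call
  changed; a median-based line is insensitive to a minority of true changes.
  For more than 2,000 common peaks the slopes are computed on a
  deterministic subsample of 2,000 peaks evenly spaced in $A$ rank, keeping
  the fit reproducible and quadratic cost bounded.
* **Matching rule.** Peaks are matched across conditions by ≥ 1 bp interval
  overlap, greatest overlap winning and each peak used at most once;
  condition-unique peaks enter the union list with a zero count for the
  missing side.
* **Degenerate input.** If all common-peak $A$ are equal the slope is fixed
  at 0 and the intercept is the median $M_{raw}$ (with a warning).

# The DIC cascade

A site is a DIC iff **all four** predicates hold:

1. peak width ≤ 3,000 bp (wider peaks are ambiguous merged signals);
2. normalized $M < -0.5$;
3. the summit lies in an *intragenic region*: the gene body minus 10-kb
   flanks around both TSS and TES, only for genes longer than 20 kb
   (strict), optionally minus extra exclusion intervals such as alternative
   promoters (empty by default — no annotation source is bundled);
4. the host gene is *responsive*: elongation-signal ratio
   (stimulated/control Pol2ser2 over the gene body) strictly > 1.2 **and**
   validated by expression (log2 fold change > 0 by default; the validation
   threshold is exposed because "validated by RNA-seq" admits several
   operationalizations).

Location classes are exclusive: a summit within 10 kb of any TSS is
`aroundTSS` (the same 10-kb window as the exclusion flank, so the promoter
class and the intragenic definition cannot overlap), then `intragenic` if
inside a region, else `intergenic`. When overlapping genes compete for a
site, the nearest TSS wins. The elongation ratio is taken over the gene body
as supplied by the caller; whether promoter-proximal bins were excluded
upstream is recorded by the caller, not assumed here.

**LC/HC split.** CTCF read density in a fixed window around each DIC summit
is clustered on $\log(x+1)$ into two 1-D components (k-means from the two
extreme starting centres, deterministic); the higher-mean component is HC.
An explicit numeric cutoff overrides clustering when a study has a
calibrated threshold. Sites with very low Rad21 density can be dropped first
(`min_rad21`, default 0 — the omission threshold is a data-quality decision
the caller owns). Clustering on logs makes the split invariant to uniform
rescaling of densities.

# Contact-map metrics

All metrics are ratio- or log-ratio-based and therefore invariant to a
uniform scaling of the matrix; balancing (iterative proportional scaling to
equal covered-bin marginals) is available but not required by any of them.

* **DLR** per bin: $\log_2(\text{distal}/\text{local})$ cis contacts, local
  meaning distance ≤ `local_cutoff` (3 Mb genome-scale convention; the
  synthetic scenes use 250 kb, scaled to their 20-Mb chromosomes), both
  aggregated over a window around the anchor bin. $\Delta DLR = B - A$;
  positive means de-compaction. $\Delta DLR(A, A) = 0$ exactly.
* **ICF** per bin: inter-chromosomal / total contacts, $\Delta ICF = B - A$.
* **Insulation score** per bin: $\log_2$ of the mean of the off-diagonal
  square spanning $w$ bins up/downstream over the chromosome-wide expected
  mean at the same distance band (no smoothing — the expected model is the
  plain per-distance mean, which makes IS exactly 0 on a noiseless decay
  matrix). Boundaries are local minima below a depth threshold; bins within
  $w$ of a chromosome end are not scored.
* **APA**: sum of $(2r+1)^2$ submatrices centred on anchor-pair pixels, each
  cell optionally divided by its distance-expected value; the score is the
  centre over the mean of the $r \times r$ lower-left corner block (the
  short-distance corner, whose higher background makes the score
  conservative). Pairs closer than $2r$ bins or too near a chromosome end
  are dropped and counted. Condition comparison is a paired two-sided t test
  on per-pair central enrichment — the paired quantity is the
  distance-normalized centre pixel, chosen because it is what the aggregate
  plot displays.

Both 5-kb and 25-kb style resolutions are supported; resolution is always an
explicit argument because published compaction analyses use both within one
study.

# Statistics

Generic tests delegate to R's exact implementations: Fisher's exact test
(two-sided by the probability-mass rule: the p-value sums all tables with
fixed margins whose probability does not exceed the observed one),
hypergeometric upper-tail overlap enrichment, paired t, and
Benjamini–Hochberg adjustment. The Mann–Whitney U test enumerates the exact
permutation distribution (tie-safe) for combined samples of up to 20
observations and uses the tie-corrected normal approximation beyond that. A
site "has a loop" iff its interval overlaps either anchor by ≥ 1 bp — a set
property, so duplicated loop records cannot inflate occurrence
probabilities. Distal-anchor annotation uses the priority order promoter >
enhancer > gene body > intergenic (one class per contact; without a
priority, category percentages would not sum to 1), with the promoter window
defaulting to ±2 kb of a TSS.

# The machine-learning layer

Feature matrices carry binary 0/1 co-localization columns (≥ 1 bp overlap)
and z-scored continuous columns, with the normalization constants retained
so a second cell type can be scored on the identical scale. The supervised
model is plain logistic regression,
$P(Y_i = 1 \mid X_i) = 1/(1 + e^{-(\beta_0 + \sum_j \beta_j X_{ij})})$,
optionally L1/L2-penalized; importance is the signed coefficient (comparable
across features because the features are standardized or binary; collinear
duplicated features split weight between them — a caveat, not an error).

* **Held-out discipline.** Evaluation rows live on held-out chromosomes
  (e.g. chr16–22); the remaining rows are split into 5 CV folds of
  near-equal size. SMOTE is applied to training folds only — synthetic
  minority rows are interpolations $x_i + u\,(x_{nn} - x_i)$,
  $u \sim U(0,1)$, between a minority row and one of its $k = 5$ nearest
  minority neighbours, binary columns re-rounded, classes balanced exactly.
  By construction synthetic continuous coordinates stay within the minority
  per-axis range.
* **Metrics.** AUROC via the rank statistic (the Mann–Whitney identity,
  ties averaged) plus average precision and a 0.5-threshold confusion
  matrix; one-class test sets yield a missing AUROC rather than a number.
* **Elastic net.** For a continuous response (the normalized M value of
  intragenic sites), minimize
  $\frac{1}{2n}\sum_i (y_i - x_i'\beta)^2 + \lambda\left(\frac{1-\alpha}{2}\|\beta\|_2^2 + \alpha \|\beta\|_1\right)$
  with $\alpha = 0.5$, over glmnet's $\lambda$ path with 5-fold CV. The
  default $\lambda$ is the **one-standard-error** choice: the goal of this
  step is feature *selection*, and the CV-minimum $\lambda$ systematically
  keeps an order of magnitude more noise features (on the planted 5-of-100
  benchmark: 9–17 false positives at the minimum vs ≤ 1 at one-SE, with the
  five true features always retained by both). The CV-minimum rule remains
  available as `lambda_choice = "min"`. The returned solution is polished by
  coordinate descent until the subgradient optimality residual of the loss
  above is below 1e-8, and the residual is reported; at $\lambda = 0$ this
  polish converges to the least-squares solution. Surviving features get a
  univariate OLS fit $Y = a + bX$ whose slope sign is the reported
  direction of association.
* **Cross-cell-type prediction** refits an L1 logistic model on the shared
  feature subset, predicts on the second cell type, and scores the overlap
  of predicted and experimental calls with an upper-tail hypergeometric
  test. Feature-name mismatches are hard errors; silent subsetting would
  invalidate the shared normalization.

# The synthetic scenes

The generator exists so that every stage has planted ground truth. The
default scene is desk-scale: 2 chromosomes × 20 Mb, 300 non-overlapping
genes of 25–120 kb, 3,000 cohesin sites (1,000 around TSSs, 1,200
intragenic, 800 intergenic), 30% responsive genes, 100 planted DICs at fold
change 0.5, ~25% of them HC — sized so the full pipeline runs in minutes on
one CPU. Seeds fan out per stage from a single scene seed, so identical
parameters give identical scenes.

* **Peak counts** are negative binomial around a log-normal site baseline
  with variance $(1 + d)\,\mu$ — `nb_dispersion` $d$ is the extra-Poisson
  variance fraction, so $d = 0$ is Poisson and the default $d = 0.1$ gives
  mild overdispersion (count CV ≈ 7% at the median baseline of 200). This
  parameterization is deliberate: it keeps the dispersion's meaning stable
  across baselines, and it represents the between-condition technical noise
  of a single matched comparison rather than between-replicate biological
  variability (which a quadratic-variance dispersion would model). Planted
  DICs multiply the condition-B mean by the fold change; a global
  `library_factor` multiplies all condition-B means to emulate library-size
  imbalance.
* **CTCF densities** are a two-component log-normal mixture (16-fold mean
  separation by default) with the component pinned to the planted subtype at
  DICs; TF co-binding columns are Bernoulli with class-dependent
  probabilities (enhancer marks high on LC, CTCF co-binding high on HC).
* **Contact maps** are Poisson over a power-law decay
  $\mu \propto (1+d)^{-1}$, with loops as pixel-mean multipliers, insulation
  boundaries as a single ×0.1 attenuation for any pair separated by a
  boundary (attenuation is deliberately not compounded across multiple
  boundaries — compounding would drive all long-range counts to zero, which
  neither real Hi-C nor the distance-expected normalizations tolerate), and
  de-compaction as moving a fraction of a bin's local contact mass to its
  distal positions. Condition B shares condition A's counts through exact
  Poisson coupling (binomial thinning where means drop, extra Poisson mass
  where they rise), so pixels with unchanged means are identical across
  conditions and a scene with nothing planted yields two equal maps — the
  clean null against which ΔDLR, ΔICF and the APA comparison are read.
* **Feature matrices** are standard normal with informative columns shifted
  by a stated effect size for class-1 rows, plus a sparse linear response at
  a stated signal-to-noise ratio and uniform chromosome labels for held-out
  splits.

**What passing tests show — and what they do not.** The scenes validate the
*logic and calibration* of the pipeline: that normalization absorbs global
factors, that the DIC predicates compose correctly, that planted compaction,
boundary and loop structure is recovered at the stated strengths, and that
the ML layer finds planted feature structure without leaking held-out rows.
They do not reproduce real-data difficulty: real ChIP-seq has peak-calling
artifacts, copy-number and mappability biases, and replicate-level
biological variability; real Hi-C has fragment-level and visibility biases
that balancing only partly removes; and real feature catalogs are heavily
correlated across assays. Numbers such as "sensitivity 1.0 at fold change
0.5" therefore bound what the method can do under its own model, not what
it will achieve on sequencing data.

# Numerical and degenerate-input policy

Intervals are 0-based half-open everywhere internally; 1-based dialects are
converted at I/O and round-trip losslessly. DLR and IS are reported missing
(NA) when a required sum is zero rather than ±Inf; ICF is missing for bins
with no contacts; single-site metaprofiles report a zero-width CI with a
warning; a two-site LC/HC input splits at the larger density; Fisher tables
with a zero margin return p = 1 with a warning; identical-map APA
comparisons return statistic 0, p = 1 without calling the t distribution on
a zero-variance difference. Matrix balancing excludes zero-marginal bins and
errors (with the residual) if it fails to converge. All tolerances used by
the test suite are stated in the tests themselves; the problem sizes there
(scenes as above; 2,000 × 50–100 feature matrices; 50 small null map pairs)
were chosen as the smallest sizes at which the planted effects are
comfortably identifiable.
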