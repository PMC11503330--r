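---
title: "Triage of peptide-array antibody signals: models and methods"
author: "pepforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of peptide-array antibody signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepforest)
```

## The problem

High-density peptide arrays tile a proteome into short overlapping peptides
(here 16-mers at 2-residue steps, so adjacent probes share 14 residues) and
measure serum IgG binding to every probe at once. With millions of peptides
and group sizes of 8–16 subjects per arm, the screen produces many apparent
disease-specific signals, and each candidate must be confirmed by ELISA — a
slow, per-peptide assay. The question this package answers is not "which
peptides differ between groups" but the more operational one: *which
array hits will survive ELISA validation?*

A peptide counts as confirmed when it meets three empiric criteria:

* **correlation** — Spearman correlation between array intensity and ELISA
  absorbance across subjects strictly greater than 0.6;
* **fold** — ratio of disease to control mean absorbance at least 5;
* **p-value** — two-sided rank-sum p-value at most 0.1.

`pepforest` computes nine per-peptide array features, trains one random
forest per criterion on a small ELISA-labeled panel, and thresholds the
three predicted probabilities into a candidate set.

## The nine array features

For a disease-versus-control contrast, `compute_features()` produces, per
peptide:

| feature | definition |
|---|---|
| `fold` | ratio of arithmetic group means of raw intensity, denominator floored at 1 |
| `rvalue` | empirical-Bayes effect-size rank (below) |
| `locfdr` | empirical-Bayes local false discovery rate (below) |
| `prop_exp` | fraction of disease subjects with intensity \(\ge \mu + 3\sigma\) |
| `prop_con` | fraction of control subjects with intensity \(< \mu + 3\sigma\) |
| `fold_nn`, `locfdr_nn`, `prop_exp_nn`, `prop_con_nn` | the same quantity averaged over the two tiling-adjacent peptides |

\(\mu\) and \(\sigma\) are the mean and *population* standard deviation
pooled over every cell of the intensity matrix; the threshold
\(T = \mu + 3\sigma\) is a whole-array high-signal cut (on the array that
motivated this design it came to 1047.4 raw fluorescence units). The
nearest-neighbor (NN) averages exploit the tiling: a real linear epitope
spans several overlapping probes, so its neighbors are bright too, whereas
an isolated bright probe is usually artifact. NN averaging excludes the
central peptide; terminal tiles take their single neighbor's value, and
neighbor-less peptides (non-tiled probe sets) fall back to their own value.

Two readings of the `prop_con` footnote are possible ("below 3 standard
deviations of the mean"): strictly below \(\mu + 3\sigma\), or below
\(\mu - 3\sigma\). We default to the former — the complement criterion to
`prop_exp` — because a single threshold is quoted for the array and
\(\mu - 3\sigma\) is negative for typical raw fluorescence distributions,
making that criterion vacuous. The alternative remains available via
`propcon_mode = "below_low"`.

`fold` is computed on raw (not log) group means, matching the raw-scale
threshold; the denominator floor of 1 raw unit keeps dark control signals
from exploding the ratio.

## Large-scale inference: locFDR and r-values

Per-peptide two-group statistics are Welch t-statistics on
\(\log_2(\text{intensity} + 1)\) (raw fluorescence is heavy-tailed;
the log transform makes the normal sampling model tenable). Standard
errors below the 1st percentile of all standard errors are raised to that
percentile so zero-variance rows cannot produce infinite z-values.

**locFDR.** `estimate_locfdr()` fits a nonparametric mixture to the
(effect, se²) pairs under the sampling model

\[
\hat\theta_i \mid \theta, \sigma^2 \sim N(\theta, \sigma^2), \qquad
s_i^2 \mid \sigma^2 \sim \sigma^2\,\chi^2_{d_i}/d_i ,
\]

with the mixing distribution supported on a product grid: a symmetric
effect grid with a dedicated point at exactly 0 (carrying the null mass)
and a log-spaced variance grid spanning the observed se² range. Weights are
maximum-likelihood estimates found by EM (the log-likelihood is monotone
per iteration and asserted as such in the tests). The local false
discovery rate of peptide *i* is the posterior probability that its true
effect is zero.

One numerical choice matters here: the spacing of the effect grid. Nonzero
magnitudes are log-spaced from a *noise floor* — twice the median standard
error — up to the largest observed effect. Grid points closer to zero than
the measurement noise are statistically indistinguishable from the null;
if present, the NPMLE diffuses genuine null mass into them and the locFDR
loses its calibration (in pure-null simulations the null weight drops from
~0.99 to ~0.86 with uniformly spaced points). Effects below the noise
floor are deliberately absorbed into the null point: that is what "null"
can mean at this measurement precision.

**r-values.** `compute_rvalues()` ranks peptides by how confidently their
effect sits in the upper tail of the effect population. A normal-normal
hierarchical model \(\theta_i \sim N(m, \tau^2)\),
\(\hat\theta_i \sim N(\theta_i, s_i^2)\) is fitted by marginal maximum
likelihood; the r-value of peptide *i* is the smallest \(\alpha\) on a grid
(0.001–0.999) such that

\[
P\!\left(\theta_i > q_{1-\alpha} \mid \hat\theta_i\right) \ge 1 - \alpha,
\]

where \(q_{1-\alpha}\) is the \((1-\alpha)\) quantile of the fitted
\(N(m, \tau^2)\). Small r-values mean strong evidence of a large effect;
because the posterior shrinks noisy estimates, a high-variance peptide
cannot earn a small r-value on a large point estimate alone. Under equal
standard errors the r-value ordering coincides with the effect ordering.

Both estimators deliberately are desk-scale variants built behind a common
interface, so alternative empirical-Bayes machinery can be swapped in; they
require at least 50 peptides, since empirical-Bayes borrowing is meaningless
without scale.

## The validation predictor

`validation_model()` fits three independent binary random forests (one per
ELISA criterion) over the nine features, using the conventional defaults of
the field's standard implementation: 500 trees, \(\sqrt{p}\) features per
split, minimum node size 1, all seedable. Predicted probabilities are
fractions of trees voting for the positive class. The three outcomes are
modelled independently because the workflow reports three separate
probabilities per peptide and combines them only at selection time.

`cross_validate()` measures performance by repeated stratified 70/30
splits (500 repeats by default; the examples and acceptance checks use 50
to keep runtimes in seconds). A split whose test fold is single-class is
resampled — with ~70 labeled peptides and unbalanced outcomes this
otherwise breaks the AUC. Single-feature AUCs are computed by refitting a
one-feature forest on the same splits; a `feature_auc_mode = "raw"` option
scores the oriented raw feature instead (locFDR and r-value are negated so
that larger always means more likely to validate). A feature block with no
variation cannot be split on and is scored 0.5 directly.

Two selection rules are implemented: `all_exceed` keeps a peptide when all
three probabilities exceed the threshold (0.5 in validation use), and
`mean_exceeds` keeps it when their mean exceeds the threshold (0.75 in
conservative discovery use). For any common threshold the first rule
selects a subset of the second, and both are monotone in the threshold.
`enrichment_report()` then compares the citrulline ('B') and
homocitrulline ('Z') content of the selection against the whole library —
the standard sanity check for contrasts dominated by
anti-citrullinated-protein responses.

## The synthetic study generator

No array of this kind can ship with a package, so every stage is exercised
against `simulate_study()`, which generates:

* a random proteome (330 proteins of 280–320 residues by default,
  arginine frequency 0.05, lysine 0.06), tiled into 16-mers at step 2
  (~50,000 peptides); 5% of proteins also appear as a citrullinated
  series, putting the library's citrulline-containing fraction near the
  few-percent scale typical of modified-probe sets;
* i.i.d. log-normal background fluorescence (meanlog 6.2, sdlog 0.3),
  calibrated so that roughly 0.3–1% of cells exceed \(\mu + 3\sigma\) —
  an array where the high-signal threshold is informative rather than
  vacuous;
* 24 planted antigens, each spanning 3–5 *consecutive* tiles of one
  (protein, series) — so the NN features are informative by construction —
  multiplying intensities by 8–16× for a 75% responder subset of the
  8 disease subjects (not every patient binds every antigen, which is
  exactly why `prop_exp` is a proportion rather than a group test);
  16 control subjects are untouched;
* ELISA absorbances for a labeled panel (70 peptides, half planted), with
  \(\mathrm{OD} = \max(0,\; 0.2 + 0.6\,z + \varepsilon)\), where *z* is the
  peptide's standardized array intensity and
  \(\varepsilon \sim N(0, 0.05^2)\). The coupling applies only to peptides
  whose ground truth flags them ELISA-valid; artifactual signals reproduce
  nothing and get baseline noise. Under these defaults planted peptides
  meet all three empiric criteria in well over 90% of draws, and with
  `coupling_slope = 0` all pass rates collapse to their null levels.

Everything is reproducible per seed through R's default Mersenne-Twister
stream.

What the generator does *not* emulate: sequence-dependent antibody
affinity, inter-array batch effects, plate effects and blank subtraction in
the ELISA, or correlated background across subjects. Passing tests
therefore demonstrate that the pipeline recovers planted truth under its
own assumptions — they say nothing about antigenicity in real sera, and
feature utilities observed here (e.g. near-perfect separation by
`prop_exp`) will be less clean on real arrays.

One consequence of an honest null: a fully null study (no planting, zero
coupling) produces single-class training labels, and no classifier can be
fitted on it. The null behavior of the *pipeline* is therefore assessed by
training on the default strong-signal study and scoring fresh null arrays,
which selects essentially nothing across seeds.

## Worked-example panels

Three small validation panels ship under `inst/extdata` (COVID-19
convalescent vs naive; lupus vs all others; spondyloarthropathy vs all
others), each with published per-peptide predicted probabilities and
empiric ELISA summaries. They pin down the exact semantics of the
criteria (strict > for correlation, inclusive ≥ and ≤ for fold and
p-value) and of the two selection rules:

```{r panels}
covid <- validation_panel("covid")
select_peptides(covid, selection_rule("all_exceed", 0.5))$peptide_id
```

## Numerical and degenerate-input choices

* Rank-sum p-values are exact (classical null distribution) when both
  groups have ≤ 10 observations without ties; with ties, forced-exact mode
  enumerates group reassignments fully (capped at 2×10⁵ arrangements);
  otherwise a normal approximation with tie and continuity corrections is
  used. "Wilcoxon" and "Mann–Whitney" here are the same two-sample test,
  two-sided throughout.
* A constant vector has no rank ordering: Spearman correlation returns NA
  with a warning and downstream criteria count it as a failed correlation.
* The ELISA fold denominator is floored at 0.001 OD; the array fold
  denominator at 1 raw unit. Both are arithmetic means (ratios of medians
  are a defensible alternative; means were chosen and fixed).
* AUC follows the Mann–Whitney U formulation with ties counted ½, and is
  undefined (an error) for single-class labels.
* EM convergence is declared at a relative log-likelihood change of 1e-8,
  capped at 5000 iterations; hitting the cap warns and returns the best
  iterate.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the default ~50,000-peptide study
once, 70-peptide labeled panel, 50 cross-validation repeats; empirical-
Bayes calibration uses 2000-peptide simulations (one pure-null array at
8 vs 8, twenty two-point-mixture replicates). These sizes were chosen so
each property is measured at a scale where its expected behavior is
unambiguous while a full run stays in the minutes range on one CPU. The
permutation-null band for the cross-validated AUC is measured as the mean
over five label permutations: a single permutation of 70 labels can sit
a few AUC points off 0.5 by chance alone.

## Known limitations

* The locFDR and r-value implementations are faithful in spirit to the
  published empirical-Bayes tools they stand in for, not bit-for-bit
  re-implementations.
* The three outcome models are independent; correlated outcomes (a peptide
  failing fold usually also fails correlation) are not exploited.
* No inter-array normalization or probe QC: inputs are assumed quantified
  and comparable.
* Motif discovery is out of scope; selections are exported as FASTA for
  external motif tools.
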