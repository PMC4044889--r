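---
title: "Methods: panel discovery under a three-way data split"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel discovery under a three-way data split}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge discovers fixed-size multi-protein biomarker panels from
case/control plasma proteomics intensity tables. This vignette records the
statistical model, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The per-protein mixed model

Each protein is modelled separately on the log2, quantile-normalized
scale. For replicate injection $i$ of biological sample $k$ in group $j$
(cancer or control),

$$ y_{ijk} = \mu + T_j + S_k + I_i + \varepsilon_{ijk}, \qquad
   S_k \sim N(0, \sigma_2^2),\;
   I_i \sim N(0, \sigma_1^2),\;
   \varepsilon_{ijk} \sim N(0, \sigma^2), $$

with a fixed group effect $T_j$ and mutually independent random effects.
The assumptions that matter are (i) normality of all random terms on the
log2 scale, (ii) samples nested in groups and replicates nested in
samples, and (iii) no cross-protein correlation — each protein is screened
marginally.

**Identifiability.** A protein-level table carries one number per
injection, so the replicate effect $I_i$ and the residual
$\varepsilon_{ijk}$ are confounded: only their sum is observable.
`fit_protein_anova()` therefore estimates the pooled within-sample
variance $\sigma_1^2 + \sigma^2$ (`var_residual`) and tests the group
effect against the *sample-within-group* stratum:
$F = \mathrm{MS}(\text{group})/\mathrm{MS}(\text{sample within group})$
with degrees of freedom $(g-1,\, N_s-g)$, computed on per-sample replicate
means. On balanced data this is exactly the classical nested ANOVA F for a
fixed effect above a random nested factor, and under the null it is exactly
F-distributed, which the suite verifies by a Kolmogorov–Smirnov uniformity
check on simulated null p-values. Between-sample variance $\sigma_2^2$
(`var_sample`) comes from expected mean squares, truncated at zero. The
naive injection-level one-way ANOVA — anticonservative whenever
$\sigma_2^2 > 0$, because replicate injections are pseudo-replicates — is
available via `denominator = "residual"` for comparison, never as the
default.

**Screening.** Candidates are proteins with raw $p < \alpha$
($\alpha = 0.01$ by default) on the *training study only*, after
restricting to proteins common to all three studies. No multiple-testing
correction is applied by design: the screen is a candidate filter feeding a
wrapper selection, not an inference procedure. Candidate order (ascending
p, ties by descending $|\hat T|$, then id) fixes the panel enumeration
deterministically.

## Preprocessing

`log2_transform()` requires strictly positive intensities and errors
otherwise, naming the offending protein and injection — silent clamping
would hide upstream quantification failures. `quantile_normalize()` forces
all injection columns of one study to a common empirical distribution: the
reference is the across-column mean of each column's sorted values; tied
entries receive the mean of their tied ranks' reference values; missing
entries are excluded from ranking and stay missing, with shorter columns
mapped onto the reference by linear interpolation of quantiles. Studies
acquired at different times are normalized separately and never
co-normalized; cross-study batch correction is deliberately out of scope,
because the three-way split treats each study as an independent
acquisition.

## The classifier

Each candidate panel of $N$ proteins feeds a feed-forward neural network
with one hidden layer, logistic sigmoid activations throughout, and a
two-node output using the two-variable encoding cancer $=(1,0)$, healthy
$=(0,1)$. Classification operates at the biological-sample level: each
sample's feature vector is the mean over its replicate injections.

Parameters, defaults and rationale:

* **hidden size** — `floor((N + 2)/2)`, clamped to at least 2: the
  between-input-and-output rule of thumb (3 hidden nodes for a five-marker
  panel).
* **loss** — total sum of squared errors against the target encoding;
  **training** — full-batch gradient descent (the analytic backprop
  gradient is exported as `ffnn_gradient()` and verified against central
  finite differences in the suite).
* **learning rate 0.05, max 300 epochs** — on standardized inputs and
  $\le 80$ training samples this converges well inside the budget;
  divergence raises an error naming the epoch rather than returning NaNs.
  A rate of 0 is allowed and leaves the initial weights untouched.
* **input standardization on** (training-set mean/sd, stored on the model
  and reapplied at prediction) — sigmoid units saturate on raw log2
  intensities around 20.
* **weight init** — Uniform($-w$, $w$), $w = 1/\sqrt{\text{fan-in}}$,
  seeded; all randomness flows through one integer seed, and per-panel
  seeds are derived by hashing the global seed with the panel's protein
  ids, so serial and parallel evaluation orders give identical results.
* **score** — `cancer_output - healthy_output` $\in (-1, 1)$, with class
  cancer iff score $> 0$ (exact ties predict control). The symmetric
  difference honours the two-variable encoding and is monotone in both
  outputs; thresholding it at 0 is provably the same as taking the larger
  output node, which the suite checks on random networks.

**Epoch budget by cross-validation.** For each panel, stratified 5-fold
cross-validation on the training study records the held-fold AUC every 5
epochs; the budget is the epoch maximizing mean held-fold AUC, and the
final network is retrained on the full training study for that many
epochs. Two open choices were resolved as follows. First, the selection
statistic for panels is the *retrained model's validation AUC* (the
CV-averaged AUC is also stored on every candidate). Second, AUC plateaus —
on separable data the held-fold AUC reaches 1.0 within a few epochs and
stays there — so "smallest epoch at the maximum" systematically
undertrains, leaving outputs near (0.5, 0.5) and a poorly calibrated
threshold-0 classifier even though ranking (AUC) is fine. Exact AUC ties
are therefore broken by the smaller mean held-fold SSE, then by the
smaller epoch: held-out SSE keeps improving while calibration improves,
and it is measured on the same held-out data, so the tie-break introduces
no new information leak.

## Panel search and the three-way split

All $\binom{m}{N}$ panels from the candidate pool are enumerated in
lexicographic candidate order and evaluated; $C^*$ is the panel maximizing
validation-study AUC, with ties broken by lower training SSE, then
lexicographic ids — every tie rule in the package is deterministic so
identical configurations give byte-identical reports. The testing study is
read exactly once, by `assess_on_test()` on $C^*$; a shared injection id
between testing and training/validation raises a leakage error. The full
$\binom{32}{5} = 201\,376$ enumeration is a supported long-running mode;
the default `pool_cap = 10` keeps desk-scale runs and the test suite in
seconds (the compiled training loop evaluates a panel, 5 CV folds plus the
final retrain, in roughly 10–30 ms).

Why the split matters is itself a testable claim: with pure-noise panels,
choosing the panel that maximizes *test* AUC inflates the apparent test
AUC well above chance, while the panel chosen on validation data scores at
chance on the test study. The acceptance suite measures this gap over 50
simulated repetitions and requires it positive at the 95% Monte-Carlo
level. Mixing studies into one pool is intentionally unsupported outside
that harness.

## The synthetic-data generator

`simulate_study()` draws from exactly the mixed model above: independent
normal sample, replicate and residual effects per protein, plus a constant
log2 shift (`effect_size`) added to the cancer group of informative
proteins. `simulate_three_studies()` produces the canonical 40/40, 40/40,
20/20 layout (study C half-sized) with a shared protein core of
`overlap_fraction` and study-specific remainders, informative proteins
always inside the core.

Defaults are the stated world of the package's tests: 40/40 samples, 2
replicate injections, grand mean $\mu = 20$ (a typical log2 intensity for
moderately abundant plasma proteins), $\sigma_2^2 = 1.0$,
$\sigma_1^2 = 0.25$, $\sigma^2 = 0.25$ — biological variation dominating
technical, at a realistic 2:1 ratio of biological to total technical
variance; no published variance components exist for the motivating
studies, so these are package choices, fixed once. Planted effects default
to 2 log2-units, and recovery benchmarks express effects in units of
$\sigma_{\text{total}} = \sqrt{\sigma_2^2 + \sigma_1^2 + \sigma^2}$.

What the generator does **not** emulate: peptide-level structure,
intensity-dependent missingness, retention-time drift, cross-protein
correlation, heavy-tailed outliers, or batch effects between studies. A
green end-to-end test therefore establishes that the pipeline recovers
planted signal under its own model assumptions — not that it is robust to
real-data pathologies outside them.

## Numerical choices and degenerate inputs

* Missing cells (`NA` or empty token) are excluded from quantile ranks and
  ANOVA cells; a protein whose remaining design is unfittable is skipped
  with a warning during screening, not an error.
* ANOVA: zero denominator MS with zero numerator gives $F = 0, p = 1$;
  with positive numerator, $p = 0$ with a `degenerate` flag.
* Metrics with zero denominators (e.g. precision with no predicted
  positives) are `NA`, never 0; percentages are kept at full precision and
  rounded to two decimals only for display, AUC to four.
* ROC construction groups tied scores into single vertices (diagonal
  segments), making the trapezoidal area exactly the Mann–Whitney
  statistic with the ½-tie convention — the suite checks this equality to
  1e-12 on a thousand random instances.
* All file formats are plain text; reports round-trip through
  `read_report()` and serialized models through `read_ffnn_model()`.

## Known limitations

* The nested F-test's Satterthwaite-style handling of unbalanced replicate
  counts is approximate (one-way ANOVA on per-sample means); it is exact
  only under balance, which both the motivating design and the generator
  satisfy.
* With one injection per sample (`n_replicates = 1`) the pooled
  within-sample variance is not estimable and is reported as `NA`; the
  group F-test remains valid.
* The exhaustive search is $O(\binom{m}{N})$ network trainings; beyond
  `pool_cap` ≈ 15 at $N = 5$ it needs the long-running mode and patience.
* Panel selection maximizes a single statistic (validation AUC) on a
  finite validation study; near-ties among top panels are expected and the
  full ranking is always written to the report rather than guessing a
  unique winner.
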