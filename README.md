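# panelforge

Multi-biomarker panel discovery for case/control plasma proteomics.

## The problem

Label-free LC-MS/MS plasma profiling yields a protein-by-injection table of
intensities for each study. Single plasma proteins rarely separate cancer
from healthy samples well; small *panels* of proteins, fed jointly into a
classifier, can. But panels selected by peeking at the final evaluation
data look better than they are: if the "best" panel is the one that
maximizes AUC *on the test set*, the reported test AUC is an optimistic,
selection-biased estimate. panelforge implements the disciplined
alternative — a strict three-way data split:

* a **training** study fits the classifier weights,
* a **validation** study chooses among panels,
* a **testing** study is touched exactly once, to report the final numbers.

## The method

For each protein *p*, measured intensity of replicate injection *i* of
sample *k* in group *j* is modelled as a nested mixed model on the log2,
quantile-normalized scale:

```
y_ijk = mu + T_j + S_k + I_i + e_ijk
S_k ~ N(0, sigma2^2),  I_i ~ N(0, sigma1^2),  e_ijk ~ N(0, sigma^2)
```

with fixed group effect `T_j` and independent random sample, replicate and
residual effects. Candidate markers are proteins whose group effect is
significant at raw p < 0.01 by the nested ANOVA F-test
(`F = MS(group) / MS(sample-within-group)`), applied to the proteins common
to all three studies. Every `choose(m, N)` panel of `N` candidates (N = 5
by default) is then scored by a small feed-forward neural network
(`N`–`floor((N+2)/2)`–`2`, logistic sigmoid, two-variable output encoding
cancer = (1,0) / healthy = (0,1)) trained by full-batch backpropagation on
the sum of squared errors, with a 5-fold cross-validated epoch budget. The
selected panel is

```
C* = argmax_C AUC(NET_C, V)
```

the panel whose network maximizes ROC AUC on the validation study `V`.
Finally C* alone is assessed on the testing study: confusion matrix,
sensitivity, specificity, precision, accuracy and AUC.

Because the clinical plasma studies this design mirrors were never
deposited, the package ships a synthetic-data generator
(`simulate_three_studies()`) that draws studies of the canonical shape
(40/40, 40/40, 20/20 samples; replicate injections; partial protein
overlap) from exactly the model above, with planted differential proteins
as ground truth.

## Worked example

```r
library(panelforge)

sim <- simulation_config(n_proteins = 100, n_informative = 8,
                         effect_size = 1.0, seed = 42)
cfg <- pipeline_config(sim_config = sim, N = 5, pool_cap = 10, seed = 42)
res <- run_pipeline(cfg, verbose = TRUE)
#> [load] loaded studies A,B,C
#> [normalize] quantile-normalized 3 studies
#> [intersect] 100 proteins common to all studies
#> [screen] 7 candidates at p < 0.01
#> [search] 21 panels evaluated; C* = [P0007;P0008;P0004;P0005;P0006]

print(res)
#> <search_result> 21 panels evaluated (N = 5)
#>   C* = [P0007;P0008;P0004;P0005;P0006], validation AUC 0.9950
#>   test: accuracy 83.75%, AUC 0.8894
```

Eight differential proteins (a 1 log2-unit cancer shift) were planted among
100; the screen found 7 candidates at p < 0.01, all 21 five-marker panels
were evaluated, and the selected panel consists entirely of planted
markers. The one-shot test assessment of C* (40 cancer / 40 control
samples the search never saw):

```r
res$cstar$test_metrics$metrics$testing
#> sensitivity 85.00%, specificity 82.50%, precision 82.93%,
#> accuracy 83.75%, AUC 0.8894   (confusion: tp=34 fp=7 fn=6 tn=33)
```

The validation AUC (0.995) is higher than the test AUC (0.889): that gap is
the selection bias the three-way split exists to keep out of the reported
numbers.

A command-line interface covers the same stages
(`inst/cli/panelforge {simulate, normalize, screen, run}`), e.g.

```sh
Rscript inst/cli/panelforge run --out results_dir --seed 42 \
    --n-proteins 100 --n-informative 8 --panel-size 5 --pool-cap 10
```

writes a ranking report (`report.txt`) and a reproducibility manifest
(`manifest.json`).

## Scope

Upstream spectral processing (peak picking, label-free quantification,
database search), pathway analysis, and batch-effect correction across
studies are out of scope: panelforge starts from protein-level intensity
tables and ends at the assessed panel.
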