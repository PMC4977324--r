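# wntbn

Discrete Bayesian network analysis of Wnt pathway epigenetics in
colorectal cancer.

## The problem

Canonical Wnt signaling is hyperactive in most colorectal tumors: the
β-catenin/TCF4/LEF1 transcription complex (*TRCMPLX*) drives targets such
as *MYC*, *CCND1* and *CD44*, while the pathway's extracellular inhibitors
(*SFRP1–5*, *DKK1–4*, *WIF1*) and intracellular antagonists (*DACT1–3*)
are silenced by promoter hypermethylation and, for *DACT3*, a bivalent
histone configuration (H3K27me3 + H3K4me3). Expression panels over these
genes are often used to classify tumor versus normal tissue — implicitly
assuming that "sample is tumorous" and "transcription complex is active"
are the same event.

`wntbn` implements the causal-model family that tests that assumption.
Tissue status (`Sample`) and complex status (`TRCMPLX`) are separate
binary latent variables in a directed acyclic graph; gene expression,
methylation and histone nodes connect to them through
literature-derived arcs. Three variants are built:

| variant | content | nodes |
|---------|---------|-------|
| `t1` | prior biological knowledge + epigenetic nodes | 34 |
| `t2` | prior biological knowledge only | 23 |
| `p1` | naive-Bayes star (all genes under *TRCMPLX*) | 21 |

Each gene node's conditional probability table is estimated from training
data: expression is discretized at the per-gene training median,
cross-tabulated against class (and methylation state where applicable),
weighted by an assumed transcription-complex effect `etgn` (default 0.9),
and pseudo-count smoothed. Non-gene nodes carry fixed printed parameters
(50/50 `Sample` prior, normalized wet-lab methylation/histone fractions,
0.99/0.01 interaction tables). Inference is exact (variable elimination,
verified against a brute-force enumeration oracle). Validation is an
exhaustive 2-holdout: every (normal, tumor) pair in turn becomes the test
set — 576 iterations for a 24 + 24 cohort — and the per-sample posteriors
Pr(TRCMPLX = active | gene evidence) and Pr(Sample = tumor | gene
evidence) are scored by ROC/AUC and compared by a two-sample
Kolmogorov–Smirnov test.

The study's expression matrix is not publicly deposited, so the package
includes a synthetic cohort generator: ancestral sampling of the full
epigenetic network under the packaged parameters with class composition
clamped, and a two-component Gaussian expression emitter.

## Worked example

```r
library(wntbn)

# worked posteriors under the printed parameters
net <- reference_network()
posterior_marginal(net, c(DACT3 = 1L), "DVL2")[2]     # 0.99
posterior_marginal(net, c(TCF4 = 2L, LEF1 = 2L, BETACAT = 2L),
                   "TRCMPLX")[2]                      # 0.99

# synthetic 24+24 cohort, full epigenetic model, exhaustive holdout
cohort  <- generate_cohort(generator_config(seed = 1))
results <- run_ge_experiment(cohort$dataset, variant = "t1")
results
#> # A tibble: 1,152 × 6
#>   iteration test_idx sample true_label pr_trcmplx pr_sample
#>       <int>    <int> <chr>       <dbl>      <dbl>     <dbl>
#> 1         1        1 s1             -1    0.00949     0.175
#> 2         1       25 s25             1    0.0713      0.799
#> 3         2        1 s1             -1    0.00944     0.195
#> 4         2       26 s26             1    0.0144      0.496
#> # ℹ 1,148 more rows

glance(evaluate_holdout(results))
#> # A tibble: 1 × 6
#>       n auc_trcmplx auc_sample ks_statistic ks_p_value ks_h01
#>   <int>       <dbl>      <dbl>        <dbl>      <dbl>  <int>
#> 1  1152       0.620      0.950        0.917          0      1
```

Reading the output: each holdout iteration contributes one row per test
sample. On this synthetic cohort the `Sample` posterior separates the
classes well (AUC 0.95), while the segregated `TRCMPLX` posterior tracks
them far more weakly (AUC 0.62) — the model's way of saying that, under
these parameters, an active transcription complex is *not* simply
synonymous with a tumorous sample. The KS flag `h01 = 1` confirms the two
prediction distributions differ. `autoplot()` methods draw the ROC curve
(`autoplot(compute_roc(...))`) and the posterior histograms
(`autoplot(results)`); `run_pipeline(run_config(...))` wires
simulate-or-load → holdout → evaluate together and writes CSV/JSON
artifacts.

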