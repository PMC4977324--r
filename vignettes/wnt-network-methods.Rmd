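---
title: "Modeling the Wnt pathway with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the Wnt pathway with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntbn)
```

## The scientific question

In colorectal cancer the canonical Wnt pathway is typically hyperactive:
the β-catenin/TCF4/LEF1 transcription complex (`TRCMPLX`) drives target
genes such as *MYC*, *CCND1* and *CD44*, while extracellular inhibitors
(the *SFRP* family, *DKK* family, *WIF1*) and intracellular antagonists
(the *DACT* family) are frequently silenced epigenetically — by promoter
hypermethylation, and for *DACT3* by a bivalent histone configuration
(repressive H3K27me3 together with activating H3K4me3).

Naive classifiers built on such expression panels implicitly assume that an
active transcription complex and a tumorous sample are the same event.
`wntbn` implements the model family that questions that assumption: the
tissue state is a separate latent variable (`Sample`) from the complex
state (`TRCMPLX`), and the expression data are left to decide how strongly
the two coincide.

## The three model variants

All nodes are binary; state 1 is always the low/off pole (inactive,
non-methylated, low concentration, normal) and state 2 the high/on pole.

* **t1** — full model: 18 gene nodes (including the two DKK3 probes), 9
  promoter-methylation nodes, the two DACT3 histone marks, plus `Sample`,
  `TCF4`, `DVL2`, `BETACAT` and `TRCMPLX` (34 nodes). Genes with a
  literature-confirmed complex interaction (*MYC*, *CCND1*, *CD44*, *DKK1*,
  *DKK4*, *SFRP1*, *WIF1*) have `TRCMPLX` among their parents; the rest
  connect to the complex only indirectly through `Sample`. `DVL2`
  concentration is inversely tied to *DACT3*; β-catenin responds to *DACT1*
  and `DVL2`; the complex forms from `TCF4`, *LEF1* and β-catenin.
* **t2** — the same causal skeleton with all epigenetic nodes (and their
  arcs) removed, 23 nodes.
* **p1** — a naive-Bayes star: every gene hangs off `TRCMPLX`, whose
  parents are β-catenin and `TCF4`; there is no `Sample` node (21 nodes).

```{r variants}
build_topology("t1")
build_topology("t2")
build_topology("p1")
```

One structural ambiguity is genuinely open in the source material: *DKK4*
is printed with parents {`Sample`, `TRCMPLX`} (a four-column table) but
grouped in the text with the methylation-parented genes. We follow the
printed table — the table's dimensionality is unambiguous — and expose
`build_topology(dkk4_methylation = TRUE)` for the alternative. `MeDKK4`
stays in the inventory as an isolated root either way, which is harmless:
path enumeration between `SFRP3` and `TRCMPLX` is invariant to the option
because methylation nodes are dead ends on the undirected skeleton.

Graph reasoning comes with the topology: `enumerate_simple_paths()` works
on the undirected skeleton (the printed path lists mix arc orientations),
and `is_d_separated()` implements the directed blocking criterion
(colliders block unless observed or with an observed descendant;
chains/forks block when observed) via Bayes-ball reachability. The test
suite checks it exhaustively against an independent
moralized-ancestral-graph oracle.

```{r dsep}
t1 <- build_topology("t1")
length(enumerate_simple_paths(t1, "SFRP3", "TRCMPLX"))
is_d_separated(t1, "SFRP3", "TRCMPLX", observed = "Sample")
is_d_separated(t1, "Sample", "TRCMPLX", observed = "SFRP1")
```

## Parameters: fixed priors and estimated gene tables

Non-gene nodes carry fixed parameters shipped with the package
(`wnt_parameters()`): a 50/50 prior on `Sample`, literature-derived
methylation and histone-mark priors (normalized ChIP/MSP/bisulfite
fractions, taken as given constants), and near-deterministic tables for
`DVL2`, β-catenin and `TRCMPLX` (0.99/0.01). Two methylation priors
(`MeDKK1`, `MeDKK4`) are not printed anywhere; they default to the neutral
[0.5, 0.5] and can be overridden through `training_config(priors = ...)`.
The same applies to the β-catenin root prior needed only by `p1`. A few
printed gene-table columns are off by a rounding unit (e.g. summing to
0.99); they are renormalized per column on load.

Gene nodes are estimated from training data. The rules share a common
skeleton — discretize at the per-gene training median, cross-tabulate the
binary state against the class label (counts `a`, `b`, `c`, `d`), convert
to fractions, optionally weight by the transcription-complex effect, smooth
— but differ per parent signature:

* `{Sample}`: class-conditional active fractions (`estimate_cpt_sample_only`).
* `{TRCMPLX}` (p1 only): identical arithmetic with the class label proxying
  the complex state (`estimate_cpt_trcmplx_only`).
* `{Sample, TRCMPLX}`: the fractions are multiplied by `p` in the
  complex-off block and `1 - p` in the on block
  (`estimate_cpt_sample_trcmplx`). `p = 1 - etgn`, where `etgn` — the
  assumed effect of the complex on its targets — defaults to 0.9 and is
  swept over 0.5–0.9 in the original analysis.
* `{Sample, Me, TRCMPLX}`: a 2×2 methylation-by-class cross table with the
  rule's own unusual denominators (`A = n_normal + b`, `B = n_tumor + a`,
  `C = n_normal + d`, `D = n_tumor + c`). These denominators are
  non-standard — the opposite class's count is added to the class total —
  but they are implemented exactly as stated rather than "corrected",
  since the printed tables are downstream of them
  (`estimate_cpt_sample_me_trcmplx`).
* `{Sample, Me}`: the estimation rule for these five genes is never derived
  in the source; we use the cross-table rule above with the complex weight
  removed, the natural two-parent analogue (`estimate_cpt_sample_me`).
* *DACT3*: active when H3K27me3 is low **and** H3K4me3 is high; every other
  histone configuration takes the flipped complement
  (`estimate_cpt_dact3`). Its columns are ordered per the printed
  serial numbering (H3K27me3 fastest, then H3K4me3, then `Sample`).

Column order everywhere: the first-listed parent varies fastest.

### Ties at the median

The source training code bins with overlapping `<=`/`>=` comparisons (a
value equal to the median would land in both bins) while its test-evidence
code uses "lower than ... else". We use the strict rule `< → state 1,
>= → state 2` everywhere, so training counts partition and training and
testing agree. Consequence: with an even sample count the median is the
mean of the two central order statistics, and exactly half the samples are
called active whenever the median falls strictly between two observed
values.

### Smoothing: fractions versus counts

The estimation prose adds the pseudo-count constant 1 to the
*fraction-valued* table before normalizing; that is the default
(`smoothing_on = "fractions"`). Note what this implies: each column entry
becomes `(x + 1) / (colsum + 2)`, which maps everything into [1/3, 2/3]
regardless of sample size — the estimator is deliberately conservative and
not consistent. The printed one-iteration gene tables contain entries like
0.95 that cannot arise under fraction smoothing, which suggests the
original computation effectively smoothed counts. Both interpretations are
available; `smoothing_on = "counts"` adds the constant to raw counts
(`(n x + 1) / (n + 2)`), is consistent, and is what the parameter-recovery
analyses in this package use. The choice is a config switch precisely
because the source is ambiguous.

## Exact inference

`posterior_marginal()` runs variable elimination with a greedy
smallest-intermediate-factor ordering. The networks are small (≤ 34 binary
nodes) and sparse, so any exact method is adequate; the contract is
exactness, which the suite verifies to 1e-9 against
`brute_force_marginal()`, an independent full-joint enumeration written
against the bit pattern of the joint index (feasible to 24 nodes). Every
call rebuilds its factors from the network — no inference state survives
between evidence sets, which removes the classic stale-evidence hazard of
reusing a conditioned engine. Evidence with zero joint probability raises
an explicit error rather than returning NaN.

```{r inference}
net <- reference_network()
posterior_marginal(net, c(DACT3 = 1L), "DVL2")
posterior_marginal(net, c(TCF4 = 2L, LEF1 = 2L, BETACAT = 2L), "TRCMPLX")
```

## The 2-holdout experiment

`generate_pairs()` forms every (normal, tumor) pair — 576 for the 24+24
cohort — with the normal index in the outer loop. Per iteration the
network is trained on the remaining 46 samples; both test samples are
discretized against the fold's thresholds (shared by the pair, since the
thresholds come from the common fold); and the posteriors
Pr(TRCMPLX = active | all gene evidence) and, for t1/t2,
Pr(Sample = tumor | ...) are recorded per test sample with the true ±1
label. Recording per sample (two rows per iteration) rather than per pair
matches how the downstream scoring consumes the predictions.

The methylation-perturbation mode (`run_me_experiment()`) sweeps all 2^9
binary methylation configurations (or a seeded subsample) as the only
evidence. A structural fact worth stating plainly: with no gene observed,
every methylation-to-`Sample` path is blocked at an unobserved gene
collider, so these posteriors provably equal the no-evidence marginals.
The sweep is retained as specified — it is the correct experiment to
demonstrate exactly this screening-off, and the tests assert it, along
with the collider opening once gene evidence is added.

## Evaluation

`compute_roc()` (threshold sweep, trapezoidal AUC, ties grouped, fixed
direction) and `ks_two_sample()` (asymptotic two-sample
Kolmogorov–Smirnov with the standard effective-n correction, α = 0.05
by default — the source reports only the rejection flag, so the α
convention is ours) score the runs; `summarize_gene_trcmplx()` reproduces
the per-gene conditional summaries: group test samples by a gene's
evidence state within each true class, average the complex posterior, and
report the majority-state mean as the inferred belief (ties break toward
repressed).

## The synthetic cohort generator

The study's expression matrix is not publicly deposited, so the package
ships a generator that emulates its statistical structure rather than its
values: ancestral sampling of the full t1 network under the packaged
parameters, with `Sample` clamped to the requested class composition
(conditioning by intervention, giving exact counts), nodes visited in
topological order under one seeded generator, and expression emitted as a
two-component Gaussian (defaults `mu_low = 0`, `mu_high = 1`,
`sigma = 0.25`; the defaults keep the state clusters separable at the
median while leaving realistic overlap). The source never models
continuous expression — only median splits — so any state-separable
emitter is faithful; the Gaussian is the simplest such choice.

What the generator does *not* emulate: real expression magnitudes,
heteroskedastic or heavy-tailed wet-lab noise, probe effects, or
inter-gene correlation beyond what the network structure induces. Passing
tests on synthetic cohorts therefore validate the pipeline's mechanics and
its statistical behavior under the model's own assumptions — not the
biological conclusions on the real cohort.

One sharp edge is documented rather than hidden: at `sigma = 0` the median
recovers the latent states only when it falls strictly between the two
emission clusters (balanced state counts). When a gene's active fraction
is away from one half, the median sits inside a cluster and the strict
`>=` rule misassigns part of it. This is a property of median
discretization itself, and the reason the parameter-recovery analyses
target the single-parent genes, whose printed tables are complementary
across classes (marginal active fraction exactly one half).

```{r cohort}
cohort <- generate_cohort(generator_config(seed = 7))
cohort$dataset
```

## Problem sizes and numerical choices

* The full t1 ge-mode holdout (576 iterations, 1152 test samples, two
  queries each) runs in well under a minute on a single core; unit tests
  use 4+4 to 8+8 cohorts, and the oracle-equivalence checks enumerate the
  full 23-node t2 joint (2^23 states) directly.
* Parameter recovery uses 2000 samples per class at `sigma = 0.001`
  (counts smoothing), recovering the single-parent tables within ±0.05.
* Probability columns are normalized to 1 within 1e-12; inference
  equality is asserted at 1e-9; smoothing guarantees all entries lie
  strictly inside (0, 1), so no evidence can be deterministically
  contradicted.
* Determinism: a single seeded generator per synthetic cohort; the holdout
  itself contains no randomness, so identical inputs give identical
  outputs.

## Known limitations

* The fixed priors are taken as printed constants; re-deriving them from
  the underlying wet-lab sources is out of scope.
* The three-parent denominators and the fraction-smoothing operand follow
  the stated rules even where those are statistically unusual; the config
  switches exist for sensitivity analysis, not as corrections.
* Static snapshot models only — no time-course dynamics.
* Printed headline AUCs of the original study require the undeposited real
  cohort and are not reproduction targets here.
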