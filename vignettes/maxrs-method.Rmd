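---
title: "Rank-sum probe selection for cross-species microarray hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-sum probe selection for cross-species microarray hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxrs)
```

## The problem

Expression microarrays exist for a handful of reference species. When the
organism under study has no dedicated array — common in ecological physiology —
RNA can still be hybridized to the array of a related species (*heterologous
hybridization*), but sequence divergence between the study species' transcripts
and the reference species' probes depresses the fluorescence signal, and it
does so unevenly: a 25-mer probe overlapping a conserved stretch of the
transcript hybridizes almost normally, while a probe overlapping a diverged
stretch may bind hardly at all.

Affymetrix-style designs interrogate each transcript with a *probe set* of
about 11 perfect-match probes spread along the sequence. Standard probe-set
summarization averages information across all probes and is badly biased when
most probes are near background. The method implemented here turns the
platform's redundancy into an asset: within each probe set, identify the probe
that consistently carries signal across arrays — presumably the one targeting
the most conserved region — and use *that probe alone* as the expression
estimator.

## The selection rule

Let $m = 1..M$ index arrays, $t = 1..T$ probe sets, and $p = 1..P_t$ the
retained probes of probe set $t$, with intensities $I_{mtp}$.

1. Within each array $m$ and probe set $t$, rank the probes by intensity in
   increasing order; call the ranks $r_{mtp}$ (midranks for ties).
2. Sum each probe's ranks over arrays: $RS_{tp} = \sum_m r_{mtp}$.
3. Select the probe with the largest $RS_{tp}$. On a tie, take the tied probe
   with the highest mean intensity over all arrays; a further exact tie falls
   back to input order, so selection is fully deterministic.

The selected probe's **raw** intensities on all $M$ arrays become the
expression estimates of probe set $t$; selection never transforms intensities.

Two diagnostics accompany selection:

* the **maximum-rank-sum statistic** $\max_p RS_{tp} / P_t$, which lies in
  $[1, M]$ and equals $M$ exactly when the same probe has the (untied) top
  rank on every array — its distribution over probe sets summarises how
  reproducibly one probe dominates;
* a per-probe-set **Friedman test** treating probes as treatments and arrays
  as blocks, with midrank tie correction and a $\chi^2_{P_t-1}$ reference
  distribution. Note the direction of the inference: *rejecting* the Friedman
  null of exchangeable ranks is what indicates a consistent probe ordering
  across arrays, so the fraction of probe sets with $p < 0.05$ measures
  rank reproducibility. The test is descriptive only and never gates
  selection; sets with $P_t = 1$, a single array, or completely tied ranks
  (where the tie-corrected statistic is undefined) are flagged `NA` and
  excluded from that fraction.

## Background filtering

Arrays carry spots with no probe; their intensities estimate the optical/
nonspecific background. The *background level* is the 95th percentile of the
background-spot intensity distribution, computed with the nearest-rank
definition (the value at index $\lceil qN/100 \rceil$ of the sorted sample) —
order-statistic exact, no interpolation. A probe is retained when its
intensity strictly exceeds the background level in **at least one** array;
probe sets retaining no probe drop out.

Two choices here were genuinely open and are worth stating:

* **Per-array thresholds** are the default: they absorb array-level brightness
  differences and coincide with a pooled threshold when arrays are
  homogeneous. `estimate_background(pooled = TRUE)` gives the pooled variant.
* Ranking after filtering uses each retained probe's intensity in **every**
  array, including arrays where that probe is below background: the retention
  rule is "above background somewhere", and a constant probe count per array
  is what the rank-sum identities require.

## Normalization and testing

After selection, the $T' \times M$ matrix of selected-probe intensities is
quantile-normalized (each column's $i$-th order statistic replaced by the mean
of the $i$-th order statistics over columns, ties receiving the mean of the
values they span), then log2-transformed with a floor:
$x \mapsto \log_2 \max(x, 1)$. The floor (default 1.0, in raw fluorescence
units) prevents near-zero intensities from exploding to large negative logs;
the transform is explicit and can be disabled (`no_log`) because the
downstream test assumes approximately normal log-scale intensities, and a
user normalizing elsewhere may already be on that scale.

Differential expression between the two conditions (sample sizes $n_1, n_2$)
uses the empirical-Bayes moderated $t$. Gene-wise residual variances $s^2_g$
(pooled, $d_g = n_1 + n_2 - 2$ df) receive a scaled inverse-chi-square prior
with hyperparameters $(d_0, s_0^2)$ fitted by moment matching on
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$: $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ by monotone root-finding on
$[10^{-2}, 10^3]$ (tolerance $10^{-8}$), with an infinite-$d_0$ branch when
the observed spread does not exceed the sampling spread; then
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. The posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ yields
$t_g = \mathrm{logFC}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ on
$d_0 + d_g$ df (normal tail at $d_0 = \infty$; the ordinary pooled $t$ at
$d_0 = 0$). Two-sided p-values are adjusted by Benjamini–Hochberg and calls
made at an inclusive $p_{adj} \le \alpha$, default $\alpha = 0.10$. The log
fold change is second-listed condition minus first-listed, so the group
file's order fixes the sign convention (recorded in the run log).

No variance-trend or outlier-robust variants are offered: the plain moderated
$t$ is the intended method, and the package's own implementation is
cross-checked against `limma::eBayes` in the test suite.

## The synthetic-data generator

Because real heterologous array data are large and external, the package
ships a generator whose defaults define the regime the method targets:

| parameter | default | meaning |
|---|---|---|
| `n_probesets` | 2000 | transcripts (probe sets) |
| `probes_per_set` | 11 | PM probes per set (platform average) |
| `n_arrays` | 4, 3 | two-condition design |
| `prop_de` | 0.1 | fraction of genes with planted DE |
| `fc_range` | 1.6–8.4 | planted linear fold changes |
| `baseline_log2_mean`, `sd` | 8, 1.5 | log2 baseline expression |
| `affinity_conserved` | U(0.5, 1) | the one conserved probe per set |
| `affinity_diverged` | U(0, 0.3) | all other probes |
| `noise_sd` | 0.25 | multiplicative noise, natural-log scale |
| `n_background` | 5000 | no-probe spots per array |
| `background_meanlog`, `sdlog` | log 50, 0.4 | background log-normal |

Probe intensity is $I = a_{tp}\, e_{tc}\, \mathrm{e}^{\varepsilon} + b$:
affinity $\times$ condition mean $\times$ log-normal noise, plus an additive
background draw from the same log-normal that produces the standalone
background spots — so the background threshold genuinely separates diverged
probes from signal. The affinity gap (0.5 vs 0.3) instantiates the working
hypothesis that one conserved region dominates hybridization; it is a
modeling choice, not an observation. Each probe set has exactly one conserved
probe; sizes are fixed at 11 by default (`jitter_probes` draws
Poisson-distributed sizes truncated at 2 for realism). All randomness flows
through one Mersenne–Twister stream seeded once, so identical seeds give
bit-identical tables.

What the generator deliberately does **not** model: array-level brightness or
batch effects (each array is statistically exchangeable within its
condition), cross-hybridization between probe sets, sequence-level mismatch
structure, and spatial artifacts. Consequences worth knowing:

* Passing tests show the algorithmic machinery is correct under the stated
  generative model; they do not certify performance on real cross-species
  data, where affinity profiles are not cleanly bimodal.
* Quantile normalization has nothing array-specific to correct in this
  simulator, while 10% of genes carry strong genuine expression differences.
  Under exactly these conditions quantile normalization mildly distorts
  non-DE genes between groups — a known failure mode when global expression
  differences are real — and the measured false discovery proportion of the
  full pipeline at $\alpha = 0.10$ sits near 0.15 rather than 0.10, although
  the test's type-I error stays calibrated and the DE statistics control FDR
  on data meeting their own assumptions (both properties are in the test
  suite). On data where DE genes are rare (of the order of 1% of probe sets,
  as in typical heterologous experiments) or where array effects dominate,
  quantile normalization behaves as intended. The pipeline keeps
  normalization because it is the method's published design; users simulating
  dense, strong DE should read the FDR accordingly.

## Numerical conventions

* Percentiles: nearest-rank; ties at the background threshold are *not*
  retained (strict inequality).
* Ranks: midranks for ties everywhere; the Friedman statistic uses the
  standard tie correction $C = 1 - \sum(t^3 - t)/(M(k^3-k))$ and is `NA`
  when $C \le 0$.
* Selection tie-break chain: rank sum, then mean intensity, then input order —
  bit-reproducible runs.
* Prior fit: bisection-free `uniroot` on a bracketing interval, tolerance
  $10^{-8}$; $d_0$ capped to $\infty$ beyond $10^3$.
* Quantile normalization is idempotent to $10^{-9}$ and equivariant under row
  permutation; both are asserted in the suite.

## Problem sizes used in the test suite

The suite exercises the full pipeline at the generator's default size
(2000 probe sets $\times$ 7 arrays) for the error-control checks — three null
experiments pooled for type-I, five planted-DE experiments for FDR and
strong-effect sensitivity — and smaller tables (tens of probe sets) for
format, determinism and composition checks. Exhaustive oracles run over all
$(P!)^M$ rank configurations for $P \le 4$, $M \le 3$ and all Friedman
permutation nulls for $k, M \le 3$.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_config(seed = 1))
flt <- apply_background_filter(sim$probes, estimate_background(sim$probes))
fit <- run_maxrs(flt)
glance(fit) # probe sets, Friedman-consistent fraction, rank statistic
expr <- log2_transform(quantile_normalize(fit))
de <- moderated_t_test(expr, sim$groups, alpha = 0.10)
glance(de) # fitted prior, up/down counts
autoplot(fit) # distribution of the maximum-rank-sum statistic
autoplot(de) # volcano
evaluate_selection(fit, sim)
evaluate_de(de, sim)
```

## Limitations

Only two-condition, single-channel designs; no model-based background
correction (the percentile filter is the method's own rule); no paired or
multi-factor designs; binary platform files are out of scope — inputs arrive
as the documented TSV. The Friedman p-values use the chi-square
approximation, adequate for the diagnostic role they play; exact permutation
references exist in the test suite for small designs.
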