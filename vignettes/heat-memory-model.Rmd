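---
title: "A nucleosome-state model of heat-stress transcriptional memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nucleosome-state model of heat-stress transcriptional memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented in `heatmem`, the
assumptions behind it, the meaning and defaults of every parameter, what
the synthetic-data generators do and do not emulate, and the numerical
choices made in the implementation. Code chunks are illustrative and not
evaluated when the vignette is built; all quantitative claims about the
package are established by its test suite and by
`scripts/acceptance.R`, not here.

## Biological setting

Plants that experience a mild heat acclimation transcribe heat-shock
genes much more strongly when a severe heat shock arrives days later.
At memory loci such as *HSP22* and *HSP17.6C* this "transcriptional
memory" tracks the slow removal of the repressive histone mark H3K27me3
and the gain of the active mark H3K4me3. JUMONJI (JMJ) H3K27me3
demethylases are induced by heat and drive the removal; quadruple *jmj*
mutants (here the `"jmjq"` genotype) retain H3K27me3 and lose most of
the memory. The package models one such locus mechanistically and
surrounds the model with the inference and screening machinery needed to
confront it with (synthetic) data.

## State space and rates

A locus carries `N` nucleosomes. Each nucleosome is in one of three
states:

* `R` — repressed, carrying H3K27me3;
* `U` — unmodified;
* `A` — active, carrying H3K4me3.

Writing `r`, `u = 1 - r - a`, `a` for the fractions of nucleosomes in
each state, the per-nucleosome transition rates (per hour) are

| transition | rate | interpretation |
|---|---|---|
| `R -> U` | `k_noise + v0 + phi * vJ * J(t)` | basal plus JMJ-driven demethylation |
| `U -> A` | `k_noise + k_act * a + vUA_S * S(t)` | recruited and stress-driven activation |
| `A -> U` | `k_noise` | noisy loss of the active mark |
| `U -> R` | `k_noise + k_rep * r` | recruited re-repression |

The recruited terms `k_act * a` and `k_rep * r` are read–write
feedback: nucleosomes in a given state recruit enzymes that convert
others to the same state. All-to-all recruitment is assumed, so the
recruiting fraction is the ensemble fraction (in the stochastic engines,
the current count divided by `N`). Direct `R <-> A` conversions are
excluded: the repressive mark must be removed before the active one can
be written, which is what makes H3K27me3 removal rate-limiting for
memory.

The genotype enters in exactly one place: the JMJ-dependent
demethylation term is scaled by `phi`, with `phi = 1` for `"WT"` and
`phi = phi_jmj` for `"jmjq"`. Nothing else differs between genotypes.

## Temperature-driven signals

Temperature acts through three filtered signals, each a linear ODE
driven by a threshold indicator of the temperature profile `T(t)`:

* **JMJ recruitment** `J(t)`: `dJ/dt = sigma_J * 1[T >= T_J] - lambda_J * J`.
  Slow decay (`lambda_J = 0.01 /h`, half-life about 3 days) makes `J`
  the long-lived carrier of the acclimation signal.
* **Stress / activation** `S(t)`: `dS/dt = sigma_S * 1[T >= T_S] - lambda_S * S`.
  Faster decay (`lambda_S = 0.05 /h`); drives both `U -> A` conversion
  and transcription.
* **Damage** `D(t)`: while `T >= T_D`, `D` relaxes toward `D_min` at
  rate `kappa_D`; otherwise it recovers toward 1 at rate `rho_D`.
  `D` multiplies transcription, capturing the global shutdown of gene
  expression during and shortly after a severe shock.

Because `T(t)` is piecewise constant, all three signals have exact
piecewise closed forms; the implementation evaluates these analytically
on a grid aligned to the profile breakpoints rather than integrating
them numerically.

## Transcription

mRNA (in arbitrary relative units) follows

```
dm/dt = D(t) * (alpha0 + alpha * S(t) * a * (1 - r)) - delta * m
```

Transcription requires the stress signal and active nucleosomes, and is
attenuated by remaining repression through the `(1 - r)` factor — a
compact way of encoding that H3K27me3 blocks productive initiation even
when some H3K4me3 is present. `alpha0` is a small basal rate and
`delta` the mRNA decay rate.

## Parameters: defaults, units, rationale

All rates are per hour; temperatures in °C; `m` is in arbitrary units.

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 20 | nucleosomes at the locus; order of a few kb of chromatin |
| `k_act` | 0.1 | recruited `U -> A` rate; feedback strong enough for state persistence |
| `k_rep` | 0.2 | recruited `U -> R` rate; repression dominates at rest, giving a repressed ground state |
| `k_noise` | 0.02 | state-independent conversion rate; sets the intrinsic noise floor |
| `v0` | 0.002 | basal demethylation; slow spontaneous loss of H3K27me3 |
| `vJ` | 0.1 | JMJ-driven demethylation per unit `J` |
| `phi_jmj` | 0.2 | residual demethylase activity of the mutant |
| `vUA_S` | 0.05 | stress-driven `U -> A` rate per unit `S` |
| `sigma_J`, `lambda_J`, `T_J` | 3, 0.01, 30 | JMJ signal gain, decay, threshold; 30 °C is crossed by acclimation and shock |
| `sigma_S`, `lambda_S`, `T_S` | 6, 0.05, 35 | stress signal gain, decay, threshold; 35 °C crossed by both heat treatments |
| `T_D`, `kappa_D`, `rho_D`, `D_min` | 42, 2, 0.02, 0.1 | damage threshold (only the 43.5 °C shock crosses it), onset and recovery rates, floor |
| `alpha`, `alpha0`, `delta` | 20, 0.02, 0.5 | transcription gain, basal rate, mRNA decay (half-life ~1.4 h) |
| `r_init` | 0.9 | initial repressed fraction; the locus starts silenced (`a = 0`) |

The defaults were calibrated once, before any tests were written, by
scanning for a regime that jointly shows (i) a repressed, stable resting
state, (ii) substantial H3K27me3 loss after acclimation in WT but not
`jmjq`, (iii) an acclimation-to-shock expression gain of a few fold
that decays over weeks, and (iv) memory lasting longer for larger `N`.
They are frozen defaults, not fitted values.

Observation parameters (`observation_params()`) map states to assays
affinely: H3K27me3 percent-input `c27 * r + b27` (defaults 10, 0.5),
H3K4me3 `c4 * a + b4` (10, 0.5), expression `cm * m` (1).

## Engines and their numerics

* **Mean-field ODE** (`simulate_mean_field()`): fixed-step RK4 on
  `(r, a, m)` with the exact signals. The step grid is aligned to the
  profile breakpoints so no heat window is straddled; `dt` larger than
  the shortest profile step is refused. Default `dt = 0.05` h, at which
  the closed-form checks in the test suite pass to about `1e-6`
  relative accuracy.
* **Stochastic simulation** (`simulate_ssa()`): an exact SSA over the
  nucleosome state counts `(n_R, n_U, n_A)`. Rates are held constant within
  each signal grid cell (the signals are smooth on the `dt` grid) and
  the algorithm redraws propensities at every cell boundary, so the
  only approximation is the piecewise-constant signal, not the jump
  process itself. mRNA is propagated through each cell with the
  closed-form solution of the linear mRNA ODE given the cell's state.
  Each run has its own derived seed; ensemble means and standard errors
  are returned. A guard refuses jobs whose expected event count is
  excessive.
* **Master equation** (`solve_master_equation()`): for `N <= 8` the full
  `(N+1)(N+2)/2`-state master equation is solved with matrix
  exponentials (`Matrix::expm`), caching one propagator per distinct
  signal value. Total probability mass is tracked and reported as the
  `mass_error` attribute. This engine is the oracle against which the
  SSA is validated.

## Inference

`fit_heat_memory()` fits chosen free parameters to a tidy table of
`(time_h, assay, genotype, replicate, value)` by minimising the sum of
squared log-residuals, `sum((log(y + eps) - log(yhat + eps))^2)` with
`eps = 1e-3`. Log residuals keep the high-expression points from
dominating the chromatin marks; the offset keeps near-zero baseline
values finite. Free parameters are optimised on an unconstrained scale
via a logistic map into their bounds (log-scaled where the bounds span
decades), using Nelder–Mead from Latin-hypercube multistarts.
Uncertainty comes from replicate-level parametric resampling: synthetic
replicates are regenerated from the fitted parameters and refitted, and
percentile intervals are read from the refits (`confint()`). The fit
object supports `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals`, `plot` and `simulate`.

## Memory analysis

`memory_ratio()` quantifies acclimation memory as the ratio of
expression 4 h after the heat shock with versus without prior
acclimation, as a function of the gap between the two treatments.
`memory_duration_scan()` scans this ratio over a gap grid for several
values of `N` and reports, per `N`, the longest gap at which the ratio
still exceeds a threshold (default 2). The duration readout uses the
grid values directly; it is a step function of the grid, so grids should
be chosen with the resolution one wants to resolve.

## Screening pipeline

The screen mimics a 0/4/24 h post-shock RNA-seq comparison of WT and
mutant. Counts are modelled as negative binomial with a common
dispersion, estimated by a pooled, inverse-variance-weighted method of
moments over all replicated (genotype, time) groups after library-size
rescaling. `nb_lrt()` performs per-gene likelihood-ratio tests of a
genotype effect at one time point (reducing to exact Poisson LRTs at
zero dispersion); `bh_adjust()` applies Benjamini–Hochberg; and
`screen_memory_genes()` calls a gene a memory gene if it is significant
and consistently directional at 4 h or 24 h but not at 0 h. Supporting
tools: `cluster_profiles()` (k-means on standardised profiles),
`hypergeom_overlap()` (upper-tail overlap test), `read_bed()` and
`call_fold_change_regions()` (fold-enrichment calls on H3K27me3
coverage regions), and `chlorophyll_content()` (the standard absorbance
formula `19.43 * A_646.8 + 8.05 * A_663.8`, µM in extract).

## Synthetic-data generators

All generators return the ground truth alongside the data.

* `gen_field_profile()` produces a field-like temperature series: a
  smooth diurnal cycle plus heat spikes on chosen days. It emulates the
  shape of outdoor temperature logs, not any particular climate record.
* `gen_timecourse()` simulates both genotypes under a profile and
  applies multiplicative lognormal assay noise (default CV 0.2) at
  chosen sampling times. It emulates qPCR/ChIP-qPCR style replicate
  noise; it does not model batch effects, detection limits, or
  normalisation artefacts.
* `gen_count_matrix()` plants memory genes (expression responding at
  4/24 h in WT but attenuated in the mutant) among null genes in a
  negative-binomial count matrix with known dispersion and library
  sizes. It emulates the statistical structure of an RNA-seq screen,
  not read-level properties (no gene length, GC, or mapping effects).
* `gen_region_counts()` plants hyper-enriched regions in paired
  coverage counts for the fold-change caller.

## Open decisions and limitations

* Recruitment is all-to-all; no spatial arrangement of nucleosomes or
  nearest-neighbour spreading is modelled. Memory-duration trends in
  `N` should be read qualitatively.
* The `(1 - r)` transcription factor is a phenomenological choice; any
  decreasing function of `r` would encode the same idea, and the fitted
  `alpha` absorbs part of that arbitrariness.
* Genotype differences are confined to `phi_jmj`; compensatory changes
  in mutants (e.g. altered HSF signalling) are not represented.
* The common-dispersion NB model ignores gene-wise dispersion trends;
  the screen's error-rate behaviour is validated only under its own
  generator.
* DNA replication, histone turnover during S phase, and cell-to-cell
  variability in signal strength are not modelled; the SSA noise is
  purely the conversion noise of a single locus.
* Signal parameters (`sigma_*`, `lambda_*`, thresholds) are weakly
  identifiable from mark/expression time courses alone and are treated
  as fixed by default; the standard fit frees only `vJ` and `phi_jmj`.
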