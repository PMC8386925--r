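---
title: "Amino-acid isotope dietary reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid isotope dietary reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aadiet)
```

## The problem

Bulk bone-collagen δ13C and δ15N integrate a decade or more of diet, but a
single pair of numbers cannot apportion a diet across three or more food
groups, and it confounds two very different kinds of atoms: amino acids
routed intact from dietary protein ("source" AAs such as Phe, Lys, Leu,
Val, Ile, which undergo negligible, sub-per-mil fractionation) and amino
acids synthesised de novo ("trophic" AAs such as Ala, Glx, Asx, whose
carbon and nitrogen are drawn from metabolic pools fed by all
macronutrients, with substantial fractionation). Compound-specific isotope
analysis (CSIA) measures each amino acid separately, so the routing can be
modelled explicitly instead of assumed away.

This package implements that modelling chain end to end:

1. **GC-C-IRMS reduction** — from per-peak deltas of derivatized amino
   acids to corrected per-AA values with propagated uncertainties;
2. **cereal prediction** — per-AA values for charred archaeological grains
   from bulk values via modern-grain offsets;
3. **mixing models** — concentration-dependent Bayesian mixing with
   metabolic routing, sampled by Metropolis-Hastings;
4. **cohort statistics** — between-sex contrasts of posterior medians;
5. **synthetic data** — generators for every input, so the whole chain is
   testable without any measured data.

## The mixing model

Let $f = (f_1,\dots,f_K)$ be the diet fractions over $K$ food sources.
Each isotopic *signal* $s$ (an element–analyte pair such as (C, Leu) or
(N, bulk)) sees source $i$ with a **carrier concentration** $q_{si}$ — the
mass fraction of the signal's carrier in that source — giving
concentration-dependent weights

$$w_{si} \;=\; \frac{f_i\,q_{si}}{\sum_j f_j\,q_{sj}},$$

and a predicted consumer value

$$\mu_s(f) \;=\; \sum_i w_{si}\, v_{si} \;+\; o_s,$$

where $v_{si}$ is the value source $i$ presents to signal $s$ and $o_s$ a
diet-to-consumer offset. The likelihood of a measured value $m_s \pm
\sigma_s$ is Gaussian. Source values and offsets carry Gaussian priors at
their measured (mean, sd); because they enter the likelihood linearly
given $f$, they are **marginalised analytically**:

$$m_s \mid f \;\sim\; \mathcal N\!\Big(\textstyle\sum_i w_{si}\bar v_{si} + \bar o_s,\;
 \sigma_s^2 + \sum_i w_{si}^2\tau_{si}^2 + \sigma_{o_s}^2\Big).$$

This yields exactly the same marginal posterior over $f$ as sampling the
nuisance values, at a fraction of the cost, and is the reason a full fit
(5000 burn-in + 10000 retained iterations) takes tens of milliseconds.

### Routing classes

Each signal is assigned a routing class that decides both $v_{si}$ and the
carrier $q_{si}$:

| routing | value $v_{si}$ | carrier $q_{si}$ |
|---|---|---|
| `source_direct` | measured AA value | AA fraction of protein (× protein fraction on the whole-diet scale) |
| `glycolytic` | bulk δ13C + carbohydrate offset | carbohydrate mass |
| `carbon_pool` | mass-weighted macronutrient δ13C | total dry mass |
| `nitrogen_pool` | bulk δ15N + trophic Glx shift | protein mass |
| `bulk_protein` | bulk value routed from protein | protein mass |
| `bulk_scrambled` | carbon as `carbon_pool`; nitrogen as protein | dry mass (C) / protein (N) |

### The four model structures

* **model 1** — source AAs only: δ13C of Leu, Val, Ile, Phe and δ15N of
  Phe and Lys, all `source_direct` with offset 0 ± 0.5 ‰ (their
  fractionation is below 1 ‰). Fractions estimated are **shares of dietary
  protein**.
* **model 2** — model 1 plus trophic AAs: (C, Ala) `glycolytic` (alanine
  carbon comes from carbohydrate digestion via pyruvate), (C, Glx) and
  (C, Asx) `carbon_pool` (TCA-cycle intermediates drawing on all
  macronutrients), and (N, Glx) `nitrogen_pool` (glutamate exchanges
  nitrogen with the whole amino-nitrogen pool). Fractions are **shares of
  whole diet by dry weight**, broadly shares of calorific value. Serine
  and glycine also have glycolytic carbon but are excluded from the
  default signal set: their collagen values are dominated by intense
  one-carbon metabolism, so only Ala, Glx and Asx act as trophic carbon
  signals here.
* **model 0p / 0wd** — the bulk-collagen baselines: two signals only
  (C, bulk) and (N, bulk), with protein-routed (0p) or
  macronutrient-scrambled (0wd) source values. They exist to show the
  resolution gained by the AA models.

An **olive-oil source** can be appended to whole-diet models: protein 0,
carbohydrate 0, lipid 1, with δ13C equal to a modern Mediterranean
olive-oil value shifted by a Suess correction (defaults −29 ± 1 ‰ and
+1.5 ± 0.2 ‰). Because it carries no protein it is invisible to every
nitrogen and source-AA signal and enters only through the carbon pool;
with model 1 it is a specification error.

### Priors, sampler and numerics

The prior on $f$ is the flat Dirichlet(1, …, 1) — no informative dietary
prior. Sampling is component-wise random-walk Metropolis-Hastings on
additive-logratio coordinates $z_k = \log(f_k/f_K)$, with the
log-Jacobian $\sum_k \log f_k$ making the flat Dirichlet exact. Step sizes
adapt per coordinate every 50 burn-in iterations toward a 0.44 acceptance
rate and are frozen afterwards, so the retained chain satisfies detailed
balance. Defaults are 5000 burn-in and 10000 retained iterations in a
single chain (the conventional BUGS-style run length for this model
class); `chains = n` pools chains started at seed offsets. Every fit is a
pure function of (inputs, seed): identical calls are bit-identical.
Diagnostics record acceptance rates and lag-{1, 5, 10, 50}
autocorrelations; an acceptance rate outside [0.05, 0.8] raises a
convergence warning, never an error.

Degenerate cases: a signal whose carrier is absent from every source is a
specification error; a source lacking a carrier for one signal simply gets
weight 0 there. A glycolytic signal requested from a carbohydrate-free
source falls back to the carbon pool with a warning (configurable to an
error), since the value is weighted by a zero carrier anyway.

The posterior mode is estimated as the best retained draw polished by
Nelder-Mead ascent of the same marginal likelihood; on three-source toys
it agrees with a brute-force 0.01-step grid search within 0.02.

### Tunable offsets (per mil)

| parameter | default | rationale |
|---|---|---|
| source-AA diet→collagen offset | 0 ± 0.5 | fractionation < 1 ‰ |
| trophic-C diet→collagen offset | 0 ± 1.0 | conservative allowance |
| Glx nitrogen-pool trophic shift | +8.0 ± 1.0 | consumer feeding-study convention |
| bulk model offsets (C / N) | +4.8 ± 0.5 / +5.5 ± 0.5 | collagen–diet conventions |
| charring correction (C / N) | +0.11 ± 0.11 / +0.31 ± 0.31 | charring-experiment convention |

All are `model_config()` / function arguments, not constants.

## GC-C-IRMS reduction

Derivatization to N-acetyl-i-propyl esters adds exogenous carbon. The
correction is exact isotope mass balance,
$n_{DC}\,\delta_{DC} = n_C\,\delta_C + n_D\,\delta_D$,
solved for the underivatized value; the correction factor $\delta_D$
(which absorbs the kinetic isotope effect of derivatization) is derived
from bracketing standards of known composition and averaged over the
session. The propagated uncertainty is

$$\sigma^2 = \sigma_S^2\Big(\frac{n_S}{n_C}\Big)^2
 + \sigma_{DS}^2\Big(\frac{n_S+n_D}{n_C}\Big)^2
 + \sigma_{DC}^2\Big(\frac{n_C+n_D}{n_C}\Big)^2.$$

The squared-ratio form is the one consistent with first-order Gaussian
propagation through the mass balance and is validated against a
Monte-Carlo oracle (10^5 draws, agreement within 5 %); an alternative
reading with unsquared second and third ratios is kept behind
`squared_ratios = FALSE` and demonstrably disagrees with the oracle.
Note the ratios are ≥ 1: derivatization-corrected uncertainties are
*amplified* relative to raw replicate scatter, most strongly for
heavily-derivatized, carbon-poor amino acids (Ala, Gly, Glx, Asx).

Other reduction choices:

* every injection (sample or standard) is normalised to its own
  co-injected norleucine peak, which removes common-mode instrumental
  drift and per-hydrolysis offsets exactly;
* nitrogen deltas pass through an ordinary least-squares calibration of
  true on raw values across the standard mixture; the fit's residual sd is
  folded into the output uncertainty;
* replicate and reference uncertainties combine as root-sum-of-squares
  (quadrature), validated against a Monte-Carlo oracle;
* all arithmetic stays on the delta scale; the linear approximation errs
  by < 0.02 ‰ at natural abundance, far below measurement noise;
* triplicates with a peak more than 3 replicate-sd from the median are
  flagged, never dropped; missing triplicates reduce `n_replicates` with a
  warning; a missing standard bracket is an error.

The default derivative carbon-count table (2 carbons per acetylated amine,
3 per esterified carboxyl; Asx/Glx 8, Lys/Tyr 7, others 5) is an argument,
not a constant, since derivative chemistry varies between laboratories.

## Cereal amino-acid prediction

Endogenous AAs cannot be recovered from charred grains. Modern grains of
the same C3 cereals give per-(AA, element) offsets from bulk — plants
synthesise all AAs de novo, so these offsets are assumed stable within a
crop type — which are pooled across the three species (a per-species mode
exists). Archaeological bulk values are charring-corrected, shifted by the
offsets, and pooled across grains, with bulk, charring, offset and
between-grain uncertainties combined in quadrature. Prediction is affine
in bulk delta, and output uncertainties are monotone in every input sd.
The same offset logic is applied symmetrically to δ13C and δ15N.

## What the synthetic generator does and does not emulate

`sim_scenario()` defaults encode the study conditions the pipeline is
designed around: 17 consumers (11 male, 6 female); three food groups — a
C3 cereal staple, terrestrial animal products, marine fish — whose
source-AA signals are separated by a Mahalanobis-style distance of at
least 3, with the marine source enriched in both 13C and 15N; per-signal
measurement sds drawn uniformly from 0.3–1.5 ‰; per-sex mean diets, in
protein shares, of (0.35, 0.35, 0.30) for males and (0.37, 0.4425,
0.1875) for females — a designed male/female marine-protein ratio of
exactly 1.6 — with individual diets drawn from a Dirichlet of
concentration 150 around the sex mean; GC sessions with triplicate
injections, standard brackets every three injections, 0.3 ‰ replicate
noise and optional linear drift; three modern and four charred grains.
Source template means are synthetic values in plausible first-century
Mediterranean ranges, never measurements.

Consumers are generated through the *same* forward model the fit inverts
(truth drawn on the whole-diet scale and converted to protein shares via
the sources' protein contents, so both scales have exact truths). Noise is
added only at the measurement level, which makes fitted coverage mildly
conservative. Consequently, passing recovery tests demonstrates the
estimator's correctness and calibration under its own assumptions — it
does **not** validate the metabolic routing against real physiology, real
baseline values, diagenesis, inter-AA error correlations, or laboratory
inter-comparability. Those require measured data.

With 17 individuals and 0.3–1.5 ‰ noise, the between-sex Wilcoxon test at
0.05 has only moderate power for a 1.6× marine ratio: a single synthetic
cohort may flag one, several or no sources. The acceptance checks
therefore score coverage and error over 100 seeded replicates, not
significance in one cohort.

## Problem sizes used by the tests and acceptance script

Recovery is scored on 100 single-consumer replicates per model (plus 50
four-source olive-oil replicates and 30 cross-check fits), each at the
full 5000 + 10000 iterations; Monte-Carlo oracles use 10^5 draws; the
grid-search oracle uses a 0.01 simplex step; the end-to-end determinism
check runs the full 17-individual pipeline twice. The acceptance script
reruns the cohort study and a 50-replicate calibration from a single
command-line seed.

## Known limitations

* Equal per-signal likelihood weights; no model for correlated errors
  across amino acids from a shared combustion interface.
* The whole-diet scale is dry weight, not an Atwater-style calorie
  conversion; for the dominant macronutrients the two are close but not
  identical.
* Trophic offsets and macronutrient δ13C offsets are configuration with
  literature-convention defaults; sensitivity to them is not explored
  automatically.
* The Glx nitrogen-pool trophic shift enters each source's value, so its
  ±1 ‰ uncertainty is treated as independent across sources; a shared
  consumer-side parameterisation would have the same posterior mean but a
  slightly larger predictive variance.
* Single-laboratory reduction model: no cross-instrument normalisation
  beyond the standard mixture itself.
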