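---
title: "Methods: partitioned-survival cost-effectiveness modelling of sotorasib versus docetaxel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Sotorasib, the first KRAS G12C inhibitor, prolongs progression-free
survival relative to docetaxel as second-line therapy for KRAS
G12C-mutated advanced non-small cell lung cancer, at a far higher drug
price. `psmcea` implements the health-economic comparison of the two
strategies from the Chinese and United States societal perspectives:
survival extrapolation from digitized Kaplan-Meier curves, a three-state
cohort model accumulating discounted costs and quality-adjusted
life-years (QALYs), the incremental cost-effectiveness ratio (ICER)
judged against willingness-to-pay (WTP) thresholds of 1-3x per-capita
GDP, and one-way plus probabilistic sensitivity analyses.

No patient-level data or digitized coordinates are publicly deposited
for the underlying trial, so the package ships a synthetic-data
generator calibrated to the published survival summaries; every stage of
the pipeline is exercised and tested against those synthetic inputs.

## Survival extrapolation

Digitized curves are lists of (time, survival) coordinates read off a
published Kaplan-Meier plot. Because no risk tables accompany them, no
individual-level likelihood exists; each of seven parametric families —
exponential, Weibull, gamma, generalized gamma, Gompertz, lognormal,
log-logistic — is fitted by nonlinear least squares on the
survival-probability scale,

$$\hat\theta = \arg\min_\theta \sum_i \big(S(t_i;\theta) - s_i\big)^2,$$

and families are compared with the Gaussian-residual least-squares AIC,
$n\log(\mathrm{RSS}/n) + 2k$, smallest value winning. Exact ties are
broken by fewer parameters, then by a fixed family order, so selection
is deterministic. Pseudo-individual-data reconstruction (Guyot-style) is
deliberately out of scope: it needs numbers-at-risk that digitized plots
alone do not provide.

Numerical choices: optimisation runs on an unconstrained scale (log for
positive parameters) from moment-style linearising starts (for the
lognormal, a regression of $\Phi^{-1}(1-s)$ on $\log t$), with a
Nelder-Mead pass polished by BFGS and three seeded jitter restarts on
failure; the exponential uses Brent. A family that still fails is
flagged and excluded from selection rather than erroring the run.
Noiseless round-trips recover all seven families' parameters to well
under 0.1% relative error.

A caveat the tests make explicit: with a nested, more flexible
competitor in the candidate set, least-squares AIC selection on noisy
monotonized points recovers the *generating family* only around 75-90%
of the time — the generalized gamma (which contains the lognormal,
Weibull, gamma and exponential as special cases) absorbs correlated
digitization noise and wins whenever its residual improvement factor
exceeds $e^{2/n}$. The selected fit's *median and landmark survival*
are nonetheless recovered accurately (see the acceptance script), which
is what the downstream model consumes.

## The cohort model

The model has three mutually exclusive states — progression-free (PFS),
progressed disease (PD), dead — and is parameterised by independent PFS
and OS curves, i.e. a partitioned-survival reading: occupancy is taken
directly off the curves,

$$\mathrm{PFS}(t) = S_{PFS}(t), \quad
  \mathrm{PD}(t) = \max\{0, S_{OS}(t) - S_{PFS}(t)\}, \quad
  \mathrm{dead}(t) = 1 - S_{OS}(t),$$

evaluated per cycle. Independently extrapolated curves can cross in the
tails; `enforce_endpoint_coherence()` reports where, and the trace clips
PD at zero there with dead $= 1 - \mathrm{PFS}$ so occupancy still sums
to one.

Tunable structural parameters, defaults and reasons:

* **Cycle length** 30.4375 days (one month) — not stated by the source
  analysis; 120 monthly cycles give a 10-year horizon, consistent with
  second-line NSCLC survival. Configurable; halving the cycle moves
  totals by under 2% in the tests.
* **Discount rates** 5%/year (China) and 3%/year (US), the respective
  national guideline conventions; swept 0-8% in the one-way analysis
  because discounting is a leading tornado driver.
* **Half-cycle correction** on by default: occupancy is evaluated at
  cycle midpoints, which brings the discrete trace within 1% of the
  continuous-time closed form already at weekly cycles.
* **Treatment duration**: drug cost accrues while progression-free
  (treat-to-progression), the standard assumption for a drug given
  until progression.
* **Adverse events**: grade >= 3 only, as one-time incidence-weighted
  costs in cycle 1. The matching QALY decrement exists behind
  `apply_ae_disutility` but defaults off, mirroring the base case it
  reproduces, whose stated limitation is exactly that AE disutilities
  were not applied; when enabled it is a one-cycle decrement.
* **Terminal care** is charged once per new death in the cycle of death
  entry; best supportive care accrues per cycle in PD; follow-up and
  hospitalization accrue while alive.
* **Currency**: all computation in USD; RMB-denominated inputs convert
  at 6.92 RMB/USD at load time.

## Economics

With $\Delta C$ and $\Delta E$ the incremental cost and QALYs,
$\mathrm{ICER} = \Delta C / \Delta E$ for trade-offs; strict dominance
in either direction suppresses the ratio. WTP thresholds are exact
products of per-capita GDP (presets $12{,}374.81 for China, $76{,}348
for the US) with multipliers 1 and 3. An ICER at or below 1x GDP is
"cost-effective", at or below 3x "acceptable", above "not
cost-effective"; a value exactly at a boundary takes the more
favourable label (documented tie rule). Net monetary benefit
$\lambda E - C$ underlies the acceptability curve.

## Sensitivity analyses

**One-way (tornado).** Each parameter in turn is set to its low and
high bound with the rest at base, and the ICER spread ranks the
entries. Bounds absent from the source table default to +/-20% of base
(utilities capped at 1). A bound that pushes the comparison out of
trade-off status is flagged, not dropped.

**Probabilistic.** 1,000 second-order Monte Carlo draws jointly resample
all cost and utility parameters; survival-curve parameters are not
resampled, matching the scope of the analysis reproduced. Distributions
are moment-matched to the table: the bound width is read as a 95%
interval, $s = (\mathrm{high}-\mathrm{low})/(2\times 1.96)$, beta
parameters follow the mean/variance identities and gamma uses
shape $= m^2/s^2$, scale $= s^2/m$. Rows labelled beta whose mean
cannot satisfy the beta identities — including the source table's
beta-labelled cost rows — fall back to uniform(low, high) with a
warning, the documented degenerate-input rule. Each parameter draws
from its own substream (seeded from the master seed and the parameter
name), so adding or removing a parameter never perturbs the others'
draws; runs are bitwise reproducible seed-for-seed.

The acceptability curve reports, per WTP value $\lambda$ on a grid
(default 0-250,000 by 2,500), the fraction of draws in which the
intervention has strictly higher net monetary benefit, ties counting to
the comparator; `ceac_crossover()` returns the first grid point at or
above 50%.

## The synthetic-data generator

`trial_like_bundle()` emulates the inputs the analysis consumes:

* **PFS curves** are lognormals calibrated *exactly* to the published
  trial summaries — sotorasib median 5.6 months with 24.8% 12-month
  PFS, docetaxel 4.5 months with 10.1% — via
  $\mu = \ln(\mathrm{median})$,
  $\sigma = (\ln t - \mu)/\Phi^{-1}(1 - s_t)$.
* **OS curves** have no published summaries in the available text; the
  stand-ins are lognormals with medians 10.65 and 11.3 months sharing
  each arm's PFS $\sigma$, which makes $S_{OS} \ge S_{PFS}$ hold
  identically (same shape, shifted location), so the bundle is coherent
  by construction. They are labelled synthetic throughout.
* **Digitization error** is additive Gaussian noise on the survival
  scale (default sd 0.01, 40 points per curve) followed by clamping to
  $[0,1]$ and running-minimum monotonization — mimicking plot-digitizer
  error without modelling risk tables. Grids default to 18 months (PFS)
  and 24 months (OS).
* **The parameter table** reproduces the published Chinese-perspective
  input table verbatim (including one adverse-event utility row whose
  printed base value lies outside its own printed bounds, which the
  validator warns about rather than rejects), and adds flagged
  synthetic placeholders for what the source omits: per-cycle follow-up
  and hospitalization costs, all grade >= 3 AE incidences, and the US
  cost side.

What passing tests on these inputs do and do not show: they validate
the pipeline's arithmetic, calibration, invariants and reproducibility
under a known generating process; they cannot validate the published
headline ICERs, because the fitted survival parameters, AE incidences,
follow-up/hospitalization costs, cycle length and discount rates of the
original analysis live in an unreproduced supplement — and the
published comparison table is internally inconsistent (its printed
ICERs do not equal printed $\Delta C/\Delta E$; one printed QALY total
is negative, which the stated utilities cannot produce). The package
therefore reproduces the arithmetic *relations* and the printed
survival summaries, not the misprints.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
the analysis's native scale — 120 cycles, 1,000 PSA draws, 40-point
curves, with 20-50 seeded replicates for the recovery and selection
studies — chosen because the whole suite completes in well under a
minute while keeping Monte-Carlo error far below the tolerances tested.

## Known limitations

* Partitioned survival ignores any correlation between PFS and OS and
  cannot model post-progression treatment switching.
* Least-squares fitting weights all digitized points equally; late
  points digitized from few at-risk patients carry the same weight as
  early ones.
* The US-perspective cost inputs and all AE incidences are synthetic
  placeholders; results under that perspective characterise the
  machinery, not the actual US price environment.
* Utilities are time-constant and AE disutilities, when enabled, are a
  crude one-cycle decrement.
* PSA leaves survival-curve uncertainty out by design; a
  multivariate-normal resampling of fit parameters would be the natural
  extension.
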