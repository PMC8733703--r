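---
title: "Hybrid modeling of fed-batch CHO bioprocesses across scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid modeling of fed-batch CHO bioprocesses across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridoe)
```

## The modeling problem

Process development for mammalian (CHO) cell culture characterizes how
critical process parameters (CPPs) — here the cultivation temperature and
the added-glucose level of the feed (F1/F2/F3 = +10/20/30 g/L) — shape the
viable cell concentration (VCC) and the product titer.  Characterization
experiments are cheap in shake flasks (0.3 L, bolus-fed) and expensive in
bioreactors (15 L, continuously fed), so two questions matter:

1. **Transferability** — can a model trained mostly on shake-flask data
   estimate 15 L bioreactor runs?
2. **Intensification** — can runs with intra-experimental CPP shifts
   (intensified design of experiments, iDoE) replace several static runs as
   training material?

`hybridoe` answers both with a *serial hybrid* (grey-box) model.  A small
feed-forward network estimates the specific rates from measurable process
inputs,

$$ (\mu,\; v_{P/X}) \;=\; f_{\mathrm{ANN}}(T,\; G_{\mathrm{feed}},\;
   \mathrm{Gln},\; \mathrm{Asn},\; \mathrm{Ala},\; \mathrm{Asp/Glu}), $$

and those rates drive the mechanistic fed-batch mass balances

$$ \frac{dX}{dt} = \mu X - D X, \qquad
   \frac{dP}{dt} = v_{P/X} X - D P, $$

where $D$ is the dilution rate (feed flow over working volume, zero
between the daily bolus additions of the shake flasks, which instead act as
instantaneous dilution events).  The network has one hidden layer of four
tanh units and a linear two-unit output; inputs are z-scored with
training-set statistics and outputs are expressed in scaled rate units
(references 0.03 h⁻¹ for growth, 5×10⁻⁴ g/L/h per 10⁶ cells/mL for
production).

Because the measured inputs do not feed back on the propagated states, the
balances are linear in $(X, P)$ given the rate trajectories and prediction
reduces to quadrature:
$X(t) = X_0\,\Phi(t)\,e^{A(t)}$ with $A=\int\mu\,dt$ and
$P(t) = \Phi(t)\,(P_0 + X_0 \int v\,e^{A}dt)$, where $\Phi(t) = V_0/V(t)$
is the dilution response of the feed schedule.  This yields closed-form
weight sensitivities ("forward sensitivities through the ODE"), which the
trainer uses as its default Jacobian; a central finite-difference Jacobian
is available as an independent check and the two agree to better than
10⁻³ relative (asserted in the test suite).

## Training, validation, ensembling

Training minimizes the concatenated residuals of VCC and titer at the
sampling times, each block divided by its training-set mean so both targets
contribute on the NRMSE scale, by a hand-written Levenberg–Marquardt loop
with an L2 (ridge) penalty, implemented through residual augmentation.  The
quality measure throughout is the normalized root mean square error

$$ \mathrm{NRMSE}\,[\%] = \frac{100}{\bar y}\,
   \sqrt{\tfrac1N \textstyle\sum_t \big(y(t)-\hat y(t)\big)^2}. $$

Cross-validation splits the runs (never time points) into training and
validation partitions: repeated random 60/40 splits for the large
campaigns, leave-one-run-out for the six iDoE runs.  Within each partition
training stops once the validation error stops improving, and the weights
at the validation minimum are kept — the ensemble gathers one such model
per partition.  The ensemble estimate is the member mean; the uncertainty
band is the member spread $SD(t) = \sqrt{\frac{1}{n-1}\sum_i
(\hat y_{\mathrm{avg}}(t)-\hat y_i(t))^2}$ with the confidence interval
$\hat y_{\mathrm{avg}} \pm SD$.

Two robustness choices deserve explanation, because the generic defaults
would be different:

* **Ridge strength.**  `train_config()` defaults to a light decay of
  1e-4, appropriate for generic least-squares problems.  `fit_hybrid()`
  however trains a 38-weight network on ~20 runs and then *exponentiates*
  the integrated growth rate; a steep spurious surface in a sparsely
  observed corner of the input space turns into a grossly implausible
  trajectory.  Its default is therefore a strong ridge (0.3), chosen as the
  smallest value in a decade scan (10⁻³…0.5) at which held-out error
  stabilized across split seeds while the training NRMSE stayed near the
  observation noise floor.
* **Plausibility screen.**  `average_predict()` excludes a member whose
  VCC prediction exceeds 40×10⁶ cells/mL anywhere — far above anything
  fed-batch CHO processes of this type reach — using the same exclusion
  pathway that handles failing members.  With ten members a single wild
  extrapolation would otherwise dominate the average.

## Input selection

The input-identification workflow mirrors a three-step screen: (i) PCA on
the autoscaled candidates and squared correlations against VCC and titer,
(ii) collinearity exclusion (|r| > 0.95; the partner with lower mean R² to
the targets is dropped — in the simulated data proline tracks
hydroxyproline), and (iii) backward elimination: every single-input-removed
subset is refitted at reduced cross-validation, the cheapest removal is
applied, and exploration stops once the best removal exceeds the lowest
validation error seen so far by more than 1 percentage point of NRMSE; the
reported set is the one at that minimum.  Comparisons within a step share
split and initialization seeds, so candidate sets are compared on identical
partitions.

## The synthetic ground truth

The study the package emulates deposited no raw data, so a simulator
replaces it and every claim is tested against its known truth.  Its design
goal is to reproduce the published center-point phenotype with one rate law
shared by both scales — no scale flag anywhere:

* shake flask (bolus): VCC peaks near 20×10⁶ cells/mL on day 9, titer
  peaks ≈0.6 g/L on day 10, viability crosses 70 % so that the run is
  harvested on day 11;
* bioreactor (continuous): monotone growth to ≈10.5×10⁶ cells/mL and
  ≈0.76 g/L at day 15, viability far above the harvest threshold.

The mechanism that makes one rate law produce both phenotypes is the
feeding mode.  Growth follows a convex (Hill-2) glutamine response with
maintenance-dominated glutamine uptake.  Daily boluses create glutamine
sawtooths: pulsed supply spends hours above the response knee and is
therefore much more growth-effective than the continuous-feed quasi-steady
state, which settles at a pinned low concentration (supply = consumption)
— the bioreactor grows slowly and monotonically while the flask races
ahead.  Consumption of glutamine *at high concentration* overflows to
alanine (classic glutaminolysis), so the flask accumulates alanine two to
three times faster; alanine drives a sharply nonlinear (Hill-4) death and
product-degradation term and the stress integral behind the viability
decline — producing the day-9 peak, the late titer decline and the day-11
harvest.  The overflow yield rises with effective temperature, so warm
runs crash earlier (day 10 at 37 °C, day 12+ at 31 °C across the
factorial).

Other deliberate features:

* **Adaptation lag.**  Cells follow CPP shifts through a first-order lag
  with τ = 48 h (`effective_cpp()`), so an iDoE shift takes roughly two
  days to take full effect.  The model inputs carry the *set-point* steps,
  which makes the lag a structural (and realistic) source of transfer
  error.
* **Sampling.**  Daily samples from day 0, plus a sample 6 h after every
  CPP shift in intensified runs.  The daily bolus is added immediately
  before the sample is drawn, so sampled values reflect the post-addition
  state; the volume bookkeeping, the integrator and the predictor all use
  the same convention.  (With the opposite, pre-bolus convention the
  measured glutamine of every fed-batch flask sample is ≈0 and the rate
  surface is not identifiable from daily data at all.)
* **Media lots.**  Aspartate and glutamate start from one of three media
  lots, cycled deterministically over the run numbers, so the
  aspartate/glutamate ratio carries run-specific information that no other
  input can substitute.  Keeping the lot assignment deterministic keeps
  noiseless simulations seed-independent.
* **Noise.**  Multiplicative lognormal observation noise: 5 % CV on VCC
  and analytes, 7 % on titer and 2 % on viability (trypan-blue counting
  precision).  The harvest rule is applied to the *observed* viability, so
  noisy flask runs are truncated on slightly varying days, as in practice.
* **Decoy analytes.**  Serine pins to a quasi-steady level within days,
  tyrosine drifts slowly, glycine accumulates with the cumulative feed,
  hydroxyproline declines moderately and proline tracks it collinearly
  (the collinearity-screen fixture).  They are realistic but carry no
  information about the true rates beyond what the six model inputs
  already provide.

What the simulator does *not* emulate: oxygen/CO₂/pH dynamics, gradients
and shear at scale, segregated (cell-cycle) population structure,
memory effects of earlier CPP exposure beyond the first-order lag, and
assay-specific error structure (dropouts, batch effects).  Passing the
recovery experiments therefore shows that the pipeline is sound and that
the study's conclusions are reachable *under these idealizations*, not
that they hold for any particular real process.

## Numerical choices

* Mass-balance integration: `deSolve::lsoda` piecewise between bolus and
  shift events at rtol 1e-8 for the general-purpose integrator; the hybrid
  predictor uses trapezoidal quadrature on a grid with duplicated nodes at
  input discontinuities (1 h spacing by default; refining changes states
  by <1e-6 relative on smooth rate inputs).  The simulator records its
  dense truth on a quarter-hour grid because the bolus-driven nutrient
  transients are fast.
* Specific-rate estimation from data: cubic smoothing splines
  (`stats::smooth.spline`, GCV smoothing by default) on the log of the
  dilution-corrected VCC and on the dilution-corrected titer;
  $\mu = d\ln X_c/dt$, $v_{P/X} = \Phi\, P_c'/X$.  At daily sampling this
  estimates the *daily-effective* rates; intra-day sawtooths are
  averaged, which is exactly what the hybrid model sees as well.
* Levenberg–Marquardt: Marquardt-scaled damping (×10 on rejection, ×0.1 on
  acceptance), acceptance only on penalized-SSE decrease, singular damped
  systems handled by escalation; degenerate zero-residual objectives
  return immediately.
* Aspartate/glutamate ratio: denominator floored at 1e-3 g/L.
* States are clipped at zero if the integrator undershoots (warning beyond
  1e-9).

## Problem sizes

The packaged experiments are sized for a single CPU: ensembles use 10
random-split partitions (or 6 leave-one-run-out partitions), up to 200
accepted LM iterations with validation patience 15, and 3 random restarts
per partition; backward elimination runs at 2 cross-validation repeats, a
2 h training grid, 50-80 iterations and 1-2 restarts.  A full transfer
experiment trains in a few minutes; the complete input-selection replicate
set takes on the order of ten minutes.  The defaults of
`cv_config()` (60/40 splits, 40 repeats) reflect the full study design and
are what `analysis/` scripts reduce from.

## Known limitations

* The exponential state propagation makes the VCC objective ill-tempered:
  small systematic growth-rate biases compound over 360 h.  The strong
  ridge and the plausibility screen manage, but do not remove, this.
* Measured-input interpolation is linear between daily samples; the true
  intra-day nutrient dynamics of bolus-fed runs are invisible to the
  model (and to any model fed daily offline data).
* The iDoE test runs visit CPP-by-state combinations absent from every
  training run; errors there are genuine extrapolation errors and remain
  the largest contribution to test NRMSE.
* `estimate_specific_rates` reports negative rates freely; they are
  data-derived quantities, not constrained to the simulator's bounds.
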