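---
title: "Chamber N2O fluxes and isotopocule-based source partitioning: methods"
author: "n2oiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber N2O fluxes and isotopocule-based source partitioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2oiso)
```

# The measurement problem

Agricultural soils emit nitrous oxide through two microbial pathways that
overlap in space and time: nitrification (ammonium oxidation) and
denitrification (nitrate reduction, which can proceed past N2O to N2).
Separating their contributions matters because mitigation levers differ
between the pathways, yet bulk flux measurements cannot tell them apart.
This package implements the observational inference chain that turns
automatic-chamber gas-bag samples into (i) areal N2O fluxes, (ii) microbial
isotopic source signatures, (iii) Monte-Carlo estimates of the
denitrification-group versus nitrification source split, and (iv) the
soil-water and model-evaluation diagnostics used to confront a daily
biogeochemical model with those observations.

# Flux estimation

Each chamber closure yields four headspace bags with fill times
3.50/7.25/11.50/14.25 min after closure (configurable). In a closed chamber
of headspace height $h$ the mole fraction grows linearly while the surface
flux is constant, so the flux follows from the OLS slope $b$ (ppb h$^{-1}$)
of concentration against time via the ideal-gas molar density:

$$F \;=\; b \cdot 10^{-9}\,\frac{p}{R\,T}\; M_{\mathrm{N_2O\text{-}N}} \cdot 10^{6} \cdot h
\quad [\mu g\ \mathrm{N_2O\text{-}N\,m^{-2}\,h^{-1}}],$$

with $M = 28$ g N per mol N2O (both nitrogen atoms). Pressure is a constant
site value from the configuration; temperature is per closure. Acceptance
requires $R^2 \ge 0.7$ of the concentration regression. A closure with zero
concentration variance has no defined $R^2$; we record flux 0 and reject it,
the conservative reading of the gate.

Weekly means are taken over accepted estimates in ISO weeks. Their standard
error combines the two error sources as

$$SE_w = \sqrt{\frac{\mathrm{var}(\bar F_c)}{n_c} + \overline{se_i^2}},$$

the between-chamber variance of chamber means plus the mean squared
regression SE. This explicit formula is our choice; with one chamber it
collapses to the regression error alone. Cumulative emissions integrate the
weekly means as a step function (each mean over its week), with interior
gaps linearly interpolated between adjacent weekly means and edge gaps
extended; units convert by $10^{-5}$ from $\mu$g m$^{-2}$ to kg ha$^{-1}$.
The integration rule is a design choice — any rule consistent at weekly
resolution differs by at most one week's worth of flux curvature.

# Keeling-plot source signatures

Every bag is a two-endmember mixture of ambient air and soil-derived N2O,
so each delta is linear in reciprocal concentration and the intercept of
$\delta$ vs $1/C$ estimates the soil source. We fit OLS per channel
($\delta^{15}$N$^{\alpha}$, $\delta^{15}$N$^{\beta}$, $\delta^{18}$O);
error-in-variables alternatives exist but the operational convention is
OLS. Site preference and bulk are derived from the averaged intercepts:
$SP = \delta^{15}N^{\alpha} - \delta^{15}N^{\beta}$,
$\delta^{15}N^{bulk} = (\delta^{15}N^{\alpha} + \delta^{15}N^{\beta})/2$.
When duplicate analyzers measured the same bags, intercepts are averaged
per channel *before* SP and bulk are computed.

Quality control grades each fit by the deviation of its prediction at
ambient concentration from the known ambient composition: within 4 permil
Q1, 4–6 Q2, 6–8 Q3, beyond 8 rejected (inclusive boundaries). A signature
is only interpreted when the flux clears 75 $\mu$g N2O-N m$^{-2}$ h$^{-1}$
and the concentration regression clears $R^2 \ge 0.7$ — low-flux Keeling
intercepts are extrapolations over a tiny $1/C$ range and are essentially
unconstrained. The $\delta^{18}$O channel is classified independently and
its failure does not reject the nitrogen signature, because ambient
agreement filters $\delta^{18}$O far more often in practice.

A quantitative caution that shapes several defaults: straightforward OLS
error propagation shows that at a flux of ~100 $\mu$g N2O-N m$^{-2}$
h$^{-1}$, 15-min closures and 0.3 permil per-bag delta noise, the intercept
standard error is about nine times the per-bag noise (~2.7 permil). The
75-unit gate does not make intercepts precise to 1 permil; it makes them
usable at the several-permil level, which is also why the quality classes
span 8 permil. The package's tests verify that the empirical intercept
error matches this analytic propagation.

# Monte-Carlo source partitioning

Emitted signatures are modeled as a production-stage mixture of a
denitrification-group endmember (bacterial plus nitrifier denitrification,
SP box $-5\ldots+5$ permil) and a nitrification endmember (SP box
$+33\ldots+38$ permil), enriched by partial reduction of the produced pool
to N2. Reduction follows the closed-system Rayleigh form on the residual
pool,

$$\delta_{emit} = \delta_{prod} + \varepsilon \ln(1-r), \qquad \varepsilon < 0,$$

with defaults $\varepsilon_{SP} = -5$, $\varepsilon_{bulk} = -7$,
$\varepsilon_{18O} = -15$ permil — literature-typical magnitudes, exposed in
the configuration because no single site value exists. Per draw we sample
endmembers uniformly within their boxes, $r$ uniformly in $[0, r_{max})$,
and the observed SP from a Gaussian with the assumed measurement sd
(`sd_sp_obs`, default 0.5 permil); we invert to production space, solve the
SP mixing equation for $f_{den}$, and weight the draw by a Gaussian
likelihood (sd 2 permil) of the bulk-channel residual. Only SP identifies
the fraction; bulk ranges are broad and overlapping and act solely through
the weighting. The published Monte-Carlo mass-balance tools in this area do
not document their exact samplers, so this uniform-prior weighted sampler
is our generic equivalent with every prior in config.

Sampling the observation uncertainty is essential, not cosmetic: with
point endmembers and no reduction prior the box sampler is otherwise
degenerate — every draw returns the same fraction and the credible
interval collapses to a point. Propagating the SP measurement sd gives the
posterior its width, and with the assumed sd matching the true noise the
95% percentile interval attains nominal coverage (the acceptance tests
check coverage over 200 replicates).

Reported quantities per signature: the weighted mean of draws clipped to
$[0,1]$ (with $f_{nit} = 1 - f_{den}$ by construction) and raw,
deliberately unclipped 2.5/97.5 weighted percentiles. Published interval
estimates for this quantity can exceed $[0,1]$, and rather than guess the
constraint convention we retain the raw percentiles so either reading is
available.

The dual-isotope mapping table pairs each signature's (SP, bulk)
coordinates with the weekly flux and the 7-day antecedent rainfall, the
window being the seven calendar days up to and including the sampling day.
The theoretical reduction line through any starting point has constant
slope $\varepsilon_{SP}/\varepsilon_{bulk}$ in the (bulk, SP) plane.

An identifiability caveat carried through from the science: rising SP can
mean more nitrification *or* more N2O reduction. The package exposes the
direction of this ambiguity — switching the reduction correction off
inflates the apparent nitrification share — rather than resolving it.

# Soil water

Volumetric water content converts to water-filled pore space by

$$WFPS = 100\,\frac{VWC}{1 - BD/PD}$$

with bulk density 1.39 g cm$^{-3}$ and particle density 2.65 g cm$^{-3}$ as
defaults. Values above 100% are retained and flagged, never clipped —
a sensor/BD mismatch is diagnostic information. Sub-daily records are
averaged to days; dates missing from the primary plot are filled by direct
substitution of the neighbor plot's daily mean (no bias adjustment, since
nothing more is defensible without overlap calibration) and flagged.
Observed-vs-simulated diagnostics use the squared Pearson correlation on
common dates (not regression-through-origin $R^2$), inclusive day counts at
or above field capacity (default 78.87% WFPS) and at or below wilting point
(39.33%), and the series ranges. Inclusive thresholds match the
"at or above / at or below" reading of those reference states.

# Model evaluation

Daily model output (total N2O, N2O from each pathway, N2, g N ha$^{-1}$
d$^{-1}$, plus simulated WFPS) is consumed from a documented delimited
format; native model output dialects vary by build and are out of scope.
The reader enforces the pathway budget
`n2o_total == n2o_nit + n2o_denit` to $10^{-6}$. Evaluation computes
cumulative totals, pathway shares, cumulative N2, and the RMSE
$\sqrt{\sum_i (S_i - O_i)^2 / n}$ between the simulated cumulative total —
interpolated to the observation dates — and the observed cumulative series.
Interpolating the simulation rather than the observations avoids inventing
observed values. Monthly weather comparisons between years use the Welch
two-sample statistic with Welch–Satterthwaite degrees of freedom on
calendar months; the degenerate zero-variance/equal-means case is reported
as $t = 0$, $p = 1$.

# The synthetic-data generator

The generator produces every input format the pipeline reads, and its
defaults are the study conditions of the tests: bag times
3.50/7.25/11.50/14.25 min in 15-min closures every 4 h; ambient background
330 ppb with bulk 6.7, SP 18.7 and $\delta^{18}$O 44.6 permil
(literature-typical values, flagged as non-site constants); chamber height
0.3 m and pressure 96 600 Pa (~440 m a.s.l.); per-bag independent Gaussian
noise, 1 ppb on concentration and 0.3 permil on deltas at the realistic
operating point. Fluxes around 103 $\mu$g N2O-N m$^{-2}$ h$^{-1}$ are used
as the canonical above-gate scale. Concentrations accumulate linearly from
the inverse of the flux equation, and deltas follow exact conservative
mixing computed with the *noiseless* added concentration, so that at zero
noise the generator and the estimators are exact inverse pairs — the basis
of the identity tests.

What the generator does not emulate: diurnal temperature coupling of
fluxes, bag-fill duration effects (15 s fills are treated as instantaneous
samples), instrument drift or calibration structure (noise is independent
per bag, whereas real analyzer error has common-mode components),
non-linear chamber feedback at long closures, and any mechanistic link
between soil moisture and emission. Passing tests therefore demonstrate
the correctness and calibration of the *inference chain* under its own
assumptions, not the field performance of the measurement system.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero concentration variance →
rejected zero flux; insufficient Keeling spread (max/min concentration
below $1 + 10^{-3}$) → degenerate-fit error; constant WFPS series →
undefined $r^2$ reported as missing; zero-variance Welch samples → the
$t=0, p=1$ convention. Weighted percentiles interpolate the weighted
empirical CDF at cumulative-weight midpoints. All randomness flows through
explicit integer seeds: campaigns, partitions and pipeline bundles are
byte-identical under a repeated seed.

The test and acceptance workloads use sizes chosen to make Monte-Carlo
checks statistically decisive while remaining quick on a laptop: 1000
closures for flux calibration, 500 replicates for Keeling recovery, 200
replicate signatures × 2000 draws for partition recovery and coverage, and
$10^5$ draws for the convergence check against the algebraic two-endmember
solution.

# Known limitations

* Source attribution uses the simplified two-way categorization
  (denitrification group vs nitrification); fungal denitrification and
  other pathways with overlapping signatures are not separable here.
* Only SP and bulk enter the partition; $\delta^{18}$O is carried but not
  modeled.
* The endmember boxes and reduction isotope effects are literature ranges,
  not site measurements; conclusions inherit their width.
* The biogeochemical model itself is not run; its daily outputs are
  consumed as data.
* Keeling intercepts at near-gate fluxes carry several-permil
  uncertainties; single-closure source signatures should be read
  accordingly.
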