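---
title: "Modelling soybean root elongation under combined mechanical and hydric stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soybean root elongation under combined mechanical and hydric stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootstress)
```

## The problem

Seedling roots growing through soil face two coupled physical stresses:
mechanical impedance, measured as soil penetration resistance $Q_p$ (MPa),
and hydric stress, which spans both water deficit and poor aeration near
saturation. Soil structure modulates both: intact no-tillage soil ("Field")
retains continuous biopores that offer low-resistance, well-aerated pathways,
while sieved and re-packed soil ("Packed") of the same material does not.
`rootstress` implements a semi-empirical pipeline that quantifies this
structure effect for soybean primary roots in a very clayey Oxisol
(particle density 2.96 Mg m$^{-3}$, Proctor maximum bulk density
1.53 Mg m$^{-3}$).

The pipeline has four stages, each a package module:

1. **Soil physical state.** From bulk density $BD$ and gravimetric water
   content $w$, derive total porosity $TP$ (mass route
   $(m_{sat}-m_{dry})/V$, or $1 - BD/PD$ when saturation masses are
   absent), volumetric water content $\theta = w \cdot BD$ (water density
   1 Mg m$^{-3}$), air-filled porosity $TP - \theta$, degree of saturation
   $S = 100\,\theta/TP$ (%), and degree of compactness
   $DC = 100\,BD/BD_{proctor}$ (%).
2. **Mechanical stress.** The Busscher power law
   $Q_p = a \cdot BD^{b} \cdot w^{c}$, fitted per structure by
   Levenberg–Marquardt from a log-linear OLS start. $b>0$, $c<0$ on
   sensible soils; the model is singular at $w = 0$.
3. **Elongation surface.** Relative root elongation
   $$R_e(Q_p, S) = a \exp\!\left(-\tfrac12\left[\left(\tfrac{S - x_0}{b}\right)^2
     + \left(\tfrac{Q_p - y_0}{c}\right)^2\right]\right)$$
   a five-parameter bivariate Gaussian fitted per structure, with the
   *calculated* $Q_p$ from stage 2 as the mechanical coordinate.
4. **Evaluation.** A 70/30 fit/validation split stratified by matric
   potential, and agreement metrics on the held-out set: RMSE,
   coefficient of residual mass $CRM = (\Sigma O - \Sigma P)/\Sigma O$,
   Pearson $r$, and the Willmott index
   $d = 1 - \Sigma(P_i - O_i)^2 / \Sigma(|P_i - \bar O| + |O_i - \bar O|)^2$.

## Reference parameter sets and what they predict

The package ships fitted parameter sets for both structures of the
reference Oxisol. Their key qualitative feature is that both resistance
optima $y_0$ are negative (−8.66 MPa Field, −27.16 MPa Packed): over the
physically reachable range, elongation declines monotonically with $Q_p$,
and far more steeply in Packed soil.

```{r worked}
field <- reference_surface_params("Field")
packed <- reference_surface_params("Packed")
round(c(field = relative_elongation(field, qp = 0.3, s = 60),
        packed = relative_elongation(packed, qp = 0.3, s = 60)), 2)
# mechanical stress contrast: Qp 1 -> 3.5 MPa at S = 60 %
round(c(field = stress_reduction(field, "s", 60, 1, 3.5),
        packed = stress_reduction(packed, "s", 60, 1, 3.5)))
```

At low resistance the Packed surface predicts the higher elongation (loose,
freshly disturbed soil is easy to penetrate); as resistance grows the Field
surface retains a large advantage — the structural mitigation the model
exists to quantify.

## Interpreting the Gaussian parameters

The surface is a descriptive response function, not a mechanistic one, and
its parameters should not be interpreted individually. Two of them are
weakly identified whenever the optimum sits outside the observed data:

* With $y_0 \ll \min(Q_p)$, the amplitude $a$ trades off against
  $(y_0, c)$ — very different $(a, y_0, c)$ triples produce nearly
  identical surfaces over the data hull. The Packed reference amplitude
  (994) versus Field (2.52) reflects this, not a biological difference.
* The Field saturation optimum $x_0 \approx 34\,\%$ similarly lies below
  the observed $S$ range.

The package therefore treats **surface agreement**, the maximum absolute
difference in predicted $R_e$ over the data hull, as the recovery
criterion, and `recovery_experiment()` reports it alongside raw parameter
biases and their standard errors.

## Fitting: numerical choices

* Both fits use Levenberg–Marquardt (`minpack.lm::nlsLM`), the damped
  variant of Gauss–Newton with the same fixed points.
* **Busscher:** initialised from OLS on
  $\log Q_p = \log a + b \log BD + c \log w$, which is the exact solution
  for noise-free data; convergence tolerances $10^{-12}$, 200 iterations.
  Alongside the conventional $R^2 = 1 - SSE/SST$ (`r2_sst`) the fit
  reports the ratio convention $1 - SS_{res}/SS_{reg}$ (`r2`) used
  historically with this model family.
* **Surface:** multi-start (default 20 starts) because the 5-parameter
  problem has local minima. One start is data-driven (peak at the highest
  observed point); one is analytic — $\log R_e$ is exactly quadratic in
  $(S, Q_p)$, so OLS of $\log R_e$ on $(S, S^2, Q_p, Q_p^2)$ inverts the
  model in closed form whenever the fitted quadratic opens downward; the
  remainder are random draws from boxes scaled to the data spread, with
  $y_0$ allowed down to three data-ranges below the observed minimum and
  half of the draws amplitude-matched through the highest observed point.
  Starts are drawn deterministically from the supplied seed; the best
  converged start by SSE wins. Widths and amplitude are bounded positive;
  $x_0$ and $y_0$ are unconstrained in sign (constraining $y_0 \ge 0$
  would make Packed-like fits unreachable).
* The water-content variable of the Busscher fit is gravimetric
  (kg kg$^{-1}$), the convention under which the reference coefficients
  reproduce their printed predictions; the fitting functions simply take a
  `water_content` column, so a volumetric variable can be supplied
  instead.
* Predictions are not clamped to $[0, 1]$ by default (the Packed surface
  legitimately exceeds 1 near its extrapolated peak); `clamp = TRUE` is
  available, and the structure contrast flags supra-unity nodes.
* $\theta > TP$ (apparent $S > 100\,\%$) is flagged, not rejected, with a
  0.02 m$^3$ m$^{-3}$ tolerance — routine measurement noise in saturation
  tables should not drop samples.
* Undefined metrics (zero variance, zero denominator) are reported as
  flagged `NA`, never silently as 0.

## The fit/validation split

The split is stratified by matric potential so that every hydric level
stays represented on both sides — an unstratified 70/30 draw can leave a
potential unrepresented in validation. Within strata, fit counts are
allocated by largest remainder, which keeps every stratum within one
sample of its target while the overall split matches `round(0.7 n)`
(110 → 77/33, 90 → 63/27). The split is deterministic for a fixed seed;
strata with fewer than two samples go wholly to the fit set with a
warning.

## What the synthetic generator emulates — and what it does not

No measured dataset accompanies the reference parameter sets, so
`generate_experiment()` produces tables with the statistical structure the
analysis assumes: 22 Field and 18 Packed columns at each of five matric
potentials (−10, −60, −100, −1000, −5000 hPa; 200 samples), Packed bulk
densities cycling {1.02, 1.10, 1.18, 1.26, 1.34, 1.42} Mg m$^{-3}$, Field
bulk density a truncated normal (mean 1.18, sd 0.10, bounds 1.00–1.45
Mg m$^{-3}$) mimicking the field's spread of compactness (66–93 %).

Water content comes from a synthetic van Genuchten retention curve
($\theta_r = 0.25$, $\theta_s = 0.65$ m$^3$ m$^{-3}$,
$\alpha = 0.02$ hPa$^{-1}$, $n = 1.25$ — plausible for a very clayey
Oxisol, and exposed in the configuration), with the per-row saturated
content capped at total porosity so $S$ never exceeds 100 %. True
resistance comes from the structure's Busscher truth, true elongation from
its surface truth evaluated at the row's own $(Q_p, S)$; measurement noise
is additive Gaussian — sd 0.1 MPa on resistance (floored at 0.01 MPa, an
instrument-resolution limit) and sd 0.05 on relative elongation (truncated
at 0). The reference rate converting relative elongation to cm d$^{-1}$
defaults to 4.83 cm d$^{-1}$, the value implied by paired rate/relative
values in the reference results (inferred, not measured).

Passing recovery tests on these tables show that the pipeline inverts its
own generating process — unbiased parameter recovery, held-out RMSE at the
injected noise level — under Gaussian noise and a shared retention curve.
They do not validate the model against real soil: real retention differs
between structures (the generator's per-structure offsets default to
zero), real elongation noise is heteroscedastic and bounded, two seedlings
per column introduce sub-replicate correlation the generator omits, and
the generated resistance envelope (roughly 0.1–10 MPa) extends beyond the
0.5–4 MPa window where the reference surfaces were calibrated —
predictions outside that window, and under full saturation or severe
drying, are extrapolations.

## Problem sizes

The test suite and the analysis scripts run the design at its native size
(200 samples per replicate). Recovery uses 20 replicates with 20
multi-start surface fits each, which completes in a few seconds; grids for
structure contrasts default to 36 × 41 nodes over $Q_p \in [0.5, 4]$ MPa,
$S \in [50, 90]$ %.

## Known limitations

* The surface is fitted to early-seedling (87 h) primary-root elongation;
  nothing here addresses longer-term root-system development.
* Parameters are structure-specific by construction; extrapolating a
  fitted surface to a different structural condition defeats the purpose
  of the parameterisation.
* The depth profile of resistance is not modelled — one $Q_p$ per sample.
* The normalisation that defines "relative" elongation is a user choice
  (`normalize_elongation()` offers group-maximum and fixed-reference
  modes); fitted amplitudes are only comparable across datasets that used
  the same convention.
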