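---
title: "Models and methods in ricephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ricephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricephys)
```

`ricephys` implements the computational chain behind multi-year rice
cultivar trials: leaf-level response-curve fitting, closed-chamber canopy
flux estimation, grain-filling kinetics, SPAD calibration, and the
comparison statistics that populate trait tables. This vignette records the
models, the defaults and the numerical and design choices, so that users
know exactly what is computed and what the validation does and does not
show.

## Leaf light response

The light-response model is the non-rectangular hyperbola

$$P_n(I) = \frac{\alpha I + P_{nmax} -
  \sqrt{(\alpha I + P_{nmax})^2 - 4\theta\alpha I P_{nmax}}}{2\theta} - R_d,$$

the minus branch of the quadratic in $P_n + R_d$. Its four parameters are
the apparent quantum yield $\alpha$ (mol CO$_2$ mol$^{-1}$ photons, the
initial slope), the light-saturated rate $P_{nmax}$
(µmol m$^{-2}$ s$^{-1}$), the convexity $\theta \in [0, 1]$ and dark
respiration $R_d$ (µmol m$^{-2}$ s$^{-1}$). Two limits deserve care:

* $\theta \to 0$ gives the rectangular hyperbola
  $\alpha I P_{nmax}/(\alpha I + P_{nmax}) - R_d$. The division by
  $2\theta$ is singular there, so `nrh_pn()` switches to this closed form
  analytically rather than relying on floating-point cancellation. The
  model is often loosely *called* a rectangular hyperbola even when the
  convexity form is the one written down; implementing the printed
  four-parameter form with the analytic $\theta = 0$ limit covers both
  readings.
* $\theta = 1$ collapses to the Blackman response
  $\min(\alpha I, P_{nmax}) - R_d$, because the discriminant becomes
  $(\alpha I - P_{nmax})^2$. Rounding can push the discriminant a hair
  below zero near this line; it is clamped to zero with a warning instead
  of producing `NaN`.

## A/Ci curves

Net photosynthesis against intercellular CO$_2$ follows the
Farquhar–von Caemmerer–Berry structure
$P_n = \min(W_c, W_j) - R_d$ with

$$W_c = V_{cmax}\frac{C_i}{C_i + K_c(1 + O/K_o)}, \qquad
  W_j = \frac{J_{max} \, C_i}{4 C_i + 8\Gamma^*}.$$

Defaults: $K_c = 404$ µmol mol$^{-1}$, $K_o = 278$ mbar, $O = 210$ mbar,
$\Gamma^* = 45$ µmol mol$^{-1}$. Two deliberate choices:

* **Units.** $K_c$ is sometimes quoted in pressure units alongside $C_i$
  in ppm, which is dimensionally inconsistent. Here $K_c$ and $\Gamma^*$
  are mole fractions (µmol mol$^{-1}$, ≡ ppm at ambient pressure) while
  $K_o$ and $O$ are O$_2$ partial pressures in mbar, so $O/K_o$ is
  dimensionless and $C_i + K_c(1 + O/K_o)$ is well-formed. This is the
  interpretation under which this particular constant set is standard.
* **Numerator form.** The rates above use plain $C_i$ numerators. The
  textbook FvCB rates carry $(C_i - \Gamma^*)$ numerators instead; both
  are available (`canonical = TRUE`), but the plain form is the default
  and the two are never mixed. The limitation crossover
  $$C_i^* = \frac{J_{max} K' - 8\Gamma^* V_{cmax}}{4 V_{cmax} - J_{max}},
    \qquad K' = K_c(1 + O/K_o),$$
  is identical under both forms because the extra factor cancels in
  $W_c = W_j$; with capacities around $V_{cmax} \approx 106$,
  $J_{max} \approx 192$ it falls near $C_i^* \approx 422$ µmol mol$^{-1}$,
  between the 350 and 425 ppm steps of the standard CO$_2$ ladder.

`fit_aci()` labels each observation `Wc` or `Wj` at the fitted optimum and
flags the unconstrained capacity as unidentifiable when all points fall on
one side of the crossover (e.g. a curve truncated at low CO$_2$ never
constrains $J_{max}$). Dark respiration can be co-estimated
(`rd = "fit"`, the default) or fixed at a separately measured value
(`rd = 1.5`); fixing is preferable when a night-time measurement exists,
since $R_d$ trades off against both capacities on noisy curves.

## Richards grain filling

Grain dry weight after anthesis follows
$W(t) = A\,(1 + B e^{-kt})^{-1/N}$: asymptotic weight $A$ (mg grain$^{-1}$),
onset parameter $B$ (larger $B$ delays filling — the signature of inferior
grains), rate constant $k$ (day$^{-1}$) and shape $N$ ($N = 1$ is the
logistic). "Modified Richards" appears in the agronomy literature without a
fixed formula; this four-parameter Richards (1959) form is adopted and
documented, and all validation is parameter *recovery* (fit of synthetic
data back to generating truth), never reproduction of any particular
published fit. The filling rate `richards_rate()` is the analytic
derivative, non-negative and unimodal.

## Closed-chamber canopy flux

A multi-chamber system closes each chamber briefly (default 45 s) and logs
headspace CO$_2$ at 1 Hz, leaving it open (default 495 s) while the other
chambers are measured; with 10 chambers the cycle period is 540 s. The
estimator chain is:

1. `segment_closures()` enumerates complete closure windows; a closure
   whose 45 s are fully logged counts even when the following open period
   is truncated.
2. `estimate_slope()` fits an OLS line to CO$_2$ vs time within the
   window. The first `trim_head = 5` s are discarded: headspace air is not
   yet well mixed immediately after lid closure, a standard closed-chamber
   precaution; the trim is configurable down to 0. A linear model over a
   45 s closure is appropriate — drawdown saturation and leak corrections
   matter only for much longer closures and are deliberately not modelled.
3. `slope_to_flux()` converts by the ideal gas law,
   $F = -s\,n_{air}/A_{ground}$ with $n_{air} = PV/(RT)$. Temperature
   defaults to 303.15 K (typical midday paddy canopy) and pressure to
   101325 Pa when unlogged; absolute fluxes scale directly with this
   conversion, so both are explicit, documented parameters of
   `chamber_spec()`. Sign convention: falling CO$_2$ during closure means
   net uptake, reported positive.

Per-closure `slope_se` and `r_squared` are carried through so users can
filter disturbed closures; no automatic quality gate is applied.

## SPAD calibration

`fit_spad_calibration()` is an ordinary least-squares line from SPAD meter
readings to extracted chlorophyll (mg g$^{-1}$ FW), fitted per cultivar —
leaf optical properties differ between cultivars, so pooling is not the
default. Predictions are clamped at zero with a warning (a negative
chlorophyll content is a sign of extrapolating far below the calibration
range).

## Trait statistics

* **Percent difference** is always
  $100\,(\bar{x}_{test} - \bar{x}_{ref})/\bar{x}_{ref}$, with the
  *reference* cultivar in the denominator; display rounding is
  half-away-from-zero at 2 decimals (`round_half_up()`), matching how such
  tables are printed. Comparison tables occasionally mix denominator
  conventions between cells; this package fixes one convention and leaves
  reconciling any table that mixed them to the reader.
* **t-tests** default to the pooled two-sided variant, with Welch
  available. When replicate variance is zero the test is reported as
  unavailable rather than erroring.
* **Two-way ANOVA** (`anova_two_way()`) requires a complete, balanced
  cultivar × year design, under which sequential and classical sums of
  squares coincide and the partition
  $SS_{total} = SS_A + SS_B + SS_{AB} + SS_E$ is exact. A single-level
  factor degrades to the one-way layout with explicit zero-df rows. An
  all-constant table yields zero SS everywhere and `NaN` F ratios —
  reported as degenerate, not an error. Unbalanced data are rejected: the
  intended designs are balanced by construction, and silently switching to
  Type-II/III sums of squares would change the estimand.
* **LSD letters** (`lsd_groups()`) use
  $LSD = t_{1-\alpha/2, df_E}\sqrt{2\,MS_E/n}$; means are sorted
  descending and every maximal run whose extremes differ by less than the
  LSD shares a letter, assigned in order. This is the classical greedy
  assignment; it can produce overlapping groups (`"ab"`), which is the
  intended reading.

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline consumes, with the
statistical structure the estimators assume:

* measurement ladders as used in the field protocols (14 PPFD levels
  2000 → 0; 13 CO$_2$ levels, 425 → 50 then 500 → 1800);
* additive, independent Gaussian noise with user-set σ. The default used
  throughout validation is σ = 0.5 µmol m$^{-2}$ s$^{-1}$ for leaf $P_n$
  (the scale of replicate SDs in published gas-exchange tables) and
  σ = 0.2 µmol mol$^{-1}$ for the CO$_2$ analyser;
* chamber logs whose within-closure slope is the exact inverse of the
  flux conversion, with instantaneous re-equilibration to ambient CO$_2$
  when the lid opens (the estimator never reads open periods, so mixing
  dynamics are irrelevant);
* trial tables built additively from base mean + cultivar effect (test
  cultivar only) + year effect + interaction + replicate noise, balanced
  by construction;
* CO$_2$ setpoints are used directly as $C_i$ in synthetic A/Ci curves.
  In a real leaf $C_i$ is below ambient; for synthesis the distinction is
  irrelevant because the generator and fitter share one driver variable.

Consequently, passing round-trip and calibration tests demonstrates that
the estimators are correct and unbiased *under the assumed error model*.
They do not demonstrate robustness to what real gas-exchange data can
contain: heteroscedastic or autocorrelated noise, stomatal patchiness,
leaks, temperature drift within a measurement, or model misspecification
(e.g. TPU limitation at high CO$_2$, which is out of scope along with
temperature response of the kinetic constants and mesophyll conductance).

## Numerical choices

All nonlinear fits minimise the residual sum of squares with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`), restarted from a fixed lattice
of starting points: 3 levels per free parameter at 15%, 50% and 85% of the
bound box, log-spaced for the Richards $B$ whose bounds span four decades.
The best final SSE wins; ties go to the earlier lattice point. There is no
randomness anywhere in a fit, so identical input gives bit-identical
results. Convergence uses `ftol = 1e-10` on the relative SSE change with
at most 500 iterations per start.

Bounds: light response $P_{nmax} \in (0, 100]$, $\alpha \in (0, 0.15]$,
$\theta \in [0, 1]$, $R_d \in [0, 10]$; A/Ci $V_{cmax} \in (0, 500]$,
$J_{max} \in (0, 1000]$; Richards $A \in (0, 2\max W]$, $B \in (0, 10^4]$,
$k \in (0, 2]$, $N \in (0, 10]$. A parameter landing on a bound is flagged,
not treated as failure. Standard errors come from the Gauss–Newton
approximation $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum, reported as
`NA` when that matrix is singular (as it is for unidentifiable fits).

Degenerate inputs are contracts, not crashes: a constant-$P_n$ curve
returns a non-converged fit flagged unidentifiable; a monotone-decreasing
"growth" trajectory converges to a flagged boundary; a constant CO$_2$
window returns slope 0 and flux 0.

## Validation problem sizes

The shipped tests and the acceptance script validate at the study's own
designs: 13/14-point curves, 200 Monte-Carlo replicates for fitter bias,
500 noisy closures for flux unbiasedness, 100 random balanced tables for
the ANOVA partition identity and 1000 simulations for type-I control —
sizes chosen to make the Monte-Carlo standard errors comfortably smaller
than the tolerances being checked.

## Known limitations

* Single-curve fits only; no hierarchical pooling across replicate curves
  and no weighted least squares.
* Kinetic constants are fixed, not temperature-corrected; fits at leaf
  temperatures far from the calibration conditions inherit that bias.
* The flux conversion assumes the logged (or default) $T$ and $P$; errors
  there propagate proportionally into absolute fluxes.
* LSD controls the comparison-wise, not family-wise, error rate — the
  standard caveat for LSD letter displays.
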