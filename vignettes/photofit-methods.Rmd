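---
title: "Models, estimators and numerical choices in photofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and numerical choices in photofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofit)
```

photofit estimates the parameters of leaf-level biophysical models from
gas-exchange, fluorescence and hydraulic measurements, and simulates C3
photosynthesis forward from those parameters. This vignette is the
package's own account of the science it implements: the model equations
and their assumptions, the tunable settings and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical decisions that make the fits reproducible.

## Standardized data

Every function consumes a tidy table in one canonical vocabulary: `A_net`
(net CO2 assimilation, μmol m⁻² s⁻¹), `Q` (PPFD, μmol m⁻² s⁻¹), `C_i`
(μmol mol⁻¹), `g_sw` (mol m⁻² s⁻¹), `T_leaf` (always Kelvin), `RH`
(fraction), `D` (kPa), `phi_PSII`, `J_F`, `psi` (MPa, ≤ 0 internally),
`PLC` (%), `mass` (g), `RWC` (%). Instrument exports are translated by
varname maps (`varnames("licor6400")`, `varnames("licor6800")`, shipped as
editable CSV config under `inst/extdata/` and transcribed from the
instrument manuals — the dialects are a documentation decision, not
physiology), and `enforce_units()` converts declared units (°C → K by
+273.15, mmol → μmol, % → fraction, kPa/MPa/bar) with dimension checking.
Temperatures below 263 K or above 333 K trigger a warning because they
almost always mean Celsius slipped through. Rows with missing required
drivers are dropped with a message; they are never silently imputed.

## The fitting engine

All nonlinear fits use Levenberg–Marquardt least squares (`minpack.lm`)
restarted over a grid of starting values, keeping the lowest-SSR converged
fit. Photosynthetic response surfaces are rich in flat directions and
local minima, so a single start is not trustworthy; the default grids put
3–5 log-spaced values per parameter (span ×3–×4) around moment-based
initial guesses obtained from linearizations of each model (for example,
the Arrhenius, Heskel, Kruse and MMRT models are linear in log space, so
ordinary regression supplies a near-exact center). Grids are capped at 500
starts, start order can be shuffled reproducibly, convergence tolerance is
1e-8 on the relative SSR change with at most 1000 iterations per start.

Two numerical details matter for robustness:

* **Parameter scaling.** Activation energies (~5×10⁴ J mol⁻¹), deactivation
  energies (~2×10⁵), the Kruse curvature term (~10⁹) and heat capacities of
  activation (~10³) differ by orders of magnitude; finite-difference
  Jacobian columns for the large parameters underflow relative to the rank
  tolerance. Temperature-response fits therefore run on an internal O(1–10)
  scale and estimates and standard errors are rescaled afterwards.
* **Starts at zero.** A parameter whose initial guess is numerically zero
  gets a zero-width finite-difference step; such starts are snapped to a
  small nonzero value on the internal scale.

Every fit returns a `photofit_fit`: a coefficient table (estimate, SE),
SSR/AIC/BIC, observation-level fitted values and residuals, and a plot
builder (`autoplot()`). When any standard error exceeds its estimate, the
fit is flagged and a warning explains that the estimate is unreliable —
large SEs are the canonical symptom of an unidentifiable parameter in
these models.

## CO2 response (FvCB)

`A = min(A_c, A_j, A_p) − R_d` with
`A_c = V_cmax (C − Γ*)/(C + K_c(1 + O/K_o))`,
`A_j = J (C − Γ*)/(4C + 8Γ*)` and `A_p = 3 V_TPU`. The fit estimates
`V_cmax`, `J`, `R_d` and optionally `V_TPU` directly on the minimum rule
(no smoothing): the minimum of smooth branches is continuous and piecewise
smooth, and the multi-start loop protects against the kinks. The estimate
reported as `J_max` is the electron transport rate at the measurement
irradiance; at saturating light it approximates the true maximum, which is
the convention most fitting tools follow. TPU limitation is fitted only
when requested or when the three highest-CO2 points flatten below
0.01 μmol m⁻² s⁻¹ per μmol mol⁻¹ — fitting an extra plateau parameter to a
curve that never reaches it is pure variance.

Kinetic constants default to the *Nicotiana tabacum* set of Bernacchi et
al. (2001, 2002) — Γ*₂₅ = 42.75, K_c₂₅ = 404.9 μmol mol⁻¹, K_o₂₅ = 278.4
mmol mol⁻¹ with their activation energies — Arrhenius-scaled to the curve's
mean leaf temperature (per-point adjustment would couple the residuals to
the temperature record of the instrument; the mean is the documented
default). With a finite assumed mesophyll conductance the CO2 axis is
first converted to the chloroplast (`C_c = C_i − A/g_mc`).

Identifiability is probed directly after fitting: if inflating the fitted
`J_max` (or `V_cmax`) by 50 % leaves the SSR unchanged, the data never
visit that limitation and the parameter is flagged unidentifiable. This is
more reliable than counting labelled points, because an unconstrained
parameter often settles exactly on the branch boundary.

## Light response

The non-rectangular hyperbola
`A = [φQ + A_sat − sqrt((φQ + A_sat)² − 4θφQ A_sat)]/(2θ) − R_d`, with the
rectangular limit used at θ = 0 and the discriminant clamped at zero so
the double root (θ = 1, φQ = A_sat) evaluates exactly. It is monotone and
concave in Q for θ ∈ (0, 1]; designs without sub-saturating light leave φ
undetermined, which surfaces through the large-SE flag rather than a hard
error because the saturated parameters are still meaningful.

## Temperature responses

Seven models are available (`t_response_models()`): Arrhenius
(`k = k_ref exp(E_a(T − T_ref)/(T_ref R T))`), the peaked Medlyn form
(Arrhenius kernel times a deactivation factor, normalized so
`k(T_ref) = k_ref` exactly), a `T_opt` re-parameterization of the peaked
model, the Heskel log-polynomial (`ln k = a + bt + ct²`, t in °C), a plain
quadratic, the Kruse modified Arrhenius
(`ln(k/k_ref) = E_a,ref x + (dEa/2) x²`, `x = (1/T_ref − 1/T)/R`), and
macromolecular rate theory. The MMRT form is anchored so `k(T_ref) =
k_ref`; anchoring absorbs the activation entropy into `k_ref`, leaving
(`k_ref`, `ΔH‡`, `ΔCp‡`) as the free parameters — the unanchored entropy
is not identifiable from rate data alone. The peaked models carry a mirror
solution with negative energies that reproduces the same curve; fits are
bounded to the physical branch (positive `E_a`, `H_d`, `T_opt` within
200–420 K). For the Medlyn form the optimum temperature has the closed
form `T_opt = H_d / (dS − R ln(E_a/(H_d − E_a)))`, exposed as
`t_opt_peaked()` and used as a cross-check in the tests.

## Light respiration and mesophyll conductance

The Kok method regresses `A` on `Q` inside a sub-inhibition window
(default 40–100 μmol m⁻² s⁻¹ — the method names no window, so it is an
explicit, configurable setting); the Yin method replaces the regressor
with `Q·Φ_PSII/4`; both report `R_light = −intercept`. The Walker–Ort
method fits one low-C_i line per irradiance and regresses intercepts on
slopes: the common intersection yields both `C_i*` and `R_light`. With
only two irradiance levels the intersection is solvable but has no
standard errors (one line through two points); the result is flagged.
Parallel lines are a hard error.

The variable-J method computes, per observation,
`C_c = Γ*(J_F + 8(A + R_l))/(J_F − 4(A + R_l))` and `g_mc = A/(C_i − C_c)`
with the sensitivity ratio `δC_c/δA = 12 Γ* J_F/(J_F − 4(A + R_l))²`.
Records with the ratio between 10 and 50 are reliable, and the bounds are
inclusive — "between 10 and 50" is read as the closed interval, and the
choice is documented here because a boundary record moves the summary.
The summary `g_mc` is the mean over reliable records (the median is a
defensible alternative; the mean is implemented and stated). `J_F` comes
from a measured electron-transport column when present, otherwise from
`calib · Q · Φ_PSII` with a user-supplied calibration — no default
absorptance is invented because it varies by leaf and instrument.
Singular records (`J_F ≤ 4(A + R_l)`) and non-physical ones
(`C_i ≤ C_c`) are excluded with per-record reasons, never silently.

## Stomatal conductance

Ball–Berry (`g0 + g1 A RH/C_s`, RH as a fraction), Leuning
(`g0 + g1 A /((C_s − Γ)(1 + D/D0))`, with Γ and D0 fixed rather than
estimated — freeing them alongside g1 on typical designs is a textbook
identifiability failure), and Medlyn in its explicit approximate form
(`g0 + 1.6(1 + g1/√D) A/C_s`), matching common package practice rather
than the implicit optimal-stomata root. All three collapse to `g0` at
zero assimilation, which the tests use as an analytic anchor.

## Hydraulics

Vulnerability curves are fitted with both the sigmoid
`PLC = 100/(1 + exp(a(ψ − b)))` (so `PLC(b) = 50` exactly) and the Weibull
`PLC = 100(1 − exp(−(−ψ/b_w)^c_w))`. Derived points use the tangent-line
convention: air entry `P_e = b + 2/a`, hydraulic failure
`P_max = b − 2/a`. Internally water potential is ≤ 0 MPa; inputs supplied
as positive tensions are auto-negated with a notice, resolving the sign
ambiguity once.

Pressure–volume curves transform to `1/|ψ|` against `100 − RWC` and locate
the post-turgor-loss linear (osmotic) region by growing the point set from
the driest end, keeping the largest set whose regression holds R² ≥ 0.995
(configurable; if no ≥ 4-point region reaches the threshold the best
region is used with a warning, so a degenerate threshold degrades
gracefully). The intercept gives `π_o = −1/b₀`; turgor is `ψ − π(RWC)`,
and the turgor-loss point comes from extending the pre-TLP turgor line to
zero — turgor is nearly linear in water content near the loss point, and
line intersection avoids the one-sample-spacing bias of interpolating the
sampled turgor directly. Capacitance at full turgor is the pre-TLP slope
of RWC fraction against ψ (MPa⁻¹) and the elastic modulus the slope of
turgor against RWC fraction (MPa). Fully hydrated points with ψ = 0 cannot
enter the reciprocal transform and are dropped with a message.

## Forward simulation

`solve_cc()` balances FvCB demand against diffusive supply
`g_tc(C_air − C_c)` by bracketed root-finding on (10⁻⁶, C_air + 500)
followed by a secant polish until the residual is below 10⁻¹²
μmol m⁻² s⁻¹ — bracketing guarantees the root, polishing guarantees the
supply–demand invariant the tests assert (< 10⁻¹⁰). Electron transport
comes from the non-rectangular hyperbola in Q; all rates and kinetics are
Arrhenius-scaled to `T_leaf`. Leaf temperature is a required input; an
energy-balance solver can be plugged in through `t_leaf_fn`, keeping the
package self-contained while leaving the coupling point open.
`simulate_photosynthesis()` runs Cartesian parameter grids and records any
failed solve as a failed row with its message.

Default parameters (`make_parameters()`) describe a healthy sun leaf:
V_cmax25 = 100, J_max25 = 180, V_TPU25 = 12, R_d25 = 1.5 μmol m⁻² s⁻¹,
φ_J = 0.425 (electron basis), θ_J = 0.85, g_mc = 0.5 and g_tc = 0.2
mol m⁻² s⁻¹, 420 μmol mol⁻¹ CO2, 1500 μmol m⁻² s⁻¹ PPFD, 25 °C, 210
mmol mol⁻¹ O2. Unknown override keys fail with a nearest-name suggestion.

## Sensitivity analysis

`analyze_sensitivity()` re-runs any fitting function over a one- or
two-factor grid of assumed inputs (for example Γ*₂₅ and g_mc in A–Ci
fitting) and `compute_sensitivity()` adds two reference-normalized local
measures: the parameter effect `PE = (m − m_ref)/m_ref` and the control
coefficient `CE = PE / ((p − p_ref)/p_ref)`, a finite-difference
elasticity. The literature uses these names without a single canonical
formula; the relative finite-difference forms are adopted as the package's
documented definitions — they make the identity map have CE ≡ 1 and tend
to the analytic elasticity as the step shrinks, which the tests verify.
The reference row has PE = 0 and an undefined CE (marked NA).

## The synthetic-data generator

`generate_synthetic_curve()` computes noiseless responses from the same
`eval_*` functions the fitters use, adds seeded additive Gaussian noise,
and optionally renames columns into an instrument dialect; the generating
parameters ride along as an attribute. Default designs mirror realistic
measurement protocols: light responses at 0–1500 μmol m⁻² s⁻¹ with the
classic step sequence, CO2 responses at 12 levels spanning 50–1500
μmol mol⁻¹ (optionally one curve per leaf temperature over 17.5–40 °C),
temperature responses every 2.5 °C, pressure–volume curves on a declining
RWC ramp, vulnerability curves over 0.5–4.5 MPa tension. Default noise
levels are instrument-realistic choices: 0.3 μmol m⁻² s⁻¹ for A–Q, 0.5 for
A–Ci, 0.05 for the respiration regressions (IRGA precision at low flux),
0.01 mol m⁻² s⁻¹ for g_sw, 2 % PLC, and 0.005 MPa (pressure-chamber
resolution) where the tests need noisy PV data.

The generator emulates additive, homoscedastic Gaussian error only. Real
gas exchange also carries systematic error (leaks, cuvette gradients,
match drift), heteroscedasticity, and operator choices about stability —
none of which it reproduces. Passing recovery tests therefore demonstrates
that the estimators are correct and calibrated under the stated error
model, not that field data meet that model.

## Problem sizes and runtime choices

The test suite's Monte-Carlo calibration uses 200 replicates per fitting
family at the default designs (9–13 observations per curve), enough to
resolve coverage to about ±1.5 %; the brute-force oracle grids use 8–20
points per parameter, which suffices to bound the multi-start optimum on
these smooth, low-dimensional surfaces. The Walker–Ort calibration uses
seven irradiance levels: its second-stage regression has `levels − 2`
degrees of freedom, and with fewer than five levels the reported
normal-theory standard errors are too heavy-tailed for 3-SE intervals to
reach nominal coverage — a property of the method, documented here rather
than hidden.

## Known limitations

C3 biochemistry only; no C4/CAM pathways. A–Ci fitting is on the C_i (or
fixed-g_mc C_c) basis — no variable-mesophyll fitting of A–Ci curves. No
energy-balance solver ships; leaf temperature is an input. No Bayesian
estimation or model averaging. The Medlyn stomatal model is the explicit
approximation. Instrument files are read as delimited text; binary or
multi-sheet exports must be converted first.
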