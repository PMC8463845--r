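---
title: "Methods: oxygen-limited metabolic scaling in stochastic spheroid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxygen-limited metabolic scaling in stochastic spheroid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spheroscale` simulates populations of cell-laden spheroids whose radii and
single-cell oxygen consumption rates (sOCR) fluctuate, computes each
spheroid's metabolic rate from the steady-state oxygen balance, and asks how
the allometric exponent relating metabolic rate \(B\) to mass \(m\) behaves
when it is estimated from whole distributions rather than from mean values.
This vignette documents the model, the numerics, the estimators, the default
parameters and their provenance, and the known limitations.

## The model

**Populations.** A study design consists of \(K = 17\) size distributions
whose mean radii \(\langle R\rangle\) form a geometric ladder from 31 to
5000 μm. Within a distribution, radii are log-normal with mean
\(\langle R\rangle\) and variance \(q_2 \langle R\rangle^2\)
(so the radius CV is \(\sqrt{q_2}\); the default \(q_2 = 0.01\) gives 10%).
Log-normality of sizes is the standard empirical finding for cells and cell
aggregates, and it makes the family *self-similar*: \(R/\langle R\rangle\)
has the same law at every rung, so the mass marginals collapse exactly with
mass exponent \(\gamma = 1\). Masses follow as
\(m = \omega \tfrac{4}{3}\pi R^3\) with homogeneous density \(\omega\)
(water, 1000 kg m⁻³). The conditioning mean mass of a rung is defined from
the *specified* mean radius,
\(\langle m\rangle = \omega \tfrac{4}{3}\pi \langle R\rangle^3\), never from
the sample mean. Each spheroid independently draws an sOCR from a Gaussian
with CV `socr_sd_frac` (default 20%); non-positive draws (probability
≈ 3×10⁻⁷ at 20% CV) are redrawn, preserving positivity without visibly
distorting the Gaussian bulk.

**Oxygen balance.** Inside a spheroid of radius \(R\), oxygen obeys the
stationary spherically symmetric reaction–diffusion equation
\[
D \frac{1}{r^2}\frac{d}{dr}\!\left(r^2 \frac{dc}{dr}\right)
  = V_M(c), \qquad
V_M(c) = \mathrm{sOCR}\,\rho_c\,\frac{c}{k_M + c},
\]
with symmetry at the centre and \(c(R) = c_0\) at the surface. A Hill-type
uptake law is available as a switch. The metabolic rate is the total oxygen
consumption; at steady state the surface-flux form
\(B = 4\pi R^2 D\, c'(R)\) and the volume integral \(\int V_M\,dV\) agree by
the divergence theorem, and the implementation verifies this on every
converged profile (within 0.1%) and returns the volume integral, which is
the more accurate on a finite mesh. The nonviable fraction is
\(\Phi = 100\,(r_{\mathrm{crit}}/R)^3\), where
\(c(r_{\mathrm{crit}}) = C_{\mathrm{crit}}\); spheroids with \(\Phi > 10\%\)
are considered physiologically compromised.

In dimensionless variables (\(u = c/c_0\), \(x = r/R\)) the problem depends
only on \(\kappa = k_M/c_0\) and the squared Thiele-type modulus
\(\phi^2 = \mathrm{sOCR}\,\rho_c R^2 / (D c_0)\). Two classical limits
anchor the solver's validation: for \(c_0 \ll k_M\) the effectiveness factor
is \(\eta = (3/\phi_1^2)(\phi_1\coth\phi_1 - 1)\) with
\(\phi_1 = R\sqrt{\mathrm{sOCR}\,\rho_c/(k_M D)}\); for \(c_0 \gg k_M\) the
profile is piecewise parabolic with a closed-form anoxic core. The test
suite checks both to 0.5–1%.

## Numerics

The two-point boundary value problem is discretized with conservative
second-order finite differences on \([0, 1]\); the symmetry condition at the
origin uses the series form of the spherical Laplacian. The nonlinear system
is solved by damped Newton iteration with projection onto \([0, 1]\)
(the physical range of \(u\)), a Jacobi-scaled residual norm (so convergence
does not depend on local cell size), and continuation: \(\phi^2\) is ramped
up in decade steps, and for near-zeroth-order kinetics
(\(\kappa < 0.1\)) \(\kappa\) is additionally ramped down, because the
almost-discontinuous uptake defeats a cold Newton start. For large \(\phi\)
the reaction confines itself to a surface layer of width \(O(1/\phi)\), and
the mesh grades geometrically from a fine surface spacing into the flat
core. Meshes are refined by doubling until the metabolic-rate integral
changes by less than 0.02% and flux/volume conservation holds to 0.05%;
the mesh-halving sensitivity of \(B\) is below 0.05% by construction.

Since the solution depends only on \((\kappa, \phi^2)\), population solves
use a precomputed table of \(\eta\) and the critical core fraction against
\(\phi^2\) (24 points per decade, monotone cubic interpolation in
\(\log\phi^2\)), which makes \(10^6\)-spheroid batches cheap. The table is
audited against direct solves; the audit tolerance is 0.5% and measured
deviations are ~3×10⁻⁶ for \(\eta\).

## Collapse estimators

Under the finite-size scaling ansatz with normalization exponents fixed at
1, the marginal density obeys
\(p(B \mid \langle m\rangle) = B^{-1} F(B/\langle m\rangle^\delta)\) and the
joint density obeys
\(p(m, B \mid \langle m\rangle) = m^{-1} B^{-1}
G(m/\langle m\rangle^{\gamma},\, B/\langle m\rangle^{\delta})\).
Each size distribution is histogrammed once, on 30 log-spaced bins
(30×30 cells in 2D) spanning its own range; the curve (surface) of a rung is
the set of points \((\log_{10} B,\ \log_{10} B\,p(B))\), respectively
\((\log_{10} m,\ \log_{10} B,\ \log_{10} m B\,p(m,B))\), over occupied bins.
Rescaling by \(\langle m\rangle^{\delta}\) (and
\(\langle m\rangle^{\gamma}\)) is then a rigid translation in log space.

Binning per distribution — rather than on a pooled grid in rescaled
coordinates — is a deliberate choice: the density estimate of a rung should
not depend on the exponent currently under trial, and rigid translation is
precisely the displacement the functionals minimize over. We verified on
exact-scaling synthetic data that pooled-grid binning gives a noisier
estimator.

Two functionals measure the closeness of the translated curves:

* **distance-based** `f_dis` / `g_joint`: the sum over ordered pairs of
  distributions of the mean squared nearest-neighbour Euclidean distance
  between their point sets, with every axis standardized by the pooled range
  (making the value unit-free);
* **residual-based** `f_res`: for every ordered pair, one curve is linearly
  interpolated at the abscissae of the other over their overlap and the mean
  squared ordinate residual is accumulated.

Histogram-origin *dithering* reduces binning noise: the functional is
averaged over a small number of bin-origin offsets (default 4 for the
marginal case, 1 for the joint case where per-cell counts are larger). The
minimizer is found on a grid (\(\delta \in [0.5, 1.3]\), step 0.005
marginal; a coarse \((\gamma, \delta)\) grid plus Nelder–Mead refinement for
the joint case), and the reported uncertainty is the **1%-variation
interval** \(\{\delta : f(\delta) \le 1.01 f(\hat\delta)\}\) (axis sections
of the 2D sublevel set for the joint case), with a multimodality flag if the
sublevel set is not contiguous. Degenerate, zero-variability inputs are
detected and reduce to the exact log–log power-law fit through the
per-distribution means, with \(\gamma = 1\) exact.

On synthetic data built to satisfy the ansatz exactly (log-normal masses,
\(B = m^{\delta_0}\xi\) with log-normal noise \(\xi\); see
`make_scaling_population()`), the distance estimator recovers \(\delta_0\)
without bias. Its replicate-to-replicate standard deviation at \(N = 200\),
mass CV 30% and noise CV 20% is ≈ 0.02 — about twice the
information-theoretic floor of a log–log regression on the same data, the
price of the fully nonparametric histogram route. This matters when reading
single-run exponents: at \(N = 200\) an individual \(\hat\delta\) carries
sampling noise of that order, while the 1%-variation interval reflects
functional curvature, not sampling error.

**Validation tests.** Whether rescaled distributions share one law is
tested with a k-sample Anderson–Darling test (implemented from the exact
null mean/variance standardization and the published critical-value
surface). Joint collapses are gated by a Henze–Zirkler multivariate
normality test of the log-rescaled coordinates of each member (log
coordinates because the underlying laws are log-normal-like, which makes the
normality gate meaningful) followed, when all members pass at the 1% level,
by a mean-vector equality test implemented as one-way MANOVA (Wilks) on the
two rescaled coordinates — the natural reading of "described by the same
vector of mean values" across three or more distributions; per-coordinate
ANOVAs are available as a switch. Both tests are Monte-Carlo calibrated in
the test suite. The HZ statistic is evaluated on at most 2000 evenly spaced
observations per member: its pairwise-distance matrix is quadratic in the
sample size, and at 2000 observations the gate's power is already far
beyond its discriminating role. Sequential windows are tested without a
multiplicity correction.

## Windows and the pipeline

`find_windows()` starts from the three smallest unassigned rungs, accepts
the triplet if the collapse is unimodal and the validation test passes
(AD \(p > 0.05\) marginal; all HZ \(p \ge 0.01\) and mean-vector
\(p > 0.01\) joint), and extends one rung at a time until acceptance fails;
the window then closes and the search restarts. Windows are labelled
*isometric* when the \(\delta\) interval contains 1, *viable* when every
member's mean \(\Phi\) is below 10% (the per-spheroid rule is printed in the
source physiology, the aggregation is not; the mean is the simplest
population summary and a quantile rule is available), and *relevant* when
nonisometric, viable and validated. Viability is monotone along the ladder
because \(\Phi\) is monotone in \(R\).

`min_n_analysis()` regenerates a window at each ladder size \(N\) with fresh
child seeds and records the functional minima; the plateau is the onset of
the terminal run of minima staying within a two-sided 10% band of the final
value (the band width is exposed in the configuration; the source physiology
states no criterion). `variability_sweep()` reruns the joint pipeline at
several \((q_2, \sigma_{\mathrm{sOCR}})\) combinations with common random
numbers across combos, the zero-variability combo degenerating to the exact
three-point solve. `sensitivity_analysis()` perturbs each kinetic parameter
by ±5% one at a time under identical seeds. Since sOCR, \(\rho_c\), \(D\)
and \(c_0\) enter the solution only through \(\phi^2\) and \(\kappa\),
paired perturbations of sOCR and \(\rho_c\) must shift the exponent
identically — a consistency check the test suite exploits.

## Parameter mapping

The kinetic constants of the two bundled phenotypes live in
`cell_type_params()`. Fixed literature values: \(D = 2\times10^{-9}\)
m² s⁻¹ (oxygen in water), \(c_0 = 0.2\) mol m⁻³ (air-saturated aqueous
medium), \(C_{\mathrm{crit}} = 0.04\) mol m⁻³, \(\rho_c = 10^{14}\)
cells m⁻³, \(\omega = 1000\) kg m⁻³. The remaining constants — the sOCR
means and \(k_M\), which published tables for these cell systems do not pin
down uniquely — were calibrated once, before any stochastic validation, to
two deterministic anchors of the reference physiology: (i) the
zero-variability three-point exponent over stem-cell rungs 8–10 equals
0.98, and (ii) the stem-cell viability boundary (mean \(\Phi = 10\%\)) falls
between rungs 11 and 12. This gives \(k_M = 0.0412\) mol m⁻³ and
\(\mathrm{sOCR}_{\mathrm{stem}} = 5.61\times10^{-17}\) mol s⁻¹ cell⁻¹. The
hepatocyte sOCR, \(2.97\times10^{-17}\) mol s⁻¹ cell⁻¹, is anchored to its
viability boundary between rungs 12 and 13. Both sOCR means sit inside the
10⁻¹⁸–10⁻¹⁶ mol s⁻¹ cell⁻¹ range reported for single cells; \(k_M\) is at
the high end of reported oxygen Michaelis constants, consistent with
whole-aggregate effective kinetics.

## What the generator does and does not emulate

The synthetic populations reproduce log-normal size dispersion with
mean-proportional variance, Gaussian metabolic heterogeneity, and the
random pairing of the two; they do not emulate cell-packing geometry,
growth dynamics, nutrient species other than oxygen, transient behaviour,
or non-spherical aggregates. Passing tests therefore demonstrate the
correctness of the solver and estimators under the stated stochastic model,
not the biological accuracy of any particular parameter set.

## Problem sizes used by the test suite

The default validation runs at desk scale: marginal exponent recovery uses
100 replicates at \(N = 200\); joint recovery 20 replicates at
\(N = 10^4\); test-size calibration 500 null replicates each; window
searches run at \(N = 200\) (marginal) and \(N = 1000\) (joint); minimum-N
ladders stop at \(10^4\) (marginal) and \(3\times10^4\) (joint). Every
stochastic quantity derives from one master seed through deterministic
child seeds, so all results are exactly reproducible.

## Known limitations

* **Magnitude of the fluctuation-induced exponent shift.** With the
  calibrated parameters, switching variability on moves the joint exponent
  of rungs 8–10 from 0.980 to ≈ 0.96 — the direction matches the reference
  physiology, but the size of the shift there (down to ≈ 0.85) is not
  reproduced. We probed per-distribution vs pooled binning, point-to-point
  vs point-to-segment distances and count weighting; none produces a shift
  of that magnitude. The shift evidently depends on normalization details
  of the original functionals and/or kinetic constants that are not
  printed, so window positions and window exponents reported by this
  package under its default calibration differ from the reference values.
* **Gate power at large N.** At \(N = 10^4\) the HZ and mean-vector gates
  detect the slight log-scale curvature that the oxygen model imprints
  within any window, so joint windows rarely validate at that sample size
  under the default kinetics; the gates behave exactly as specified, and
  their thresholds are configurable.
* **Estimator efficiency.** The histogram-based collapse estimator has
  about twice the sampling standard deviation of the parametric information
  floor at \(N = 200\) (see above), so single-run exponents at small N
  should be read with that uncertainty in mind.
* The Anderson–Darling p-value uses the standard interpolated
  critical-value surface, adequate between roughly 0.001 and 0.5; extreme
  p-values are extrapolations.
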