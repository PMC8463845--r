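# spheroscale

Metabolic allometric scaling of cell-laden spheroids in the presence of
correlated fluctuations in mass and metabolism.

## The problem

How the metabolic rate *B* of a biological system scales with its mass *m* —
isometrically (*B ∝ m*) or allometrically (*B ∝ m^δ*, δ ≠ 1, with
Kleiber's 3/4 as the famous benchmark) — is usually asked with mean values.
Real populations of 3D cell aggregates (spheroids, organoids) fluctuate in
both size and single-cell metabolism, and the exponent one estimates can
depend on those fluctuations. `spheroscale` is an in silico pipeline for
designing physiologically relevant 3D cell-culture experiments with this in
mind. It is aimed at tissue engineers and quantitative biologists who want
to know, before running an experiment: in which size range do spheroids of a
given cell type scale nonisometrically while remaining viable, and how many
samples are needed to estimate the exponents from distributions?

The pipeline:

1. **Generate** stochastic spheroid populations: 17 size distributions with
   log-normal radii (mean radii 31–5000 μm, radius CV `sqrt(q2)`, default
   10%) and Gaussian single-cell oxygen consumption rates (sOCR, default
   CV 20%), randomly paired. Masses are `m = ω (4/3) π R³`.
2. **Solve** the stationary oxygen balance in each spheroid,
   `D (1/r²) d/dr(r² dc/dr) = sOCR ρ_c c / (k_M + c)` with `c(R) = c0`,
   giving the metabolic rate `B = ∫ V_M dV` (equal to the surface inward
   flux `4πR² D dc/dr|_R` by conservation) and the nonviable volume fraction
   `Φ = 100 (r_crit/R)³` where `c(r_crit) = C_crit`.
3. **Collapse** the distributions: under the finite-size scaling ansatz
   `p(B|⟨m⟩) = B⁻¹ F(B/⟨m⟩^δ)` (marginal) and
   `p(m,B|⟨m⟩) = m⁻¹B⁻¹ G(m/⟨m⟩^γ, B/⟨m⟩^δ)` (joint), the rescaled log-log
   curves/surfaces of different size distributions superimpose at the true
   exponents; δ (and γ) are estimated by minimizing a residual-based
   (Bhattacharjee–Seno) or nearest-neighbour distance functional, with
   1%-variation intervals and k-sample Anderson–Darling / Henze–Zirkler /
   MANOVA validation.
4. **Classify** size windows (≥3 consecutive distributions that collapse
   together) as isometric/nonisometric, viable/nonviable (mean Φ < 10%), and
   *physiologically relevant* (nonisometric + viable + validated), and run
   the meta-experiments: minimum-N plateau analysis, variability sweeps,
   kinetic-parameter sensitivity.

See the methods vignette (`vignettes/spheroscale-methods.Rmd`) for the
model, numerics, parameter calibration, and known limitations.

## Worked example

```r
library(spheroscale)

params <- cell_type_params("stem")
pops <- build_populations(size_ladder()[9:11], params,
                          n_samples = 200, seed = 1, indices = 9:11)
sols <- solve_populations(pops, params)
fit <- collapse_marginal(sols, method = "distance")
fit
#> Marginal collapse (distance method), distributions 9, 10, 11
#>   delta = 0.9314  (1%-variation interval [0.9154, 0.9522])
#>   f_min = 0.03397, Anderson-Darling p = 0.5012
coef(fit)     # delta = 0.931
confint(fit)  # the 1%-variation interval
```

Here three adjacent stem-cell size distributions (mean radii ≈ 394, 541,
743 μm, 200 spheroids each) collapse onto one curve with scaling exponent
δ ≈ 0.93: metabolic rate grows sublinearly with mass in this size range
because oxygen penetration starts to limit the core. The Anderson–Darling
p-value (0.50) accepts that the three rescaled distributions share one law;
the interval is the 1%-variation range of the collapse functional, a
curvature summary rather than a confidence interval (replicate noise at
N = 200 is about ±0.02).

The full pipeline with window classification:

```r
report <- run_pipeline(default_config("stem", n_samples = 200, seed = 1),
                       mode = "marginal")
report$windows_marginal
#> Size windows (marginal mode): 2 window(s)
#>   1-11: delta = 0.997 [0.990, 1.003], AD p = 0.166 | isometric, viable
#>   12-17: delta = 0.737 [0.729, 0.745], AD p = 0.089 | nonisometric, nonviable
```

Under the package's default (literature-calibrated) kinetics, stem-cell
spheroids below ~750 μm mean radius scale isometrically and viably, and
larger ones scale like δ ≈ 0.74 but with oxygen-starved cores — the
physiologically interesting transition sits at the boundary, and sharpening
it is exactly what the variability sweep and joint analysis are for. A thin
command-line front end is installed at `inst/scripts/spheroscale`
(subcommands `run`, `generate`, `solve`, `collapse-marginal`,
`collapse-joint`, `windows`, `min-n`, `sweep`, `sensitivity`).

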