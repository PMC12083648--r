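# deerstate

Global analysis of DEER/PELDOR dipolar evolution traces for proteins
studied under multiple biochemical conditions, plus the companion
MD-trajectory contact statistics. Written for spectroscopists and
structural biologists who record four-pulse DEER on spin-labeled pairs
(apo / substrate / nucleotide / inhibitor series and the like) and want
per-condition conformational-state populations with honest uncertainties.

## The model

A phase-corrected, zero-time-aligned trace is modelled as

    V(t) = V0 · B(t) · [1 − Δ(1 − F(t))],     B(t) = exp(−k t^(d/3)),

with the form factor F(t) the powder-averaged dipolar transform of a
sum-of-Gaussians distance distribution

    P(r) = Σᵢ aᵢ N(r; r0ᵢ, σᵢ),    ν(r) = 52.04 MHz · (r/nm)⁻³.

The *global* fit shares component centers and widths across all conditions
of one spin-labeled pair, gives each condition its own population simplex
(aᵢ ≥ 0, Σaᵢ = 1, enforced exactly), and each trace its own modulation
depth, background rate and scale. The number of components is selected by
AICc (BIC reported alongside), and 2σ confidence bands on P(r) are
propagated from the parameter covariance by the delta method. Fitted
components can be mapped to named reference states (Gaussian summaries of
rotamer-library predictions) by overlap coefficient, yielding
per-condition state populations and shifts.

The MD module computes per-frame minimum distances, salt bridges
(4.5 Å cutoff), per-lipid-type contact percentages (4.0 Å cutoff) and
RMSD versus the first frame from multi-model PDB trajectories; a
synthetic-data module generates every input with exact ground truth,
including a pseudo-membrane in the 20:14:35:22:9
cholesterol:POPC:POPE:POPS:SAPI molar ratio.

## Worked example

```r
library(deerstate)

sc  <- make_scenario(demo_scenario(seed = 1))        # 5 conditions, known truth
fit <- deer_global_fit(sc$traces, k = 2, options = fit_options(seed = 1))
fit
#> Global DEER fit, pair 'T193-M298': 2 component(s), 5 condition(s), 5 trace(s)
#>   component 1: r0 = 40.09 +/- 0.19 A, sigma = 3.08 +/- 0.23 A
#>   component 2: r0 = 54.71 +/- 0.24 A, sigma = 3.92 +/- 0.64 A
#> Per-condition amplitudes:
#>   apo          0.294+/-0.029  0.706+/-0.029
#>   Sph          0.497+/-0.027  0.503+/-0.027
#>   MgATP        0.387+/-0.027  0.613+/-0.027
#>   MgATP-Sph    0.677+/-0.024  0.323+/-0.024
#>   PF-543       0.887+/-0.022  0.113+/-0.022
#> chi2_red = 1.002 on 1000 points, 24 free parameters; AICc = 1027.35, BIC = 1143.90
```

The generating truth placed components at 40 and 55 Å with short-distance
populations (0.3, 0.5, 0.4, 0.7, 0.9) — every estimate lands within its
quoted uncertainty, and χ²_red ≈ 1 says the residuals match the recorded
noise level. Mapping the components onto two reference states and
differencing conditions:

```r
refs <- data.frame(name = c("closed", "open"), pair = "T193-M298",
                   r0 = c(40, 55), sigma = c(3, 4), source = "demo")
tab <- population_table(fit, assign_components(fit, refs))
round(population_shift(tab, "apo", "PF-543"), 3)
#>     closed       open unassigned
#>      0.593     -0.593      0.000
```

i.e. the inhibitor-like condition shifts 59 % of the population into the
closed state. `plot(fit)` draws each condition's P(r) with its 2σ band;
`select_components(sc$traces, fit_options())` scans k = 1…4 and prints the
criteria table; `confidence_band()`, `predict()`, `simulate()`,
`residuals()`, `coef()` and `vcov()` behave as for any R model object.

A command-line layer wraps the same functions:

```sh
Rscript inst/scripts/deerstate simulate --seed 3 --out sim/
Rscript inst/scripts/deerstate select --traces sim/ --k-max 4 --seed 3 --out out/
Rscript inst/scripts/deerstate contacts --traj fix.pdb \
    --sel-a "resid 225 and chain P" --sel-b "resid 162 and chain P" --out out/
```

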