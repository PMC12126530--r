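# cpmgbind

Global analysis of protein–ligand binding kinetics from solution NMR.

Weak, transient complexes — such as a J-domain co-chaperone engaging
Hsc70 — are often invisible as distinct species: the bound state is a few
percent of the population and its resonances are broadened away. What
remains measurable on the free-state peaks is millisecond exchange
broadening (¹⁵N CPMG relaxation dispersion) and small exchange-induced
shifts (δ_ex). `cpmgbind` fits both observables jointly to the two-state
scheme

    JDP + Hsc  ⇌  JDP·Hsc        (k_on, k_off;  K_d = k_off/k_on)

with explicit ligand material balance: the bound fraction at totals J and H
is the physical root of

    p_B = { J + H + K_d − sqrt((J + H + K_d)² − 4JH) } / 2J,

the pseudo-first-order on-rate is k_on·[Hsc]_free, and
k_ex = k_on_app + k_off. Dispersion profiles are computed by exact
propagation of the 2×2 complex Bloch–McConnell evolution matrix through the
constant-time echo train (R₂,eff = −ln(|M_A(T)|/M_A(0))/T, with
R₂ᴮ = 5·R₂ᴬ by default), and δ_ex as the frequency of the slowly decaying
eigenmode. Global parameters (k_on, k_off) are optimised on a log scale by
Levenberg–Marquardt with a multi-start grid; per-residue Δω (ppm, shared
across fields) and R₂ᴬ (per field) are nuisance parameters.

The package also covers the surrounding calculators of a titration-by-NMR
study: R₂,eff extraction with duplicate-based errors, R₁/R₁ρ/hetNOE
relaxometry, chemical-shift-perturbation significance by iterative
corrected standard deviations, open-state populations from fast-exchange
peak positions, WEX hydrogen-exchange buildups and protection factors,
alignment-tensor fitting of RDCs by SVD (with the Clore–Garrett R-factor),
fluorescence-polarisation isotherms, and seeded synthetic-data generators
for every observable.

## Worked example

Simulate a three-field CPMG + δ_ex titration at the DNAJB6 JD-GF-like
study conditions (truth: k_off = 580 s⁻¹, K_d = 380 µM, 200 µM protein,
ligand at molar ratio 0.1, 2% intensity noise) and refit it:

```r
library(cpmgbind)

g    <- gen_cpmg_titration(cpmg_generator_spec(seed = 1))
prob <- fit_problem(g$cpmg, g$condition, dex = g$dex)
fit  <- fit_global(prob)
fit
#> Global two-state binding fit
#>   k_on  = 1.495e+06 +/- 8.4e+03 M^-1 s^-1
#>   k_off = 550.2 +/- 7.3 s^-1
#>   K_d   = 368.1 +/- 5.4 uM
#>   [d1] p_bound = 0.03441, k_ex = 569.8 s^-1
#>   chi2 = 2471 (523 dof)
```

`k_off` and `K_d` land within a few percent of the generating truth at this
noise level (the spread across seeds is ~4%); `k_ex` is derived from the
fitted constants through the material balance at the sample composition, so
it is exactly consistent with the reported rates. Convergence is assessed
by a grid search that re-optimises the per-residue parameters at each node:

```r
grid <- convergence_grid(prob, fit, span = 0.2, steps = 3)
round(attr(grid, "chi2_matrix"), 1)
#>           347.1  550.2     872
#> 943100  13019.1 9790.5 13613.9
#> 1495000  3772.1 2470.6  4312.0
#> 2369000  6086.3 7792.9  6797.4
```

The χ² minimum sits at the central (reported) node. The same machinery
answers consistency questions directly; for instance, the k_off implied by
K_d = 380 µM and k_ex = 600 s⁻¹ at this composition:

```r
cond <- titration_condition(uM_to_M(200), uM_to_M(20))
koff_from_kex(cond, kd = uM_to_M(380), kex = 600)
#> [1] 579.7727
```

## Documentation

The methods vignette (`vignettes/binding-kinetics.Rmd`) describes the
model, its assumptions, the numerical choices (propagator conventions,
closed-form validity domains, error estimators, identifiability probes)
and the limitations of the synthetic benchmarks. Function-level
documentation is in the roxygen comments in `R/`.
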