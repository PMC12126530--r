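---
title: "Two-state binding kinetics from CPMG dispersion and exchange-induced shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state binding kinetics from CPMG dispersion and exchange-induced shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgbind)
```

## The problem

A J-domain co-chaperone construct (the NMR-visible species, "JDP") binds an
Hsp70-family chaperone ("Hsc") reversibly:

$$\mathrm{JDP} + \mathrm{Hsc}
  \underset{k_\mathrm{off}}{\overset{k_\mathrm{on}}{\rightleftharpoons}}
  \mathrm{JDP{\cdot}Hsc}, \qquad K_d = k_\mathrm{off}/k_\mathrm{on}.$$

When the complex is large and the bound population small, the bound state is
invisible directly but leaves two measurable fingerprints on the free-state
resonances: millisecond exchange broadening, quantified by ¹⁵N CPMG
relaxation dispersion, and small displacements of the observed peaks
(exchange-induced shifts, $\delta_{ex}$). `cpmgbind` fits both observables
jointly to this two-state scheme and returns the rate constants, the
affinity, and per-residue structural parameters.

## The model

### Material balance

Because the reactant concentrations are comparable to the $K_d$, free ligand
is depleted by binding. The bound fraction of the visible species at total
concentrations $J$ and $H$ is the physical root of the mass-action
quadratic,

$$p_B = \frac{J + H + K_d - \sqrt{(J + H + K_d)^2 - 4JH}}{2J},$$

evaluated internally in the rationalised form $p_B = 2H/(J+H+K_d+\sqrt{\cdot})$
to avoid cancellation at small $p_B$; the $J \to 0$ limit is taken
analytically. The pseudo-first-order on-rate is
$k_\mathrm{on}^\mathrm{app} = k_\mathrm{on} [\mathrm{Hsc}]_\mathrm{free}$
with $[\mathrm{Hsc}]_\mathrm{free} = H - p_B J$, and
$k_\mathrm{ex} = k_\mathrm{on}^\mathrm{app} + k_\mathrm{off}$. Every fit
result reports $k_\mathrm{ex}$ by evaluating this chain at the fitted
constants, so the kinetic summary is exactly consistent with the reported
$(k_\mathrm{on}, k_\mathrm{off})$. Concentrations are molar internally;
micromolar appears only at user boundaries (`uM_to_M()`).

### Exchange forward model

The in-phase ¹⁵N coherences of the two states evolve under

$$L = \begin{pmatrix} -R_2^A - k_\mathrm{on}^\mathrm{app} & k_\mathrm{off} \\
 k_\mathrm{on}^\mathrm{app} & -R_2^B - k_\mathrm{off} + i\Delta\omega
\end{pmatrix},$$

with the rotating frame set at the apo resonance. A constant-time CPMG
element of length $T$ is propagated exactly: one echo unit is
$\tau$–180°–$\tau$ with $\tau = 1/(4\nu_\mathrm{CPMG})$, a refocusing pulse
is complex conjugation of the magnetisation, and two consecutive units form
the linear map $P = \overline{W}W$ with $W = \overline{U}U$,
$U = e^{L\tau}$, applied $T\nu_\mathrm{CPMG}$ times via the closed-form
eigendecomposition of the 2×2 complex matrices (degeneracy tolerance 1e-9,
handled by the defective-matrix limit). The effective rate is extracted the
way it is measured:
$R_{2,\mathrm{eff}} = -\ln(|M_A(T)|/M_A(0))/T$, starting from the
equilibrium populations $(1-p_B, p_B)$ and referenced to the experiment
without the relaxation period. The bound-state rate is tied to the apo rate,
$R_2^B = s\,R_2^A$ with $s = 5$ by default, reflecting the
molecular-weight ratio of complex to free protein; $\Delta\omega$ is shared
across fields in ppm, while $R_2^A$ is free per residue and field.

The exchange-induced shift is the precession frequency of the slowly
decaying eigenmode of $L$: the imaginary part of the eigenvalue with the
largest real part, converted to ppm with
$|\gamma_N/\gamma_H| = 0.101329118$. The sign convention (positive
$\Delta\omega$ = downfield bound state) is global; only relative signs are
identifiable from these data.

### Closed forms and their domain of validity

`carver_richards_r2eff()` implements the standard two-site closed form. It
is numerically identical to the decay rate of the *dominant eigenmode* of
the echo propagator. The finite-$T$, amplitude-based rate defined above
additionally contains mode-mixing amplitude terms of order
$p_B(\Delta\omega/k_\mathrm{ex})^2/T$; the two routes therefore agree to
better than 0.1 s⁻¹ only for skewed populations away from coalescence
(roughly $p_B \lesssim 0.0125\,(k_\mathrm{ex}/\Delta\omega)^2$) and diverge
by tens of s⁻¹ near $k_\mathrm{ex} \approx \Delta\omega$ with
$p_B \to 0.5$, where no single-mode description exists. This is a property
of the physics, not an implementation artefact: the propagator is verified
against brute-force ODE integration of the Bloch–McConnell equations (with
explicit conjugation events) to ~1e-7 s⁻¹ including the coalescence corner.
The closed form is consequently used only for cross-checks and previews,
never in fitting.

Similarly, the eigenmode definition of $\delta_{ex}$ is validated against a
dense FID simulation (Fourier transform of $\sum e^{Lt}$, parabolic peak
interpolation): agreement is within 0.5% across
$k_\mathrm{ex}/\Delta\omega \in [1, 20]$, $p_B \in [0.01, 0.1]$ — the
dilute-bound regime in which an exchange-induced shift is the relevant
observable. At larger $p_B$ the merged, asymmetric line places its maximum
measurably away from the eigenmode frequency (a real lineshape effect), so
the comparison is not meaningful there.

## The global fit

The target function is

$$\chi^2 = \sum_\mathrm{CPMG}
  \left(\frac{R_{2,\mathrm{eff}}^\mathrm{obs} -
  R_{2,\mathrm{eff}}^\mathrm{calc}}{\sigma}\right)^2 +
  \sum_{\delta_{ex}} \left(\frac{\delta_{ex}^\mathrm{obs} -
  \delta_{ex}^\mathrm{calc}}{\sigma_\delta}\right)^2,$$

minimised by Levenberg–Marquardt (minpack.lm) over
$(\log_{10} k_\mathrm{on}, \log_{10} k_\mathrm{off})$ — log scale because
the rates span decades — and the per-residue nuisances, with a
block-structured finite-difference Jacobian exploiting the fact that each
residue's parameters touch only its own residuals. Bounds:
$k_\mathrm{on} \le 10^{10}\,\mathrm{M^{-1}s^{-1}}$ (diffusion limit),
$k_\mathrm{off} \in [10^{-2}, 10^6]\,\mathrm{s^{-1}}$. Initialisation is a
5×5 multi-start grid over the rate constants with nuisances re-optimised at
each node (fast-limit heuristics provide their starting values), unless the
caller supplies `init`. The procedure is deterministic given the data.

Whether the shift and dispersion terms should carry different relative
weights is not derivable from the data themselves; shifts without a stated
uncertainty receive a floor of 0.002 ppm (`dex_sigma_floor`), which is a
typical ¹⁵N peak-position reproducibility, and the flag `use_delta_ex`
turns the second sum off entirely (the package fits CPMG-only problems the
same way).

Identifiability is probed rather than assumed: after convergence the
nuisances are re-optimised half a decade away from the optimum in each rate
constant, and a surface that fails to rise (e.g. all
$\Delta\omega \approx 0$: flat dispersions carry no exchange information)
flags the result `non_identifiable`. `convergence_grid()` exposes the same
profile-$\chi^2$ machinery as the user-facing grid search around the
optimum.

Measurement uncertainties follow the acquisition design:
$R_{2,\mathrm{eff}} = -\ln(I/I_0)/T$, with the pooled duplicate-difference
estimator $\sigma = \sqrt{\sum d^2/2m}$ from the CPMG field strengths
measured twice, applied to all points of that curve. With only two
duplicate pairs this estimator is strongly heavy-tailed (the inverse of a
2-d.o.f. variance estimate has no finite mean), so reduced $\chi^2$ values
well above 1 are expected even for a correct model; parameter point
estimates are unaffected, which is why the recovery checks below are stated
on parameters rather than on $\chi^2$.

## Ancillary calculators

* **Relaxometry** — single-exponential fits (rate errors from the fit
  covariance), $R_2 = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta$ with
  $\theta$ from the 1.5 kHz spin lock and per-residue offsets, and hetNOE
  ratios with first-order error propagation.
* **CSP analysis** — $\Delta\delta_\mathrm{comb} =
  \sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}$ and the iterative
  corrected-standard-deviation cutoff: values more than 3 SD above the mean
  of the surviving set are trimmed until stable; the final SD is taken
  about zero (CSPs are magnitudes) and doubled for significance. The two
  conventions in circulation — trimming about the mean versus about zero,
  final SD about zero versus about the mean — are both exposed
  (`trim_about`, `final_about`) because the published descriptions mix
  them; the defaults trim about the mean and report about zero.
* **Open-state populations** — in fast exchange the observed peak
  interpolates linearly between the closed and open reference positions;
  per-residue populations are aggregated by inverse variance, using ¹⁵N
  positions (reference separations below ~5× the peak-position uncertainty
  are excluded). `kex_from_rex()` then places the exchange rate via the
  fast-limit identity $R_{ex} = p(1-p)\Delta\omega^2/k_\mathrm{ex}$; the
  caller must establish the fast regime independently.
* **Hydrogen exchange** — WEX buildups follow the two-pool transfer
  solution $I(T) = A k_\mathrm{obs}(e^{-R_{1w}T} -
  e^{-(R_{1a}+k_\mathrm{obs})T})/(R_{1a}+k_\mathrm{obs}-R_{1w})$ (with the
  analytic limit at rate degeneracy). The shape determines only
  $A\,k_\mathrm{obs}$ and $R_{1a}+k_\mathrm{obs}$, so the amplitude is
  pinned to the reference intensity; otherwise $k_\mathrm{obs}$ would be
  undetermined. $R_{1w}$ is a single shared water pool. Protection factors
  are $\log_{10}(1.5\,k_\mathrm{int}/k_\mathrm{obs})$, with the 1.5 factor
  keeping fully exposed amides non-negative; intrinsic rates are supplied
  as an input table (sequence-based reference calculations are out of
  scope).
* **RDCs** — couplings are linear in the five Saupe components; the tensor
  is the SVD least-squares solution, with $D_\mathrm{max} =
  -\mu_0 h \gamma_i\gamma_j/(16\pi^3 r^3)$ from coordinate-derived
  internuclear distances (an effective N–H length of 1.041 Å is available
  as an override; the two-bond coupling uses the C′(i−1)–Hᴺ(i) vector).
  Plain least squares by default, 1/σ weighting optional. The
  Clore–Garrett quality factor is
  $R = 100\sqrt{\langle(D_\mathrm{obs}-D_\mathrm{calc})^2\rangle /
  2\langle D_\mathrm{obs}^2\rangle}$; the denominator can be replaced by a
  supplied expected mean square for the powder-average variant. Designs
  with near-collinear vectors are rejected with the condition number.
* **Fluorescence polarisation** — $P = (I_\parallel - I_\perp)/
  (I_\parallel + I_\perp)$ and the unit-slope isotherm
  $y = b + (t-b)/(1 + K_d/x)$, whose inflection satisfies
  $y(K_d) = (b+t)/2$; the Hill exponent is fixed at 1 (a free slope exists
  behind `free_slope` for diagnostics only). Competition-mode inflections
  are reported raw, without conversion to $K_i$.

## Synthetic data: what it emulates, and what it does not

The generators (`gen_cpmg_titration()` and friends) define the study
conditions used throughout the tests: $k_\mathrm{off} = 580$ s⁻¹,
$K_d = 380$ µM, 200 µM visible protein with ligand at molar ratio 0.1
(hence $p_B \approx 0.034$, $k_\mathrm{ex} \approx 600$ s⁻¹), spectrometers
at 600/800/950 MHz, a 40 ms constant-time element with 12 CPMG field
strengths from 25–1000 Hz snapped to the even-echo constraint, the first
two field strengths duplicated, 2% fractional Gaussian noise applied at the
intensity level (so the duplicate-based error estimator is exercised by the
measurement route), and 0.002 ppm noise on $\delta_{ex}$. Per-residue shift
differences are uniform on 0.5–3.5 ppm and apo rates uniform on 8–16 s⁻¹ —
representative of amide ¹⁵N in a small folded domain. Every generator is
seeded and emits a manifest sufficient to regenerate its output
bit-exactly.

What passing recovery tests on these data demonstrate: the estimator is
consistent and approximately unbiased under the stated noise model at the
stated information content. What they do not demonstrate: robustness to
peak overlap, baseline and phasing errors, off-resonance pulse
imperfections, temperature drift between titration points, or deviations
from two-state behaviour — none of which the generator emulates. Real-data
fits should lean on the convergence grid and on the flatness flag rather
than on the synthetic benchmarks.

## Problem sizes and numerical choices

The test suite runs the full recovery study at the study conditions (15
residues × 3 fields × 12 field strengths + shifts, 20 random seeds), which
completes in a few minutes on a single core; the oracle-equivalence grids
use 500 regime points each. Quadratic discriminants within 1e-12 of zero
are clamped; eigen-degeneracies are resolved by the defective-matrix limit;
$\nu_\mathrm{CPMG}$ values are snapped to the constant-time delay the way
acquisition software snaps them, and unsnapped values are rejected with the
nearest valid alternatives listed.

## Known limitations

Two-state exchange only (no three-site or cooperative schemes); in-phase
¹⁵N coherences only (no anti-phase/MQ or ¹H CPMG, no off-resonance R₁ρ
model); one global `ExchangeParams` per fit problem (constructs are fitted
independently); RDC fitting is single-structure (no ensembles or
shape-based alignment prediction); intrinsic hydrogen-exchange rates are
inputs, not computed. The published R-factors for the deposited
experimental RDC set are not reproduced here — that requires the deposited
data and structure model — and the package's RDC claims are correspondingly
property-based (exact recovery on synthetic data).
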