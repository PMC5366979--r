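---
title: "Models and methods in dielax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dielax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielax)
```

## The dielectric model

A permittivity spectrum is modelled as a superposition of Debye relaxation
processes above a high-frequency limit:

$$\varepsilon^*(\omega) = \varepsilon_\infty +
  \sum_{k} \frac{\Delta\varepsilon_k}{1 + i\omega\tau_k}
  \;-\; i\,\frac{\sigma_{dc}}{\omega\varepsilon_0},
  \qquad \omega = 2\pi f .$$

For aqueous amino-acid solutions three processes describe the data across
the microwave-to-THz range: a slow **L** process from rotational diffusion
of the solute, a fast **H** process from bulk water, and a small
intermediate **M** process. Labels are assigned purely by descending
relaxation time. The optional conduction term models ionic dc conductivity,
which contaminates only the loss channel at the low-frequency end; no
electrode-polarization model is included because the analysis band starts
high enough (0.5 GHz) for electrode effects to be negligible.

Each Debye term is Kramers–Kronig consistent in closed form: its loss peaks
exactly at $f = 1/(2\pi\tau)$ with height $\Delta\varepsilon/2$, its real
part is monotonically non-increasing in frequency, and the zero-frequency
limit of the model is the static permittivity
$\varepsilon_s = \varepsilon_\infty + \sum_k \Delta\varepsilon_k$. These
closed forms are the oracles of the test suite.

A symmetric Cole–Cole broadening $\Delta\varepsilon/(1+(i\omega\tau)^{1-\alpha})$
is available per process (`debye_process(..., alpha = )`) for exploring
whether a small intermediate process can be absorbed into a broadened slow
process; the fitting routine itself fits pure Debye terms only, which is
the model the main analysis asserts.

Sign convention: files and objects store the loss $\varepsilon''$ as a
positive magnitude, and $\varepsilon^* = \varepsilon' - i\varepsilon''$ is
formed internally. Frequencies are in Hz at all interfaces. Physical
constants are CODATA values ($k_B$ = 1.380649e-23 J/K,
$\varepsilon_0$ = 8.85418781e-12 F/m, $N_A$ = 6.02214076e23 /mol).

## Fitting

`fit_relaxation()` minimises the joint residual over both channels with
Levenberg–Marquardt (`minpack.lm::nls.lm`):

* **Weighting.** Default `"relative"`: each residual is divided by the
  channel's data magnitude floored at 1. The two channels differ by up to
  two orders of magnitude across the band while the measurement accuracy is
  a uniform relative figure, so relative weighting matches the error model.
  `"uniform"` is available for homoscedastic data.
* **Parameterization.** $\log\Delta\varepsilon$, $\log\tau$,
  $\log(\varepsilon_\infty - 1)$ and $\log\sigma_{dc}$ are the free
  parameters: positivity is structural, never achieved by clipping, and the
  problem is conditioned across decades. During optimisation the model is
  built without constructor validation and exponents are clamped at
  $\pm 500$ so extreme trial steps stay finite; the returned model is a
  validated object.
* **Bounds.** Relaxation times are box-constrained (on the log scale) to
  the reciprocal data band padded by three decades either side, or to
  user-supplied per-process intervals.
* **Multi-start.** Five starts by default: the deterministic initial guess
  (relaxation times log-spaced across the reciprocal band, the observed
  $\varepsilon'$ span split equally among the strengths,
  $\varepsilon_\infty$ from the highest-frequency $\varepsilon'$) plus
  seeded log-normal perturbations (sd 0.5). The best deviance wins. The
  perturbation RNG is used locally and restored, so fits do not disturb the
  session RNG stream.
* **Standard errors** come from the local curvature of the weighted
  least-squares problem, transported to the natural scale by the delta
  method. They are curvature-based approximations, not profile intervals.
* **Convergence** is flagged from the optimizer's return code;
  a non-converged fit is returned with `converged = FALSE`, never silently.

**dc conductivity.** With `conductivity = "auto"` the spectrum is first fit
without a conduction term; if the measured loss at the lowest frequency
exceeds the fitted relaxation-only loss there by more than 5%, a second fit
co-estimating $\sigma_{dc}$ (seeded as if half the lowest-frequency loss
were conduction) is run and kept only if it wins the penalised criterion
below. The 5% threshold is deliberately permissive: a relaxation-only fit
partially absorbs a conduction tail, so the residual excess understates the
contamination, and a false trigger only costs a trial fit.

**Model comparison.** `compare_models()` ranks candidate configurations by
a Gaussian AIC on the weighted residuals,
$2N\log(\mathrm{SSR}/2N) + 2p$ ($N$ data points, $p$ parameters), a
deterministic penalised-residual criterion. Two caveats the tests make
explicit: a small intermediate process that changes the spectrum by less
than the noise floor is *correctly* ranked away (parsimony), so the
three-versus-two self-consistency check runs on noiseless data, where the
extra process changes the band-limited spectrum by about 0.1% RMS; and
non-converged fits are excluded from the ranking rather than compared.

## Hydrodynamic prediction

The rotational relaxation time of a prolate ellipsoid (semi-axes
$a \ge b$, $\rho = b/a$) with dipole along the long axis:

$$\tau_{rot} = \frac{8\pi\eta a^3}{3 k_B T}\,
  \frac{1-\rho^4}{(2-\rho^2)\,S/\sqrt{1-\rho^2} - 1},\qquad
  S = \ln\frac{1+\sqrt{1-\rho^2}}{\rho},$$

which reduces to the Debye sphere value $4\pi\eta a^3/(k_B T)$ as
$\rho \to 1$; within $|1-\rho| < 10^{-9}$ the sphere formula is dispatched
directly to avoid the 0/0 limit. Inputs are semi-axes (a 3.67 Å long
*semi*-axis for glycine), accepted in Å at the interface and converted to
SI internally. The measured dielectric time then follows from the
macroscopic-field correction
$\tau_{DR} = 3\varepsilon_s/(2\varepsilon_s+\varepsilon_\infty)\cdot\tau_{rot}$,
whose factor lies in $[1, 1.5)$; for the slow solute process the
high-frequency permittivity is that process's own high-frequency limit, not
the overall $\varepsilon_\infty$. No hydration shell is added to the
geometry — the bare-molecule calculation is the stated model, and its known
consequence is that strongly hydrated solutes (serine, arginine) are
predicted somewhat fast.

The defaults $T$ = 293 K and $\eta$ = 1.002 mPa s are pure water at the
measurement temperature. Whether 293 or 293.15 K is used shifts the
predictions by well under a picosecond; predictions are kept at full double
precision and rounded to the nearest picosecond only in reports.

`local_viscosity_ratio()` divides an observed solute relaxation time by the
pure-water prediction. Because the SED law is linear in viscosity, this
ratio is an estimate of local viscosity in solvent units: values near 1 for
amino acids inside a collagen network — whose macroscopic viscosity is
orders of magnitude above water — are the quantitative signature of
hierarchical (local vs macroscopic) viscosity.

## Mixture estimators

Four deliberately simple, exactly linear/power-law estimators for rod
macromolecule solutions (defaults describe atelocollagen: 1.5 nm × 300 nm,
300 kg/mol, 3 × 1000 residues; solution density 1 g/cm³, the dilute-aqueous
assumption):

* volume fraction per wt%: $0.01\rho_{sol}/M\cdot N_A \pi r^2 L$ (0.0106;
  reported as 0.01 at one significant figure);
* dielectric decrement: wt% × (φ per wt%) × $\varepsilon_{water}$, ideal
  volume-exclusion mixing with $\varepsilon_{water}$(293 K) = 80.2
  (the aggregate `mixture_estimates()` chains the one-significant-figure
  volume fraction here, the precision at which the estimate is quoted:
  4 × 0.01 × 80.2 = 3.2);
* bound-water mole fraction: bound waters per residue × residues ×
  rod moles / water moles per kg of solution. The per-residue count is an
  input; 2 waters per residue is the documented default and gives 1.5% at
  4 wt% — an upper-end inference, as structural reports put the count at
  one to a few;
* rods per cube: number density × cube volume (2168 at 4 wt% in a 300-nm
  cube; ~2000 at one significant figure).

Exact values are always returned; `report = TRUE` (or the `reported`
fields) rounds to the rhetorical one-significant-figure precision so
reproduction of quoted numbers is separated from reusable computation.

## Synthetic data

`simulate_spectrum()` evaluates the forward model on a log-spaced grid and
multiplies each channel pointwise by independent $1 + N(0, \sigma_{rel})$
factors, truncated so the loss stays non-negative. The default
$\sigma_{rel}$ = 3% is the net relative accuracy of averaged TDR waveform
measurements; noise is i.i.d. across frequencies and channels because the
stated accuracy is a single relative figure with no correlation structure.
Seeding uses R's Mersenne–Twister locally (the algorithm name is recorded
in the `noise_spec` object);
the same seed reproduces a spectrum bit for bit.

Band presets cover the two instruments: TDR 0.5–25 GHz, THz-TDS
0.3–2.5 THz, at 10 points/decade by default. What the generator does *not*
emulate: TDR timing-jitter error structure, THz optical-path artefacts,
electrode polarization, or temperature drift. Passing recovery tests
therefore demonstrate that the fitting procedure is correct and stable
under the stated noise model — not that every instrumental systematic of
real data is survivable.

Fixture models: `water_293K` (single Debye, $\varepsilon_s$ = 80.2,
$\tau$ = 9.4 ps, $\varepsilon_\infty$ = 5.3 — literature-style constants);
`glycine_solution` (three processes; the L process carries the reported
fitted values $\tau_L$ = 72 ps, $\Delta\varepsilon_L$ = 28.7, static
permittivity 120; M and H are plausible invented stand-ins, the M process
being small and unpublished); `collagen_glycine_solution` (identical L
process — encoding the collagen-independence of the solute dynamics — with
a slightly smaller water strength). No conclusion in the test suite depends
on the invented M/H values.

## Parameter-recovery benchmark sizes

The recovery properties are exercised at sizes chosen to finish in seconds
while still being informative: noiseless round-trips on the 18-point TDR
grid recover all parameters to better than 0.1%; the noisy benchmark runs
20 seeds at 3% noise on the joint two-instrument grid at 20 points/decade
(110 points), where the median recovered $\tau_L$ lands within a few
percent of truth. The joint band matters: with only the 18-point single
band at 3% noise the three-process decomposition is weakly identified and
an occasional fit parks a spurious slow process at the $\tau$ bound; the
THz segment pins $\varepsilon_\infty$ and the water process, the way the
combined measurement does in practice. Medians (not means) summarise the
seeds because rare bound-hitting outliers are part of honest nonlinear
fitting; the collagen-vs-plain comparison uses a rank-based test
(Wilcoxon) for the same reason.

## Known limitations

* Pure Debye terms only in the fitter; no Havriliak–Negami or stretched
  exponentials, and no temperature dependence of parameters.
* Oblate ellipsoids and perpendicular-dipole rotation are out of scope;
  axes must come from external structure estimates.
* The dc term models conduction loss only; strongly conducting samples
  with electrode polarization need pre-processing the package does not do.
* Standard errors are local-curvature approximations and can understate
  uncertainty near weakly identified decompositions.
* The mixture estimators are order-of-magnitude tools by design; they
  assume ideal mixing, a fixed solution density of 1 g/cm³ and rigid-rod
  geometry.
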