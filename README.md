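# dielax

Dielectric relaxation analysis of aqueous biomolecular solutions:
multi-Debye spectral decomposition, Perrin-ellipsoid hydrodynamic
predictions, and order-of-magnitude estimators for rod-macromolecule
(collagen-like) solutions.

## The problem

Broadband dielectric spectroscopy of an aqueous solution measures the
complex permittivity ε\*(ω) = ε′(ω) − iε′′(ω) from hundreds of MHz to the
THz range. For solutions of small zwitterionic solutes (amino acids) the
spectrum decomposes into a sum of Debye relaxation processes,

ε\*(ω) = ε∞ + Δε_L/(1 + iωτ_L) + Δε_M/(1 + iωτ_M) + Δε_H/(1 + iωτ_H),

where the H process is bulk water (~9 ps), the L process is rotational
diffusion of the solute (tens to hundreds of ps), and M is a small
intermediate process. The L-process time probes the *local* viscosity felt
by a rotating molecule: by the Stokes–Einstein–Debye (SED) law it is linear
in the viscosity of the medium. Comparing a fitted τ_L with the value
predicted for the bare molecular geometry in pure water tells you whether a
solute inside a macroscopically viscous network (e.g. a few wt% of rod-like
collagen, which can raise bulk viscosity 100-fold) still rotates in
water-like surroundings.

The prediction chain for a prolate solute with semi-axes a ≥ b
(ρ = b/a) and dipole along the long axis is Perrin's extension of SED,

τ_rot = (8πηa³ / 3k_BT) · (1 − ρ⁴) / [ (2 − ρ²)·S/√(1−ρ²) − 1 ],
S = ln( (1 + √(1−ρ²)) / ρ ),

followed by the macroscopic-field (internal-field) correction

τ_DR = 3ε_s / (2ε_s + ε∞) · τ_rot,

where ε_s is the solution's static permittivity and ε∞ is the
high-frequency limit of the process under study.

The package provides:

- `fit_relaxation()` — Levenberg–Marquardt decomposition of a spectrum into
  1–4 Debye processes (optional dc-conductivity loss term), returning a
  classed fit object with `print`, `summary`, `coef`, `predict`,
  `residuals`, `plot` and `simulate` methods;
- `perrin_tau_rot()`, `macroscopic_correction()`, `predict_tau_a()`,
  `local_viscosity_ratio()` — the hydrodynamic prediction chain;
- `volume_fraction_per_wt()`, `dielectric_decrement()`,
  `bound_water_mole_fraction()`, `rods_in_cube()` — composition estimators
  for rod-macromolecule solutions;
- `simulate_spectrum()`, `fixture_model()`, `band_preset()` — a seeded
  synthetic-spectrum generator for the TDR (0.5–25 GHz) and THz-TDS
  (0.3–2.5 THz) bands with multiplicative measurement noise;
- `run_study()` — the full pipeline: fit spectra, predict τ from geometry,
  tabulate the comparison, append the mixture estimates.

## Worked example

Predict the dielectric relaxation time of glycine in water at 293 K and
compare it with a fitted synthetic spectrum:

```r
library(dielax)

geom <- ellipsoid_geometry(3.67, 2.11)          # semi-axes in Angstrom
ctx  <- correction_context(120, 91.3)           # eps_s, L-process hf limit
tau_a <- predict_tau_a(geom, solvent_conditions(), ctx)
round(tau_a * 1e12)
#> [1] 74

sp  <- simulate_spectrum(fixture_model("glycine_solution"),
                         band_preset("tdr"), noise_spec(0))
fit <- fit_relaxation(sp, n_processes = 3)
fit
#> Multi-Debye relaxation fit (3 processes), converged
#> Relaxation model: eps_inf = 5.3, 3 process(es)
#>   L  delta_eps =     28.7  tau =       72 ps
#>   M  delta_eps =        4  tau =       25 ps
#>   H  delta_eps =       82  tau =      9.8 ps
#>   static permittivity eps_s = 120
#>   residual RMS: eps' 1.7e-14, eps'' 1.55e-14  (88 iterations)

local_viscosity_ratio(fit$model$processes[[1]]$tau, tau_a)
#> [1] 0.9784695
```

The fitted slow-process time (72 ps) against the predicted one (74 ps)
gives a local-viscosity ratio ≈ 0.98: the solute rotates as if in pure
water. The mixture estimators quantify why a 4 wt% collagen network leaves
the water phase essentially unperturbed:

```r
est <- mixture_estimates(solution_composition(4))
str(lapply(est, `[[`, "reported"))
#> List of 4
#>  $ volume_fraction_per_wt: num 0.01
#>  $ dielectric_decrement  : num 3.2
#>  $ bound_water_percent   : num 1.5
#>  $ rods_in_cube          : num 2000
```

Each wt% of rods excludes only ~1% of the volume, the dielectric-constant
decrement at 4 wt% is ~3.2, at most ~1.5% of water molecules are surface
bound, and yet a 300-nm cube holds ~2000 rods — a dense network that raises
macroscopic viscosity while leaving nearly all water free.

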