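---
title: "From umbrella-sampling timeseries to a blocker dissociation constant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From umbrella-sampling timeseries to a blocker dissociation constant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfkd)
```

## The problem

A pore blocker — a toxin, a toxin-mimetic polymer, a small molecule — binds a
potassium channel such as Kv1.3 by occluding the selectivity filter. The
standard computational route to its affinity is: sample the blocker–channel
separation `z` along the pore axis in overlapping harmonically biased windows
(umbrella sampling, with the blocker's center of mass confined to a cylinder
of radius `R` so the sampled volume is defined); stitch the biased window
histograms into one unbiased free-energy profile `W(z)` — the potential of
mean force (PMF) — with the weighted histogram analysis method (WHAM); and
integrate the profile into a standard dissociation constant,

$$K_d^{-1} \;=\; 1000\,\pi R^2 N_A \int_{z_\mathrm{min}}^{z_\mathrm{max}}
  e^{-W(z)/kT}\,dz ,$$

with `z_min` at the fully bound state, `z_max` in the bulk, and the `1000
π R²` prefactor converting the cylinder's sampled volume into a molar
reference concentration (SI lengths; internally the package keeps Ångströms
and uses the identical factor `π R² · 10⁻²⁷ L/Å³ · N_A`).

pmfkd implements this pipeline for 1D reaction coordinates, together with the
statistical machinery that makes the estimate defensible: a decorrelation
rule, bootstrap profile uncertainty, and a convergence diagnostic. Because
production umbrella-sampling data come from cluster-scale MD, the package
also contains a Langevin generator with *known* ground-truth potentials, so
every estimator is validated against exact references rather than against
other software.

## Units and conventions

* Energies are carried in kT throughout; the temperature (default 298.15 K)
  matters only when converting kcal/mol inputs at the I/O boundary. All WHAM
  exponents and the Kd integral are naturally dimensionless in kT.
* The bias convention is `E = ½ k (z − z₀)²` with `k` in kT/Å². Metadata
  files must declare their dialect (`half-k`/`full-k`, `kT`/`kcal/mol`);
  full-k springs are doubled on load so the bias energy is preserved. There
  is no guessing: the ½k-versus-k ambiguity is a classic silent error across
  WHAM tools.
* Out-of-domain evaluation of a potential is an error, never a clamp —
  clamping corrupts Boltzmann weights silently.

## The synthetic generator

`simulate_window()` integrates overdamped Langevin dynamics
(Euler–Maruyama), `z ← z − D·dt·∂(U+bias)/∂z + √(2·D·dt)·ξ`, recording every
`s_save` steps. This emulates the statistics of biased MD sampling — a
correlated 1D process whose stationary law is the Boltzmann distribution of
truth + bias — without pretending to be MD: there is no solvent, no
membrane, no 3D geometry, and affinities of real compounds cannot be
produced by it. What passing tests show is that the *estimators* are
correct, not that any particular blocker binds.

Defaults, chosen once as typical of umbrella-sampling practice:

* `D = 1 Å²/ps`, `dt = 0.005 ps`, `s_save = 200` → samples saved every 1 ps,
  mirroring the usual save interval, with window relaxation times of a few
  tenths of a ps so successive saved points are decorrelated to about 1/e or
  better.
* `dt` keeps `D·dt·k` at 0.02–0.05 for the stiffest defaults, well inside
  the hard stability bound `D·dt·k_max < 0.1` that is checked before any
  stepping. Euler–Maruyama carries an O(dt) bias in its stationary
  distribution (a harmonic well's variance is inflated by ≈ `D·dt·k/2`);
  at these settings the bias is a fraction of a percent, below what a
  chi-square test at n = 10⁵ can detect.
* The first 10% of saved samples are flagged equilibration and excluded
  downstream, standing in for the discarded docking/equilibration phase of a
  production run.
* Per-window seeds are `seed + index − 1`: window sets are reproducible yet
  mutually independent streams; identical inputs give bitwise-identical
  samples.
* Forces on tabulated potentials use central finite differences at the grid
  nodes, linearly interpolated — no smoothness assumption beyond the table
  itself. Trajectories reflect at finite domain edges.

The canonical study conditions used by the validation suite and the
acceptance script are `example_binding_potential()` — a smooth binding
profile with an 8 kT Gaussian well at z = 10 Å, a 3 kT shoulder well at
z = 13 Å, and W → 0 in the bulk — sampled by 12 windows on 8–30 Å (spacing
2 Å, `k_s = 4 kT/Å²`, 5×10⁴ production samples per window). These sizes keep
a full pipeline run under half a minute on one core while leaving the
statistical error (≈ 0.1 kT RMSE) far below the 0.3 kT recovery budget.

`simulate_pull()` adds the docking protocol: a flat-bottom restraint whose
upper bound ramps linearly (e.g. 12 Å → 3 Å) and then holds, pulling the
coordinate in without biasing the bound geometry. The restraint stiffness
default (10 kT/Å²) is a configurable placeholder typical of docking
restraints.

## WHAM

`solve_wham()` iterates the two self-consistency equations

$$P_j = \frac{\sum_i n_{ij}}{\sum_i N_i\, e^{(f_i - c_{ij})/kT}},
\qquad e^{-f_i/kT} = \sum_j P_j\, e^{-c_{ij}/kT}$$

directly (no binless estimator), with the gauge `f₁ = 0`, probability
renormalisation each sweep (a pure gauge choice that keeps `exp(f)`
bounded), and `exp(−c)` precomputed — entries that underflow are bins a
window cannot reach and correctly contribute nothing. Iteration stops when
`max|Δf| ≤ tol` (default 10⁻⁷ kT, cap 10⁵ iterations — tight enough that
tolerance error is far below statistical error; non-convergence is an
error, not a warning). The residual typically rises for ~20 sweeps on wide
window sets while information propagates between distant windows, then
decays monotonically; 2-window problems decay monotonically almost from the
start.

Numerical choices:

* Default bin width 0.5 Å (not dictated by anything in the data; narrow
  enough that the trapezoid Kd changes by < 0.5% on halving).
* Half-open bins `[lo, hi)`; a value exactly at the last edge is dropped.
* Empty bins carry `W = +∞` rather than being smoothed — smoothing would
  bias the Kd integral, which simply excludes them (with a warning).
* The PMF zero is set by convention after solving: `bulk` (default;
  subtract W at the largest-z finite bin, so profiles approach zero in
  solution) or `min`.

The test suite checks the solver against an independent brute-force
fixed-point oracle written in plain R (≤ 10⁻⁸ kT on small fixtures), against
Boltzmann inversion in the single-window limit, and for invariance under
window reordering and rigid coordinate shifts.

## Decorrelation, bootstrap, convergence

*Decorrelation.* `autocorrelation()` computes the standard biased ACF and
reports `τ_e`, the smallest lag at which the ACF has fallen to 1/e —
inclusive, so an ACF exactly at 1/e counts (the tie-break matters for
AR(1)-like data sitting on the threshold). If the ACF never crosses within
the estimated range, `τ_e` conservatively equals the maximum lag.

*Bootstrap.* `bootstrap_pmf()` draws `n_boot = 10` pseudo-datasets with
duplication allowed, resampling independently within each window, and
reconstructs a PMF from each; `σ(z)` is the pointwise SD across replicates
(n−1 denominator, appropriate at n = 10) and `σ_max` its maximum over
finite bins — the single-number uncertainty quoted for a profile. The
resampling unit is the *decorrelated* sample (each window strided by its own
`τ_e` first): resampling raw correlated points would understate the
variance. Whether one resamples per-window or pooled, raw or strided, is
genuinely open in most descriptions of this procedure; the per-window,
strided choice here is a documented decision. Calibration is tested by
comparing `σ_max` against the empirical SD of the profile depth across 20
independently seeded regenerations (they agree within a factor of 2 under
the canonical conditions).

*Convergence.* `convergence_depths()` reruns WHAM on the first
25/50/75/100% of each window's production samples and reports the profile
depth — defined as min(W) minus the bulk-bin value, a choice the package
documents rather than inherits — per fraction, plus the drift (max pairwise
difference). Stationary data show drift comparable to the statistical
error; a deliberately injected nonstationarity (a mean ramp in the
bound-side windows) is flagged by drift well beyond it. Note the
fraction-truncated depths are themselves noisier than the full-data
bootstrap σ_max, so drift of a few×σ_max on stationary data is not alarming
by itself; the diagnostic is for *systematic* trends.

## Kd and its uncertainty

`compute_kd()` integrates `exp(−W)` by the trapezoidal rule over the bins in
`[z_min, z_max]` (defaults: the profile's finite extremes) and applies the
cylinder factor. Degenerate ranges follow the documented contract: equal
bounds give a zero integral and `Kd = ∞` (no binding); inverted bounds are
an error. `kd_bounds()` shifts the whole profile by ±σ_max — a uniform
shift factors out of the integral exactly, so the bounds are
`Kd·e^{∓σ_max}` — a deliberately conservative interval matched to a
single-number uncertainty, not a standard error. For a proper statistical
comparison the replicate profiles in a `bootstrap_result` can be integrated
individually (the end-to-end test does exactly this, using 3×SD of ln Kd
across replicates plus the < 0.5% grid term as its combined error).

`fraction_blocked(C, Kd) = C/(C+Kd)` is the single-site block relation that
maps a predicted Kd onto the fraction of current suppressed at a given
blocker concentration — the quantity an electrophysiology IC50 estimates.

## Worked example

```{r pipeline, eval = FALSE}
truth <- example_binding_potential()
cfg <- sim_config(seed = 1, n_steps = ceiling(5e4 / 0.9) * 200)
series <- generate_window_set(truth, 8, 30, 2, 4, cfg)

edges <- seq(6.75, 30.25, by = 0.5)
boot <- bootstrap_pmf(series, edges, n_boot = 10, seed = 2)
boot$sigma_max                       # ~0.09 kT at these sample sizes
res <- compute_kd(boot$pmf, radius = 8)
res                                  # Kd ~1.5 mM for the 8 kT example well
kd_bounds(boot$pmf, boot$sigma_max)
```

The same pipeline is available from a shell (`pmfkd simulate | wham |
bootstrap | converge | kd`; see `?pmfkd_cli`), with a YAML config holding
per-subcommand sections, flags overriding the config, and every run logging
the seed and the parameters actually used.

## Limitations

* 1D, non-periodic coordinates only; no 2D WHAM, no replica exchange, no
  binless (MBAR-style) estimator — the direct histogram method is the point
  of reference here.
* The generator reproduces the *sampling statistics* of umbrella-sampling
  MD, not its physics: no orthogonal slow degrees of freedom, no
  force-field error, no finite-size electrostatics. Passing validation says
  the estimators are unbiased on data that satisfy their assumptions; real
  MD data can violate those assumptions (hidden slow modes lengthen
  correlation times beyond what any 1D ACF shows).
* The uniform ±σ_max Kd interval is conservative by construction; it widens
  with the worst-sampled bin even when that bin barely contributes to the
  integral.
* An 8 kT well gives Kd in the millimolar range; nanomolar blockers
  correspond to ~14 kT and beyond, where umbrella-sampling coverage — not
  the estimators — is the limiting factor.
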