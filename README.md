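# pmfkd

Umbrella-sampling free-energy profiles and channel-blocker affinity in R.

Predicting how tightly a pore blocker (a scorpion-toxin mimetic, a peptide,
a small molecule) binds an ion channel such as Kv1.3 is routinely done by
computing the potential of mean force (PMF) `W(z)` along the pore axis from
umbrella-sampling simulations and integrating it into a standard
dissociation constant. pmfkd implements that pipeline for people who have
per-window reaction-coordinate timeseries (or want to generate synthetic
ones with known ground truth) and need a tested, reproducible route from
those files to a Kd with an honest error bar:

* **WHAM** — self-consistent weighted-histogram reconstruction of `W(z)`
  from biased windows (`build_histograms()`, `solve_wham()`), with a
  compiled inner loop, log-safe weights, `+∞` sentinels for unsampled bins,
  and an explicit bulk/min zero convention (`rezero_pmf()`).
* **Kd from the profile** — for a blocker whose center of mass was confined
  to a cylinder of radius `R` during sampling,

  ```
  Kd⁻¹ = 1000 π R² N_A ∫ exp[−W(z)/kT] dz        (z from bound state to bulk)
  ```

  evaluated by `compute_kd()` (trapezoidal rule; Å-based unit chain proven
  equal to the SI form in the tests), plus `kd_bounds()` and the single-site
  block relation `fraction_blocked(C, Kd) = C/(C+Kd)`.
* **Statistics** — the 1/e autocorrelation decorrelation rule
  (`autocorrelation()`), bootstrap profile uncertainty from 10 resampled
  pseudo-datasets (`bootstrap_pmf()`, reporting pointwise `σ(z)` and
  `σ_max`), and a PMF-depth convergence diagnostic over data fractions
  (`convergence_depths()`).
* **Synthetic data** — an overdamped Langevin simulator
  (`simulate_window()`, `generate_window_set()`, `simulate_pull()`) with
  exact ground-truth potentials, so every estimator is validated against
  closed forms instead of other software.
* **Files and CLI** — Grossfield-style metadata (`path center spring` with
  mandatory energy/bias dialect declarations), two-column timeseries, PMF
  tables, and a `pmfkd` command-line driver
  (`simulate | wham | bootstrap | converge | kd`) with YAML configs.

## Worked example

Twelve umbrella windows (centers 8–30 Å, spacing 2 Å, k = 4 kT/Å², 5×10⁴
production samples each, saved every 1 ps) over a known binding profile with
an 8 kT well, then PMF + bootstrap + Kd:

```r
library(pmfkd)
truth  <- example_binding_potential()
cfg    <- sim_config(seed = 1, n_steps = ceiling(5e4 / 0.9) * 200)
series <- generate_window_set(truth, 8, 30, 2, 4, cfg)

edges <- seq(6.75, 30.25, by = 0.5)
boot  <- bootstrap_pmf(series, edges, n_boot = 10, seed = 2)
boot
#> <bootstrap_result> 10 pseudo-datasets (seed 2); sigma_max = 0.092 kT
boot$pmf
#> <pmf_profile> 47 bins on [7, 30] A (0 unsampled)
#>   depth (min - bulk): -8.031 kT; zero convention: bulk
#>   max pointwise uncertainty: 0.092 kT

compute_kd(boot$pmf, radius = 8)
#> <binding_result>
#>   cylinder radius: 8 A; range: [7, 30] A; T = 298.15 K
#>   integral exp(-W/kT) dz: 5468.12 A
#>   Kd = 0.00151 M (1.51e+03 uM); Ka = Kd^-1 = 662.093 L/mol
```

The reconstructed depth (8.03 kT) matches the 8.13 kT ground truth within
the bootstrap uncertainty, and the Kd of ~1.5 mM is what an 8 kT well in an
8 Å cylinder corresponds to (the truth profile gives 1.48 mM). The
`kd_bounds()` interval from `σ_max = 0.092 kT` is [1.38, 1.66] mM, and
`fraction_blocked(3e-3, kd)` says such a blocker suppresses 66% of the
current at 3 mM. Tight (sub-micromolar) blockers correspond to deeper
profiles (≳ 14 kT); the machinery is identical.

The same run from a shell:

```sh
pmfkd simulate --seed 1 --n-samples 50000 --out-dir windows
pmfkd bootstrap --metadata windows/window_metadata.txt --seed 2 --out pmf.dat
pmfkd kd --pmf pmf.dat --radius 8
```

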