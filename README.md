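# hydropatch

Tools for studying **structural microheterogeneity in liquid water**: the
temperature-dependent organization of the hydrogen-bond network into patches
of four-bonded molecules, and the signatures that organization leaves in
vibrational spectra.

The package is aimed at molecular-simulation and vibrational-spectroscopy
practitioners who want a self-contained, tested pipeline from trajectory (or
measured spectrum) to network and band-shape statistics.

## What it computes

**Simulation side.** A scaled-down NVE molecular-dynamics engine for
flexible three-site water (velocity Verlet at 0.1 fs, Ewald summation with
shifted-force short-range terms, Boltzmann initialization, simulated-
annealing equilibration), followed by:

* hydrogen-bond detection by the joint criteria
  *E* < −8 kJ/mol, *R*<sub>OH</sub> < 0.25 nm, α < 30°;
* bond-count histograms (n<sub>hb</sub> = 0…5, bifurcated bonds pooled at 5)
  and ⟨n<sub>hb</sub>⟩;
* cluster-size distributions of the H-bonded network and a percolation
  check (largest cluster ≥ 95% of molecules);
* the patch-size distribution *g(N₄)* — patches are connected components of
  molecules that donate exactly two and accept exactly two hydrogen bonds;
* partial radial distribution functions g<sub>OO</sub> and g<sub>OH</sub>
  (intra/intermolecular parts separated);
* power spectra of molecular motions,
  *S*(ω) = (1/2π) ∫ ⟨C(t)⟩ e<sup>−iωt</sup> dt, from summed H- and O-site
  velocity autocorrelation functions, with band skewness
  g₁ = m₃/m₂<sup>3/2</sup> and two-Gaussian decompositions
  (ω_max, W<sub>1/2</sub>, S_max per component).

**Spectroscopy side.** A band-shape toolkit for measured mid-IR spectra:
total-area normalization, difference spectra, Savitzky–Golay second
derivatives with component location, isosbestic-point detection, combination-
mode arithmetic (δ+L₂, 2L₂+2L₁, δ+2L₁), and a **mirror-FWHM** procedure for
asymmetric bands: the band is shifted so its maximum sits at zero, each
branch is reflected about the intensity axis, and the total FWHM is the sum
of half the FWHM of the two mirrored symmetric lines. For a split Gaussian
(σ_L left, σ_R right of the peak) this equals √(2 ln 2)(σ_L+σ_R) exactly.

**Synthetic data.** Generators with exact ground truth: ice-rule diamond
lattices with random bond dilution, damped-oscillator velocity trajectories,
and temperature series of split-Gaussian spectra with an exact two-state
isosbestic crossing.

## Worked example

Simulate the three reference state points — ambient water at 26 °C
(0.997 g/cm³) and 34 °C (0.994), and pressurized water at 103 °C represented
by its density (0.969) — at a small, fast-running scale (64 molecules, 10 ps production) and
collect network and band statistics:

```r
library(hydropatch)

cfg <- pipeline_config(n_molecules = 64, n_production_steps = 100000,
                       annealing_stage_steps = 4000, store_interval = 1,
                       vacf_max_lag = 2000, seed = 20)
rep <- run_pipeline(cfg)
print(rep)
```

which prints (times on one CPU core; full run ≈ 7 min):

```
pipeline run (...): all stages ok
  26C: simulate=ok, hbonds=ok, rdf=ok, spectra=ok (133.5 s)
    <n_hb> = 3.75, <N4> = 23.34, largest-cluster fraction = 1.00
  34C: simulate=ok, hbonds=ok, rdf=ok, spectra=ok (133.4 s)
    <n_hb> = 3.70, <N4> = 26.33, largest-cluster fraction = 1.00
  103C: simulate=ok, hbonds=ok, rdf=ok, spectra=ok (133.8 s)
    <n_hb> = 3.44, <N4> = 8.63, largest-cluster fraction = 1.00
```

Reading: the mean hydrogen-bond count per molecule decreases on heating
(3.75 → 3.70 → 3.44) while the largest cluster still spans the box — the
network stays percolating at 103 °C, but the mean patch size ⟨N₄⟩ collapses
(≈23 → ≈9): local tetrahedral order shrinks rather than vanishing. The
bending and stretching bands of the same runs are right-skewed at every
state point (skewness +0.45/+0.54/+0.85 bending, +0.48/+0.45/+0.63
stretching): molecules sample a distribution of hydrogen-bond environments.

The mirror-FWHM toolkit on a synthetic asymmetric bending band:

```r
grid <- seq(1300, 2100, 1)
s <- ifelse(grid < 1645, 30, 50)           # split Gaussian
band <- spectrum_curve(grid, exp(-(grid - 1645)^2 / (2 * s^2)))
mirror_band_analysis(band, c(1400, 2000))
#> band at 1645.24 cm^-1: total FWHM 94.19 (left 35.56 + right 58.63), skewness 0.385
```

(√(2 ln 2)(30+50) = 94.19 — the closed form, recovered from the sampled
curve.) And the combination-mode arithmetic:

```r
combination_mode_positions(mode_fundamentals(delta = 1645, L2 = 680, L1 = 395))
#>  delta+L2   2L2+2L1 delta+2L1
#>      2325      2150      2435
```

The numbered scripts under `analysis/` run this workflow end to end
(simulation → network statistics → RDFs → power spectra → IR band-shape
analysis on a synthetic temperature series) and write their tables under
`results/`.

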