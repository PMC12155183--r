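---
title: "Methods: hydrogen-bond microheterogeneity and vibrational band shapes in liquid water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond microheterogeneity and vibrational band shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hydropatch)
```

# Scope and scientific question

Liquid water is structurally heterogeneous on the molecular scale: molecules
that momentarily donate two and accept two hydrogen bonds ("four-bonded"
molecules) cluster into patches of ice-like local order embedded in a less
ordered, space-filling hydrogen-bond network. `hydropatch` implements the
computational machinery needed to quantify this microheterogeneity and its
temperature dependence:

* a scaled-down NVE molecular-dynamics engine for flexible three-site water;
* hydrogen-bond detection by joint energetic and geometric criteria, with
  bond-count histograms, cluster-size distributions, percolation checks, and
  the patch-size distribution $g(N_4)$ of connected four-bonded molecules;
* partial radial distribution functions $g_{OO}$ and $g_{OH}$;
* power spectra of molecular motions from site-velocity autocorrelation
  functions, with band skewness and two-Gaussian decompositions;
* an IR band-shape toolkit for measured spectra: area normalization,
  difference spectra, smoothed second derivatives, isosbestic-point location,
  a mirror-FWHM procedure for asymmetric bands, and combination-mode
  arithmetic;
* synthetic-data generators with exact ground truth for every analysis stage.

Internal units are nm, fs, u, kJ/mol, elementary charge, K and cm$^{-1}$;
all conversions route through the single constant set `water_constants`
($k_B = 0.0083144621$ kJ mol$^{-1}$ K$^{-1}$, $c = 2.99792458\times10^{-5}$
cm fs$^{-1}$, $f = 138.935458$ kJ nm mol$^{-1}$ e$^{-2}$).

# The molecular-dynamics engine

## The surrogate potential

The engine targets the behavior of flexible central-force water models:
three charged sites (O at $-0.66e$, H at $+0.33e$), an intramolecular power
series in internal coordinates, and pairwise intermolecular site-site terms.
Because the exact literature coefficients of that model family are not
reproduced here, the engine ships its own fully documented surrogate
parameterization; every coefficient sits in one block (`potential_params()`)
so an alternative set can be dropped in.

Intramolecular terms, with $s_i = r_i - r_e$ (nm) and
$s_\theta = \theta - \theta_e$ (rad):

$$V_\mathrm{intra} = \tfrac{k_r}{2}(s_1^2 + s_2^2)
 + k_{r3}(s_1^3 + s_2^3) + k_{r4}(s_1^4 + s_2^4)
 + \tfrac{k_\theta}{2} s_\theta^2 + k_{rr}s_1 s_2
 + k_{r\theta}(s_1 + s_2)s_\theta$$

Defaults: $r_e = 0.09572$ nm, $\theta_e = 104.52^\circ$ (gas-phase
geometry), $k_r = 4.0\times10^5$ kJ mol$^{-1}$ nm$^{-2}$,
$k_{r3} = -4.4\times10^6$, $k_{r4} = 5.5\times10^7$ (a Morse-consistent
cubic/quartic pair, $k_{r3} \approx -k_r a/2$ with $a \approx 22$ nm$^{-1}$),
$k_\theta = 545$ kJ mol$^{-1}$ rad$^{-2}$, and small stretch-stretch and
stretch-bend couplings. The stretch anharmonicity is physically essential:
a hydrogen-bonded O-H elongates in the field of its acceptor, and the cubic
term turns that elongation into the red shift that gives the liquid
stretching band its shape. $k_\theta$ and $k_r$ were calibrated once so
that the *liquid-phase* bending and stretching bands of the surrogate fall
near their observed positions (about 1650 and 3400-3500 cm$^{-1}$); the
resulting gas-phase normal modes sit slightly below the experimental gas
values, a deliberate trade-off documented here.

Intermolecular terms per site pair (OO, OH, HH):

$$V_{ab}(r) = \frac{f q_a q_b}{r} + A e^{-b r} - \frac{C_6}{r^6}
 - D e^{-\gamma (r - r_0)^2}$$

The Gaussian well (default only on O-H: $D = 20$ kJ/mol, $r_0 = 0.175$ nm,
$\gamma = 1500$ nm$^{-2}$) supplies the directional-contact cohesion that
central-force models place in their O-H short-range function. With it the
surrogate binds at about $-47$ kJ/mol per molecule near ambient conditions
(close to real water), hydrogen-bonded dimers sit near $-30$ kJ/mol (well
below the $-8$ kJ/mol bond criterion), and the mean bond count per molecule
reaches the 3.3-3.8 range at 299 K. Without it the liquid is underbound and
the network too sparse. The well depth, width and position were chosen at
design time against these qualitative anchors (cohesion, dimer energy,
$\langle n_{hb}\rangle$, band positions and asymmetry signs) and are not
revisited by any test.

## Electrostatics and cutoffs

Long-range Coulomb interactions use Ewald summation: real-space
erfc-screened sum, reciprocal sum over integer lattice vectors with
$|\mathbf n|^2 \le 27$, self-energy, and intramolecular exclusion
corrections (each molecule's three site pairs interact only through the
valence terms). Defaults: splitting parameter $\alpha = 5/L$ and real-space
cutoff just under $L/2$, resolved against the box at use time.

All real-space radial terms - including the erfc part - are truncated with
shifted-force smoothing: $V_{sf}(r) = V(r) - V(r_c) - (r - r_c)V'(r_c)$.
For the erfc term the shift constants are of order
$\mathrm{erfc}(2.5) \approx 4\times10^{-4}$ of the bare term, so accuracy is
essentially unchanged, while the potential becomes exactly continuous with
continuous forces at the cutoff. This matters for NVE quality: with plain
truncation, pairs crossing the cutoff inject small energy jumps that put a
floor under $\Delta E/E$.

## Integration, equilibration, and the energy-stability metric

Production dynamics is velocity-Verlet at a 0.1 fs step, strictly NVE, with
positions and velocities stored every 1 fs by default. Equilibration is
simulated annealing: by default three stages at target+150 K, target+50 K
and the target, with exact velocity rescaling (and momentum removal) every
50 steps; the final stage holds six times longer than the hot stages
because the slow tail of structural ordering otherwise continues into
production and drifts the temperature upward.

The energy report covers production only and defines
$\Delta E/E = (\max - \min)/|\mathrm{mean}|$ of the stored total energy.
This metric divides an absolute integration error by the system's total
energy, so at fixed integrator quality it degrades as systems shrink: the
velocity-Verlet shadow-energy wander here is $\approx 0.03$ kJ/mol over
5 ps regardless of size, which is $\sim10^{-5}$ of $|E|$ for a 400-molecule
box but only $\sim3\times10^{-5}$ for 32 molecules. For runs that must meet
the $10^{-5}$ band at small sizes the engine provides
`integrator = "yoshida4"`, a 4th-order symplectic composition of three
velocity-Verlet substeps at the same 0.1 fs step (time-reversible, strictly
NVE, explicit velocities at every stored step); it conserves to
$\sim10^{-7}$ at triple the force cost. Velocity-Verlet remains the default
for production physics runs.

Divergence protection: the integrator aborts with the failing step count
when the total energy becomes non-finite or grows by more than an order of
magnitude.

# Hydrogen-bond network analysis

A donor-hydrogen/acceptor pair is bonded when all three criteria hold:
(i) molecule-pair interaction energy $E < -8$ kJ/mol, (ii)
$R_{OH} < 0.25$ nm between donor hydrogen and acceptor oxygen, (iii)
inclination $\alpha < 30^\circ$ of the donor O-H bond to the O-O line. The
pair energy for criterion (i) is the full unscreened intermolecular
site-site sum (bare Coulomb + short-range terms, minimum image, no cutoff):
pair energies are only well defined outside the Ewald lattice-sum
decomposition, whose real/reciprocal split has no per-pair meaning.

Derived statistics:

* **Bond-count histogram** - per-molecule degree (donor or acceptor);
  molecules with more than 5 bonds are pooled into the displayed
  $n_{hb} = 5$ ("bifurcated") bin but counted exactly in
  $\langle n_{hb}\rangle$.
* **Cluster-size distribution** - connected components of the undirected
  bond graph. Two means are reported: the per-cluster mean and the
  per-molecule weighted mean $\sum N^2 / \sum N$ (the expected size of the
  cluster containing a randomly chosen molecule). In a percolating box the
  weighted mean approaches the molecule count while the per-cluster mean is
  dragged down by small fragments; reporting both resolves the ambiguity of
  "mean cluster size" without choosing.
* **Patches** - a molecule is four-bonded iff it has *exactly* two donor
  and two acceptor bonds (a 3+1 split of degree 4 does not qualify; a
  molecule with a fifth bond cannot qualify). Patches are connected
  components of the subgraph induced on four-bonded molecules, with edges
  restricted to bonds whose both endpoints are four-bonded. The relaxed
  reading that admits bifurcated molecules (at least 2+2) is available via
  `include_bifurcated = TRUE`.
* **Percolation** - the network is called space-filling when the largest
  cluster holds at least 95% of molecules (configurable).

Frame-averaged statistics sample every 100 fs by default to reduce serial
correlation between analyzed frames.

Graph components are computed with igraph; the test suite checks them (and
the patch logic) against a hand-written exhaustive-reachability oracle on
a thousand random graphs.

# Radial distribution functions

$g(r)$ is the minimum-image pair-distance histogram divided by the
ideal-gas shell expectation $4\pi r^2 \Delta r\, \rho_\mathrm{pair}$ per
frame. Pair densities: $N(N-1)/2$ over $V$ for O-O; $2N(N-1)/V$ for
intermolecular O-H; and the uncorrelated-sites convention $2N^2/V$ for
intramolecular O-H, under which $4\pi\rho_H \int g r^2 dr$ over the bond
peak equals exactly 2 hydrogens per oxygen. Default bin width 0.002 nm and
$r_\mathrm{max} = L/2$ (requests beyond $L/2$ are an error: the spherical
shell normalization breaks there).

# Power spectra and band statistics

The spectral density is the cosine transform of the even-extended, tapered
velocity autocorrelation function:
$S(\omega) = \tfrac{1}{2\pi}\int \langle C(t)\rangle e^{-i\omega t} dt$.
The VACF is averaged over time origins (FFT-based) and over sites, per
species; the combined curve is the unweighted mean of the normalized H and
O curves (a mass-weighted option exists; the choice only rescales relative
band intensities, not positions). The default maximum lag is 2 ps at 1 fs
sampling, giving $\approx 8$ cm$^{-1}$ resolution - matching the positional
uncertainty quoted for such spectra. A Hann taper is the default window
(rectangular available); it suppresses the truncation ripple that would
otherwise bias skewness estimates. Small negative lobes left by the taper
are clipped to zero with a message. On the discrete grid the transform
satisfies Parseval's identity exactly (tested to $10^{-6}$).

**Band skewness** is the third standardized moment of the
intensity-weighted wavenumber distribution inside a fixed window
(1400-2000 cm$^{-1}$ for bending, 3150-3950 cm$^{-1}$ for stretching),
optionally after an endpoint-anchored linear baseline. Power spectra decay
to zero and use no baseline; measured absorbance bands use the linear mode.
Positive values mean a longer right tail.

**Two-Gaussian decomposition** fits
$S(\tilde\nu) \approx \sum_{i=1,2} S_i \exp(-(\tilde\nu-\omega_i)^2 \ln 2 / W_i^2)$
by Levenberg-Marquardt least squares with jittered restarts. $W_i$ is the
half-width at half maximum of component $i$; because the conventional
"half-width" label is ambiguous, the component table reports both $W_{1/2}$
and the full width $2W_{1/2}$. Components are ordered by descending height.
A two-component fit can never have a larger residual than the
single-component fit of the same window (tested).

# IR band-shape toolkit

* **Normalization** divides by the trapezoid integral over the recorded
  range (the exact normalization window is configurable; results only
  change by a global scale, to which every shape statistic is invariant).
* **Difference spectra** subtract a reference (typically the coldest
  temperature) pointwise, resampling mixed grids linearly onto the coarser
  grid over the overlap.
* **Second-derivative component location**: Savitzky-Golay smoothing
  (default window 15 points, order 3), analytic second differentiation
  through the same filter, smoothing again ("before and after"). Components
  are interior local minima with depth at least `min_prominence` (default
  0.1) of the largest |second derivative| *and* a surrounding
  negative-curvature run of at least `min_width` points (default three
  smoothing windows). The width criterion encodes the filter's resolution
  floor: narrower minima are noise artifacts; with it, pure-noise input
  yields an empty component list while overlapping bands unresolved in the
  raw sum are still separated.
* **Isosbestic location** minimizes the across-spectra standard deviation
  of intensity on a common grid; an exact two-state mixture series pins the
  crossing to one grid step. Degenerate input (identical spectra) is
  flagged rather than returning an arbitrary point.
* **Mirror-FWHM** for asymmetric bands: locate the maximum, refine position
  and height with a 3-point parabola (sub-grid accuracy matters because
  reported shifts are below the instrument resolution), shift the peak to
  zero, split the band, and reflect each branch about the intensity axis to
  form two symmetric lines. The total FWHM is the sum of half the FWHM of
  the two mirrored lines, each measured by linear interpolation at half
  maximum. For a split Gaussian ($\sigma_L$ left, $\sigma_R$ right of the
  peak) this equals $\sqrt{2\ln 2}(\sigma_L + \sigma_R)$ exactly, which the
  tests verify along with the skewness sign matching
  $\mathrm{sign}(\sigma_R - \sigma_L)$. Ties among equal maxima break
  toward the lower wavenumber with a message; a maximum on the window edge
  is an error (the window is too narrow). Baseline handling is linear
  through the window endpoints by default ("none" available) and is
  recorded in the result.
* **Combination modes**: from fundamentals $\delta$ (bending, 1645),
  $L_2$ (major libration, 680) and $L_1$ (minor libration, 395 cm$^{-1}$),
  the candidate assignments $\delta + L_2$, $2L_2 + 2L_1$ and
  $\delta + 2L_1$ evaluate to 2325, 2150 and 2435 cm$^{-1}$.

# Synthetic generators and what they do (not) show

* `generate_lattice_network()` places oxygens on a diamond-cubic (cubic-ice)
  lattice and orients all bonds along an Eulerian circuit of the 4-regular
  bond graph, which enforces the ice rules (two donors, two acceptors per
  molecule) exactly; bonds are then deleted independently with probability
  $p$. It provides exact ground truth for every network statistic (mean
  degree $4(1-p)$, binomial fluctuations) - but only connectivity, not
  thermodynamically realistic geometry.
* `generate_oscillator_trajectory()` builds site velocities as damped
  cosines with random phases plus optional white noise; the sampling guard
  requires at least ten samples per period of the fastest mode. It
  validates the VACF/spectral-density chain (peak positions to one
  resolution element, power ratios as amplitude squared) without any
  anharmonic or rotational physics.
* `generate_spectrum_series()` produces labeled temperature series of
  split-Gaussian components with linear parameter ramps, optionally plus an
  exact two-state pair sharing a crossing, plus noise, with the exact
  per-label parameter table returned. The split-Gaussian family is chosen
  because mirror-FWHM and the skewness sign have closed forms there.

Passing tests on these generators demonstrates the estimators' correctness
on data with known truth; they do not certify the MD surrogate against real
water beyond the qualitative anchors listed above.

# Problem sizes and study conditions

The workstation-scale study conditions used by the tests, the analysis scripts and
the acceptance script are: 64 molecules and 10 ps of production (0.1 fs
step, frames every 1 fs) per state point for network and spectral
statistics, with the three state points (26 °C, 0.997 g/cm$^3$), (34 °C,
0.994) and (103 °C, 0.969) - the last representing the pressurized liquid
through its density alone, since the NVE ensemble fixes volume and pressure
is never computed; and 32 molecules, 5 ps for the energy-stability run.
These sizes were chosen as the smallest at which the percolating network,
the temperature ordering of $\langle n_{hb}\rangle$ and $\langle N_4\rangle$,
and the band-asymmetry signs are stable. Full-scale (400 molecules, 50 ps,
$\sim10^6$-step equilibration) values such as
$\langle n_{hb}\rangle = 3.4/3.2/2.8$ cannot be reproduced at this scale and are
treated as qualitative anchors: at this scale the surrogate's absolute
numbers differ, while orderings and signs reproduce.

# Known limitations

* The surrogate potential is calibrated to qualitative anchors, not to
  thermodynamic data; its absolute $\langle n_{hb}\rangle$, patch sizes and
  band widths differ from the full central-force model.
* Small boxes make the Ewald cutoffs ($\alpha = 5/L$, $r_c < L/2$)
  system-size-dependent; RDF tails within ~0.05 of 1 require $\gtrsim100$
  molecules.
* Bending-band skewness in a fixed window is sensitive to the band's
  position within that window; the surrogate places the liquid bend near
  1650 cm$^{-1}$ by calibration.
* The realized mean temperature of short annealed runs can sit several K
  from the target (residual structural relaxation); the three state points
  remain well separated.
* No H-bond lifetime/autocorrelation analysis; no induced dipoles or
  quantum corrections; non-cubic boxes and binary trajectory formats are
  out of scope.
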