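---
title: "Excitonic couplings and 2D-DAS analysis of strongly coupled chlorophylls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitonic couplings and 2D-DAS analysis of strongly coupled chlorophylls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exciton2des)
```

`exciton2des` models the photophysics of small, strongly coupled chlorophyll
assemblies — the water-soluble chlorophyll protein (WSCP), which binds four
chlorophylls as two "open-sandwich" dimers, is the motivating system — and
analyses their ultrafast dynamics the way 2D electronic spectroscopy (2DES)
practitioners do: global multiexponential fitting of the full
(excitation, emission, waiting-time) data cube, followed by interpretation of
the resulting 2D decay-associated spectra (2D-DAS). This vignette documents
the models, the defaults, and the numerical choices.

## The Frenkel exciton model

Each pigment is reduced to a point transition dipole: a center (the central
Mg atom), a Qy direction, a dipole magnitude $\mu$ (Debye) and a site energy
(cm$^{-1}$). The coupling between pigments $a$ and $b$ is the point-dipole
interaction

$$V_{ab} \;=\; C\,\frac{\kappa_{ab}\,\mu_a \mu_b}{R_{ab}^{3}},\qquad
\kappa_{ab} = \hat\mu_a\!\cdot\!\hat\mu_b
  - 3(\hat\mu_a\!\cdot\!\hat R)(\hat\mu_b\!\cdot\!\hat R),$$

with $C = 5034.1\ \mathrm{cm^{-1}\,\mathring{A}^3\,D^{-2}}$ (the vacuum
Coulomb prefactor $1\,\mathrm{D^2/\mathring{A}^3}$ expressed in wavenumbers;
no dielectric screening by default, an optional multiplier is accepted). The
site Hamiltonian carries site energies on the diagonal and the $V_{ab}$ off
the diagonal; its eigenvectors define the exciton states, and exciton
transition dipoles are the eigenvector-weighted sums of the site dipoles, so
the total dipole strength $\sum_k |\boldsymbol\mu_k|^2 = \sum_i \mu_i^2$ is
conserved exactly.

For a degenerate dimer the exciton splitting is exactly $2V$. With the
literature monomer dipoles (Chl *a* 4.58 D, Chl *b* 3.83 D) and
dimer geometries like those of WSCP, intradimer couplings fall around
$10^2\ \mathrm{cm^{-1}}$ and the expected splittings around
$200\ \mathrm{cm^{-1}}$ (Chl *a*) and $130\ \mathrm{cm^{-1}}$ (Chl *b*).

Two conventions are deliberately configurable because published analyses
rarely state them: the Qy direction is taken as the normalized NB→ND ring
nitrogen vector (a widely used convention, but the sign and the atom pair can
be changed), and the dipole origin is the Mg atom. Absolute couplings
computed from a structure can shift by a few cm$^{-1}$ under different
conventions or screening assumptions; comparisons at the ±10 cm$^{-1}$ level
are the honest resolution of the method. The package bundles no crystal
structure; `write_synthetic_tetramer()` emits a clearly labelled synthetic
tetramer (two parallel side-by-side dimers, $\kappa = 1$, 10.12 Å Mg–Mg)
whose intradimer coupling of a 4.58 D dipole is ≈102 cm$^{-1}$, so the whole
geometry → coupling → Hamiltonian chain is exercised end to end without
external downloads.

## The synthetic 2DES generator

`generate_dataset()` synthesizes absorptive 2DES data directly in the
frequency domain: each feature is a 2D Gaussian with principal axes along the
diagonal and antidiagonal, its time-dependent amplitude follows a named
channel of a first-order kinetic network ($\dot p = Kp$, solved exactly), and
every peak is weighted by a Gaussian laser envelope evaluated at both its
excitation and emission frequency. Coherence-dephasing dynamics — the
ultrafast loss of exciton-superposition amplitude — are modelled as
non-oscillatory overdamped channels $a\,e^{-t_2/\tau_{\mathrm{deph}}}$.
Noise is i.i.d. Gaussian with standard deviation expressed as a fraction of
the global noiseless maximum, drawn from the recipe seed; a recipe is
bit-reproducible.

This forward model is deliberately inside the model class of the downstream
fit (sums of exponentials per pixel), which makes parameter recovery a clean
test surface. What it does **not** emulate: finite-pulse/pulse-overlap
artifacts, oscillatory coherence beats, Stokes-shift dynamics, spectral
diffusion and inhomogeneous lineshape evolution, excited-state absorption of
opposite sign. Passing tests therefore demonstrate the correctness of the
fitting and interpretation machinery, not the fidelity of any lineshape
theory.

`fixture_recipes()` encodes four ground-truth recipes emulating the four
WSCP complexes studied by 2DES at 77 K:

| recipe | exciton states (cm$^{-1}$) | kinetics | noise |
|---|---|---|---|
| Lv-a | 15 070, 14 850 | 100 fs downhill + 2 ps slow | 1% |
| Bo-a | 14 830, 14 600 | same | 1% |
| Lv-b | 14 660, 15 050, 15 400, 15 660 | same + 10 fs coherence | 0.5% |
| Bo-b | 14 620, 14 900, 15 300, 15 650 | same + 10 fs coherence | 0.5% |

All recipes use the experimental sampling of the motivating study: $t_2$
from 0 to 1000 fs in 7.5 fs steps, a laser envelope centered at
15 380 cm$^{-1}$ with the ≈1840 cm$^{-1}$ bandwidth of an 8 fs
transform-limited pulse (`pulse_bandwidth(8)`), and 10 cm$^{-1}$ frequency
grids spanning 14 200–16 200 cm$^{-1}$. The slow component is set to 2 ps —
inside the ">1 ps, slower than the window" regime; its exact value is not
resolvable from a 1 ps window and is not asserted anywhere. Lineshapes
(FWHM 150 cm$^{-1}$ diagonal, 70 cm$^{-1}$ antidiagonal) are narrower along
the antidiagonal, as for partially inhomogeneously broadened low-temperature
spectra. Peak amplitude scales (diagonal 1.0 with the bleach/stimulated-
emission split 0.6/0.5, relaxation cross peak 0.7, coherence amplitudes
0.6 diagonal / 0.8 cross) were fixed once at values typical of such data —
coherence cross peaks comparable to the main features, as early-time 2DES
maps of coupled dimers show. The Chl-a lower diagonal peak is dominated by
slowly decaying ground-state bleach plus a weak (0.3) rising
stimulated-emission term, so the fast DAS shows the canonical
positive-diagonal / negative-below-diagonal relaxation signature.

## Global fitting by variable projection

The fit model at every pixel is $S(t_2) = \sum_{i=1}^{k} A_i\,
e^{-t_2/\tau_i}$ with the $\tau_i$ shared across all pixels; the maps
$A_i(\omega_1,\omega_3)$ are the 2D-DAS (positive = decaying,
negative = rising — amplitudes are unconstrained in sign by definition).
Points with $t_2 < 15$ fs are excluded by default, suppressing
pulse-superposition artifacts in real data and, in the synthetic fixtures,
forcing the 10 fs component to be inferred from its tail alone.

Because the amplitudes enter linearly, the outer search runs only over
$\log\tau$ (positivity by construction) and solves the amplitudes exactly by
least squares at every step (variable projection). The outer optimizer is a
Nelder-Mead simplex with five multi-starts: a log-spaced base set over
5 fs–5 ps plus seeded jittered variants; the best pooled SSR wins, ties going
to the smallest fast $\tau$. The inner solve uses a QR factorization for the
reported amplitudes and the normal equations (with a cached $\|Y\|^2$) inside
the objective for speed; a basis condition number above $10^{10}$ — nearly
equal time constants — is an error naming the offending pair. An optional
plateau (infinite-$\tau$) column represents dynamics far slower than the
window when a free slow $\tau$ would be poorly determined.

### Choosing the number of components

`select_components()` fits $k = 1,\dots,k_{\max}$ and minimizes a pooled
BIC. The parameter count is $k$ shared time constants plus $k$ amplitudes
per pixel, but the two kinds of parameter are not informed by the same
amount of data: the time constants see all $n = n_t \times n_{\mathrm{pix}}$
residuals, while each pixel's amplitudes are determined only by that pixel's
$n_t$ trace points. The criterion therefore penalizes them with their
effective sample sizes,

$$\mathrm{BIC}(k) = n\log(\mathrm{SSR}/n) + k\log n
  + k\,n_{\mathrm{pix}}\log n_t .$$

Penalizing every amplitude with $\log n$ instead would make the criterion
blind to any shared component whose pooled evidence is overwhelming but whose
per-pixel amplitude is modest — on the four-state fixtures it would reject a
third component that the fit recovers to better than 1%, which is how this
design choice was settled. With the effective-sample-size form the fixtures
behave correctly: two components for the Chl-a recipes, three for the Chl-b
recipes (the 10 fs coherence channel), one for pure noise.

## Interpreting the 2D-DAS

`find_extrema()` locates local extrema of $|A(\omega_1,\omega_3)|$ above a
prominence threshold (default 20% of the map maximum) after a light Gaussian
smoothing (FWHM 3 grid steps ≈ 30 cm$^{-1}$, far below the 70 cm$^{-1}$
antidiagonal linewidth). The smoothing exists because the $t_2 \ge 15$ fs
tail of a 10 fs exponential has a tiny basis norm, so its DAS carries
amplified amplitude noise that would otherwise fragment broad features into
spurious extrema; positions move by at most about one grid step. Extrema are
read off at grid coordinates — mirroring how DAS coordinates are read in
practice — rather than centroid-refined.

* `estimate_relaxation_gap()` pairs the strongest positive diagonal extremum
  with a negative below-diagonal extremum in the same excitation column
  (tolerance: the diagonal-band tolerance, default 2 grid steps): the
  emission-frequency difference estimates the donor→acceptor exciton gap.
* `count_exciton_states()` deduplicates diagonal extrema within one
  antidiagonal-linewidth estimate (default 4 grid steps) and reports which
  state pairs are connected by symmetric cross peaks — the hallmark of
  excitonic coupling.
* `infer_effective_dipole()` exposes the quadratic dipole–intensity
  relation: at fixed geometry $V \propto \mu^2$ and the gap $\propto V$, so
  $\mu_{\mathrm{eff}} = \mu_{\mathrm{ref}}
  \sqrt{\Delta E_{\mathrm{obs}}/\Delta E_{\mathrm{calc}}}$. It is a
  calculation, not an asserted constant: which observed splitting feeds it is
  the analyst's choice. An observed Chl-b splitting four times the
  point-dipole prediction, say, turns a 3.83 D reference dipole into 7.66 D —
  the regime where protein-induced dipole enhancement is the parsimonious
  reading.

## Degenerate inputs, tie-breaks, tolerances

Eigenvalues are returned ascending with eigenvector signs fixed (first
non-zero component positive). Missing coupling pairs default to zero with a
notice; duplicate labels, coincident centers, non-symmetric Hamiltonians and
non-conserving rate matrices are errors. Sub-2 Å separations flag the
point-dipole approximation as invalid. The kinetics solver uses the
eigen-decomposition of $K$ and falls back to a scaling-and-squaring matrix
exponential when $K$ is defective. Dataset containers are plain text (one
matrix per $t_2$ plus a JSON sidecar) and round-trip at 9 significant
digits.

## Problem sizes

The full fixtures (201×201 pixels × 134 waiting times) fit in seconds to a
few tens of seconds per model size on one core; the package's test suite exercises the complete
chain on the full fixtures once and uses 57×57-pixel, 15 fs-step variants
of the same recipes for the property sweeps (20 noise realizations for
robustness, 10 for end-to-end gap recovery). `run_pipeline()` writes every
intermediate plus a manifest of md5 hashes, and identical configuration and
seed reproduce identical hashes.

## Known limitations

Point-dipole couplings degrade at contact distances (WSCP intradimer
separations of ~10 Å are near the edge of comfort); no transition-charge or
quantum-chemical couplings are provided. The generator's Gaussian,
non-evolving lineshapes cannot probe lineshape-analysis methods. Model
selection assumes i.i.d. Gaussian residuals; correlated residuals (scatter,
phasing errors) in real data would require a noise model this package does
not implement. Bootstrap error bars on $\tau$ and DAS amplitudes are future
work.
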