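# exciton2des

Frenkel exciton models and global lifetime analysis of two-dimensional
electronic spectra, for small strongly coupled chlorophyll assemblies such as
the water-soluble chlorophyll protein (WSCP) — a tetramer binding four
chlorophylls as two "open-sandwich" dimers. The package is aimed at
spectroscopists and modellers who need to connect pigment geometry to
excitonic structure and then to the ultrafast relaxation signatures seen in
2D electronic spectroscopy (2DES).

It covers the full chain:

1. **Excitonics** — point-dipole couplings
   `V = C κ μₐμᵦ / R³` (C = 5034.1 cm⁻¹ Å³ D⁻², μ in Debye, R in Å) from
   PDB/mmCIF geometry, Frenkel Hamiltonian assembly and diagonalization,
   exciton gaps (exactly `2V` for a degenerate dimer) and stick spectra.
2. **Synthetic 2DES** — seeded, bit-reproducible datasets
   `S(ω₁, ω₃, t₂)`: Gaussian exciton peaks on diagonal/antidiagonal axes,
   first-order downhill relaxation kinetics, overdamped coherence-dephasing
   channels, laser-envelope weighting and additive Gaussian noise, including
   ground-truth recipes for the four WSCP complexes (Lv-a, Lv-b, Bo-a, Bo-b).
3. **Global fitting** — variable projection: shared time constants across all
   pixels (outer search on log τ, multi-start), exact per-pixel linear
   amplitudes, yielding 2D decay-associated spectra (2D-DAS; positive =
   decaying, negative = rising) and BIC model-size selection. Waiting times
   below 15 fs are excluded by default.
4. **DAS analysis** — extremum picking, exciton-state counting with symmetric
   cross-peak connectivity, donor→acceptor relaxation-gap estimation, and
   effective-dipole inference via μ_eff = μ_ref √(ΔE_obs / ΔE_calc).

## Worked example

```r
library(exciton2des)

# 1. Couplings and exciton gaps from geometry
pdb <- tempfile(fileext = ".pdb")
write_synthetic_tetramer(pdb)            # synthetic WSCP-like tetramer
pigments <- parse_structure(pdb)
model <- diagonalize(build_hamiltonian(pigments))
coupling_table(model)
#>       a     b distance_A kappa      V_cm1
#> 1 CLAA1 CLAB1   10.12000     1 101.885236
#> 2 CLAA1 CLAC1   25.00000     1   6.758227
#> 3 CLAA1 CLAD1   26.97062     1   5.382449
#> 4 CLAB1 CLAC1   26.97062     1   5.382449
#> 5 CLAB1 CLAD1   25.00000     1   6.758227
#> 6 CLAC1 CLAD1   10.12000     1 101.885236
exciton_gap(model, 1, 3)
#> [1] 193.0056
```

Two dimers with intradimer coupling ≈102 cm⁻¹ and order-of-magnitude weaker
interdimer terms: the four exciton states form two nearly degenerate pairs
split by about 2V ≈ 204 cm⁻¹ (the weak interdimer couplings spread the
individual gaps, here 193 cm⁻¹ between states 1 and 3).

```r
# 2. Simulate the Lv-a fixture and fit two shared time constants
recipe <- fixture_recipes(seed = 1)[["Lv-a"]]
dataset <- generate_dataset(recipe)
dataset
#> <dataset_2des Lv-a>  134 maps of 201 x 201 (omega1 x omega3), t2 0.0-997.5 fs
fit <- global_fit(dataset, fit_config(n_components = 2, seed = 1))
fit
#> <global_fit_result>  k = 2, tau = 99.95, 2002 fs, SSR = 464.412
```

The two shared time constants recover the recipe's ground truth (100 fs
downhill relaxation, 2 ps slow decay) from data carrying 1% noise.

```r
# 3. Read the DAS: exciton states and the relaxation gap
analysis <- analyze_fit(fit)
analysis$states$energies
#> [1] 14850 15070
analysis$gap
#> <gap_estimate>  15070 -> 14850 cm^-1, gap 220 cm^-1 (tau = 99.95 fs)
```

The fast-component DAS shows the canonical downhill-relaxation signature — a
positive (decaying) diagonal peak at the upper exciton and a negative
(rising) cross peak below the diagonal — and the emission-frequency
difference of that pair estimates the exciton gap: 220 cm⁻¹ here, matching
the recipe's state separation. When an observed splitting exceeds the one
calculated from geometry with literature dipoles, the quadratic
dipole–intensity relation converts the ratio into an effective dipole:

```r
infer_effective_dipole(gap_observed = 350, gap_calculated = 134,
                       mu_reference = 3.83)
#> <dipole_rescale>  mu_ref = 3.83 D, gap obs/calc = 350/134 cm^-1 -> mu_eff = 6.19 D
```

`run_pipeline(pipeline_config("Bo-b"))` chains all stages (optional
couplings → simulate → fit with model selection → DAS analysis) and writes
every intermediate plus an md5 manifest; identical config and seed give
identical outputs.

See `vignettes/exciton2des-methods.Rmd` for the models, defaults and
numerical choices.

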