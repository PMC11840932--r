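# ftirbind

FTIR band analysis and binding-distance modelling for the interaction
of Endonuclease III (EndoIII) — a [4Fe4S]-cluster DNA-repair
glycosylase — with double-stranded DNA.

When EndoIII binds dsDNA, characteristic infrared bands move: the
amide-I band (1653 cm⁻¹) downshifts by ~3 cm⁻¹, the Fe–S thiolate
stretch of the cluster downshifts from 362 to 352 cm⁻¹, the DNA
deoxyribose (890 cm⁻¹) and O–P–O bending (967 cm⁻¹) bands disappear,
and several sugar–phosphate bands shift by a few wavenumbers.
`ftirbind` is for spectroscopists and structural bioinformaticians who
want to turn such band tables into quantitative statements about the
complex. It provides:

* **Synthetic spectra** — a forward model (pseudo-Voigt bands +
  polynomial baseline + seeded gaussian noise) packaged with the full
  documented band inventory for dsDNA, EndoIII, and the complex, so
  the entire analysis is testable without instrument data.
* **Preprocessing** — iterative polynomial baseline correction,
  Savitzky–Golay second derivatives, prominence-filtered peak
  detection, and greedy cross-spectrum band matching producing a
  shift table (ν₀, ν, Δν, intensity change, shifted / disappeared /
  new / unchanged).
* **Distance model** — the inverse law *r* = *k*/|ν − ν₀| (interaction
  energy taken ∝ Δν and ∝ 1/*r*), calibrated so the largest shift maps
  to the closest approach (7.0 Å) and capped at 16 Å.
* **Regression** — closed-form ridge (α = 1.0, unpenalized intercept)
  and a fixed 2-5-1 ReLU network trained by full-batch gradient
  descent, evaluated with an 80/20 split plus 5-fold CV (MSE, R²).
* **Thermodynamics** — ΔG = −RT ln K_d and ΔS = (ΔH − ΔG)/T with
  R = 8.314 J/(mol K), reported under the stated sign convention.
* **Structure** — [4Fe4S] cubane geometry (core vs thiolate Fe–S
  bonds) and protein–DNA distance sets (cluster + backbone-N donors
  to DNA phosphate acceptors, 50 shortest) from PDB coordinates via
  `bio3d`.

## Worked example

```r
library(ftirbind)
rep <- run_pipeline(default_run_config(seed = 1L))
print(rep)
#> <run_report> cb5d2b2629fd65abf5a465d53678db72
#>   shifts: 17 rows (4 shifted, 2 disappeared, 2 new)
#>   distances: 4 estimates in [7.00, 16.00] A
#>   regression: training-fit-only
#>   thermo: dG = 28.52 kJ/mol, dS = -196.39 J/(mol K)

subset(rep$shifts, status %in% c("shifted", "disappeared"))
#>            assignment    nu0     nu delta_nu      status
#> 2       Fe-S thiolate  362.0  352.1    9.896     shifted
#> 7    deoxyribose ring  890.6     NA       NA disappeared
#> 8       O-P-O bending  967.0     NA       NA disappeared
#> 9  phosphate backbone 1055.1 1058.0    2.938     shifted
#> 12    CH2 wag/N-H def 1281.9 1280.7    1.174     shifted
#> 15            amide-I 1652.9 1650.1    2.828     shifted

rep$distances[, c("assignment", "delta_nu", "r", "capped")]
#>           assignment delta_nu  r capped
#> 1      Fe-S thiolate    9.896  7  FALSE
#> 2 phosphate backbone    2.938 16   TRUE
#> 3    CH2 wag/N-H def    1.174 16   TRUE
#> 4            amide-I    2.828 16   TRUE
```

Reading this: the pipeline simulated the four packaged spectra,
recovered the thiolate downshift (Δν ≈ 9.9 cm⁻¹, i.e. 362 → 352) and
the amide-I downshift (≈ 2.8 cm⁻¹), flagged the 890/967 cm⁻¹ DNA bands
as disappeared (intensity-confirmed), calibrated the distance law so
the largest shift anchors at 7.0 Å, and capped the small-shift bands
at 16 Å — the two ends of the documented binding-distance range. The
thermodynamics block evaluates ΔG = −RT ln K_d = 28.52 kJ/mol at
K_d = 10 μM and T = 298 K, and ΔS = −196.39 J/(mol K) with
ΔH = −30 kJ/mol (positive ΔG under this convention; see the methods
vignette).

Cluster geometry from coordinates:

```r
geom <- extract_cluster(parse_structure(synthetic_cubane_pdb(2.30)))
geom$summary   # 12 core + 4 thiolate bonds, mean 2.30 Å
```

A thin CLI over the same functions lives at
`inst/scripts/ftirbind-cli.R` (`run`, `simulate`, `thermo`,
`structure` subcommands).

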