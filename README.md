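# pectinporo

Pectin cross-linking and plant cell wall porosity analysis in R.

The porosity of the plant cell wall controls which molecules reach the
cell, and it is set largely by how strongly the wall's pectin network is
cross-linked: homogalacturonan (HG) chains join through
-COO⁻‖Ca²⁺‖-COO⁻ bridges between deprotonated galacturonic-acid
residues and, more weakly, through hydrogen bonds involving
methyl-esterified or protonated carboxyl groups. This package implements
three connected analyses that quantify that link, for plant cell-wall
researchers working with fluorescence quenching assays, electron
micrographs, or molecular trajectories:

1. **Quencher-diffusion model of fluorescence decay.** A wall of
   thickness *h* separates a quencher bath (concentration *q_b*) from a
   fluorophore-labelled membrane of thickness *h_m*. With effective
   diffusion *D_e = CφD/η(φ)* and Bruggeman tortuosity *η = φ^(−1/2)*,
   the membrane concentration is *q_m(t) = q_b(1 − e^(−t/T))* with
   characteristic time *T = h_m h / D_e*, and the Stern–Volmer relation
   gives the relative fluorescence

   *I(t) = 1 / (1 + K q_b (1 − e^(−t/T)))*.

   Fitting *(K, T)* per genotype by bounded nonlinear least squares and
   comparing characteristic times yields the porosity ratio
   *φ_alt/φ_ref = (T_ref/T_alt)^(2/3)* — the unknown pore attenuation
   *C* and the geometry cancel.

2. **Pore-size quantification from micrographs.** Otsu thresholding →
   morphological opening → 8-connected labelling → inclusive 5–300 nm²
   area filter → 15 nm²-wide frequency bins over 5–305 nm², and the
   coverage porosity estimate *φ = ⟨A_p⟩·N_p / A_s*.

3. **Cross-link statistics from trajectories.** Distance-based detection
   of calcium bridges (Ca–O ≤ 0.30 nm on two chains), methyl/carbonyl
   hydrogen bonds (≤ 0.40 nm) and carboxyl hydrogen bonds (≤ 0.25 nm)
   under periodic boundary conditions; contact lifetimes from maximal
   presence runs; and the time-averaged largest chain aggregate *N_agg*.

Seedable synthetic-data generators with planted ground truth
(fluorescence series, pore scenes, trajectories with scheduled
cross-link events) make every stage testable end to end with no external
data.

## Worked example

```r
library(pectinporo)

# simulate a two-genotype quenching experiment with a planted porosity
# ratio of 1.4717 (wild type vs a low-cross-linking mutant)
g <- gen_two_genotypes(phi_ratio = 1.4717, T_ref = 300, K = 1e4,
                       q_b = 5e-4, seed = 7)
res <- fit_genotypes(g$series, q_b = 5e-4, reference = "Col0")
res$fits
#>  label     K_hat    T_hat      se_K      se_T          rss n converged
#>   Col0  9873.355 295.9495 222.75846 13.206172 5.338098e-05 6      TRUE
#>   sfr8  9882.806 156.6930 101.71729  5.269583 2.126039e-05 6      TRUE
res$porosity_ratio
#>    sfr8
#> 1.52796
```

The fit recovers *K* near the planted 10⁴ m³ mol⁻¹ for both genotypes
and the two characteristic times (planted: 300 s and 168 s); the mutant
wall comes out ≈1.5× more porous than the wild type, estimating the
planted ratio 1.4717 from noisy data. Across replicate experiments the
median absolute error of the recovered ratio is below 3%.

The `analysis/` directory holds numbered drivers that run the full
workflow and write tables under `results/`:

```sh
Rscript analysis/01_simulate_fluorescence.R   # two-genotype decay series
Rscript analysis/02_fit_quenching.R           # fits + porosity ratio
Rscript analysis/03_pore_analysis.R           # pore distributions + phi
Rscript analysis/04_xlink_analysis.R          # per-system cross-link table
```

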