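# mdmri

Multidimensional diffusion–relaxation MRI (MD-MRI) resolves sub-voxel
tissue heterogeneity by acquiring brain volumes under many combinations of
tensor-valued, frequency-dependent diffusion encoding b(ω), echo time and
repetition time, and inverting each voxel's signal into a nonparametric
distribution of diffusion–relaxation components. `mdmri` implements that
analysis chain for R, together with the test–retest reliability and
repeatability statistics needed to judge whether the derived parameter
maps are stable enough for clinical research use, and a synthetic
test–retest brain-phantom cohort for end-to-end validation.

It is aimed at quantitative-MRI methods researchers who want a tested,
scriptable implementation of the estimator and its statistics rather than
a scanner-specific toolchain.

## The model

Each voxel's signal is a weighted sum of discrete components

S(b(ω), TE, TR) = Σ_c f_c · exp(−∫ b(ω) : D_c(ω) dω) · (1 − e^(−TR·R1_c)) · e^(−TE·R2_c)

where each component carries an axisymmetric diffusion tensor whose axial
and radial diffusivities follow Lorentzian frequency transitions

D(ω) = D(0) + (D0 − D(0)) · ω² / (ω² + Γ²)

between the zero-frequency values (D∥, D⊥) and a high-frequency isotropic
diffusivity D0 — the spectral signature of restricted diffusion — plus
longitudinal and transverse relaxation rates R1, R2. The per-voxel
distribution over (D∥, D⊥, θ, φ, D0, Γ∥, Γ⊥, R1, R2) is estimated by
Monte Carlo inversion: non-negative least squares over randomly sampled
component dictionaries with quasi-genetic refinement, bootstrap
replication (300 solutions of up to 10 weighted components), and median
aggregation of the derived statistics over bootstraps. Derived maps
include the means E[Diso], E[DΔ²], E[R1], E[R2], their frequency
dependence Δω/2π[x] over the 6.6–21 Hz window, spectral-bin signal
fractions fbin1–3 (≈ white matter, gray matter, CSF) from the
(Diso, DΔ²) plane, and bin-resolved relaxation means. Reliability and
repeatability are quantified with ICC(A,1), the within-subject
coefficient of variation CVws, and Bland–Altman analysis, with mask-aware
Gaussian smoothing for voxel-wise comparisons.

## Worked example

Build the default 139-measurement protocol, synthesize the signal of a
white-matter-like voxel, invert it, and reduce to map statistics:

```r
library(mdmri)

prot <- makeDefaultProtocol(seed = 1)
prot
#> AcquisitionProtocol: 139 measurements (9 with b = 0)
#>   b: 0.1-3 ms/um^2; b_delta in {-0.5, 0, 1}
#>   centroid frequencies: 6.6-21 Hz
#>   TE in {40, 63, 83, 150} ms; TR in {0.62, 1.75, 3.5, 5, 7, 7.6} s

wm  <- tissueArchetypes()$wm              # ground-truth WM-like voxel
sig <- signalModel(wm, prot)              # noiseless forward signal
res <- invertVoxel(sig, prot, inversionConfig(n_bootstrap = 16, seed = 2))
round(voxelStatistics(res)[c("e_diso", "e_ddelta_sq", "e_r1", "e_r2",
                             "d_diso", "d_ddelta_sq",
                             "fbin1", "fbin2", "fbin3")], 3)
#>      e_diso e_ddelta_sq        e_r1        e_r2      d_diso d_ddelta_sq
#>       0.766       0.290       0.587      14.603       0.273      -0.194
#>       fbin1       fbin2       fbin3
#>       0.680       0.320       0.000
```

The voxel is recovered as a low-diffusivity (E[Diso] ≈ 0.77 μm²/ms),
anisotropic (E[DΔ²] ≈ 0.29) environment with white-matter-like relaxation
(E[R1] ≈ 0.59 s⁻¹, E[R2] ≈ 14.6 s⁻¹); the positive Δω/2π E[Diso] and
negative Δω/2π E[DΔ²] are the restriction signature built into the
archetype, and about two thirds of the signal falls in the anisotropic
(WM-like) spectral bin.

Test–retest statistics on a subjects × sessions table:

```r
icc <- iccA1(cbind(c(1, 2, 3), c(2, 3, 4)))
icc$icc; icc$category
#> [1] 0.6666667
#> [1] "moderate"
cvWS(cbind(c(1, 2, 3), c(2, 3, 4)))
#> [1] 0.2828427
```

`runPipeline(runConfig(...))` chains the full study: cohort simulation →
per-voxel inversion → parameter maps → voxel-wise and ROI reliability →
NIfTI/TSV/JSON report bundle, resumable per stage.

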