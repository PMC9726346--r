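# alpsim

Simulation and analysis of the **DTI-ALPS index** — *diffusion tensor image
analysis along the perivascular space* — an MRI marker of glymphatic
(perivascular fluid-transport) function used in clinical neuroimaging
studies that compare patient groups and correlate the index with age.

At the level of the lateral ventricle body, perivascular spaces run
right-left (x), perpendicular to the projection fibers (z) and association
fibers (y). Freer perivascular water raises x-axis diffusivity in both
fiber regions, and the index

```
ALPS = mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)
```

is computed from 5-mm spherical ROIs on the diffusion-tensor axis
diffusivity maps of each hemisphere.

Clinical DTI-ALPS studies rarely deposit raw images, so this package
validates the measurement chain by **parameter recovery on digital
phantoms**: it simulates diffusion-weighted cohorts whose per-subject ALPS,
age, and demographic structure are drawn from published group
distributions, then the full pipeline — single-tensor signal simulation
with Rician noise (b = 0/600 s/mm², 30 directions, 8 b0), log-linear
tensor fitting with one weighted refinement pass, centroid-placed spherical
ROIs, bilateral ALPS extraction, Mann-Whitney/Pearson statistics with a
Bonferroni threshold of .017 — must hand back the generating parameters.

See `vignettes/alps-methods.Rmd` for the model, assumptions, parameter
choices and known limitations.

## Worked example

Simulate the default two-group study (30 ASD children, 25 controls, SNR
40), image every subject on the 64 × 64 × 16 phantom grid, and run the
statistics — about half a minute on one core:

```r
library(alpsim)

cfg    <- default_run_config(seed = 42L)
cohort <- sample_cohort(cfg$cohort, seed = 42)        # known ground truth
est    <- estimate_cohort_alps(cohort, snr = 40, seed = 42)

compare_groups(est)[, c("variable", "mean_1", "sd_1", "mean_2", "sd_2", "p")]
#>       variable mean_1   sd_1 mean_2   sd_2        p
#>      alps_left   1.02  0.126   1.26  0.228 1.57e-05
#>     alps_right   1.06  0.120   1.27  0.235 4.82e-04
#>     age_months  48.90 19.528  41.79 11.661 3.25e-02
#>       ga_weeks  39.65  1.021  39.46  0.967 5.48e-01
#>            sex  25.00 83.333  16.00 64.000 1.28e-01

age_correlations(est)
#>     group hemisphere     r r_squared        p  n
#> 1     ASD       left 0.697     0.486 1.84e-05 30
#> 2     ASD      right 0.769     0.592 6.79e-07 30
#> 3 control       left 0.677     0.459 2.00e-04 25
#> 4 control      right 0.714     0.509 6.19e-05 25
```

The recovered group means (1.02 ± 0.13 vs 1.26 ± 0.23 left, 1.06 ± 0.12 vs
1.27 ± 0.23 right) reproduce the generating distributions (1.02 ± 0.12 vs
1.27 ± 0.25 and 1.03 ± 0.12 vs 1.32 ± 0.20) within sampling error of a
30/25-subject draw; both group differences are significant below the .017
Bonferroni threshold while the matched demographics are not, and the
age-ALPS correlations recover the generating R² (0.47/0.44 ASD, 0.30/0.37
control) up to small-sample variability. `report_stats()` renders these as
publication-style CSV tables ("1.02 ± 0.13", "<.001") plus a raw-numbers
JSON, and `plot_age_alps()` draws the per-group scatter panels.

Lower-level pieces are exposed individually:

```r
tt <- alps_to_tensors(1.5)     # region tensors realising ALPS = 1.5
analytic_alps(tt)              #> 1.5 (exact inversion)
phantom <- build_phantom(default_layout(), left = tt, right = tt)
dwi     <- simulate_dwi(phantom, build_default_scheme(), snr = 40, seed = 1)
field   <- fit_tensor(dwi, mask = phantom$s0 > 0)
subject_alps(field, phantom$labels)$row
```

A thin CLI over the same functions lives at `inst/cli/alps.R`
(`run` / `simulate` / `fit` / `index` / `stats` subcommands; the stages
communicate only through their declared files). Volumes are written as
NIfTI-1 with FSL-style `.bval`/`.bvec` gradient tables.

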