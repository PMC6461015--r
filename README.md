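# pmkin — principal movement analysis of whole-body kinematics

Human movements are the direct output of the neuromuscular system, but most
motion analyses reduce them to a handful of pre-selected joint angles and
discard the segment interactions that make movement coordination
interesting. `pmkin` takes the opposite, data-driven route for researchers
in movement science, postural control and sports biomechanics: it treats
every motion-capture frame (all `N = 3n` marker coordinates) as a point in
*posture space* and extracts, by PCA of the pooled covariance of a
multi-trial cohort, the orthogonal whole-body movement patterns — principal
movements `PM_k` — that dominate the data.

For a cohort of preprocessed, vertically concatenated trials `D_all`:

- eigenvectors `PC_k` of `cov(D_all)` (computed by SVD) define the movement
  patterns; eigenvalues `EV_k` — reported as percentages `rEV_k` — give the
  pooled variance each explains;
- scores `PP_k(t) = D PC_k` are each trial's principal positions, and their
  first/second derivatives `PV_k`, `PA_k` the principal velocities and
  accelerations;
- per trial, `rVAR_k` / `rSTD_k` (a trial's variance / SD share along
  `PC_k`), cumulative versions, and the residual variance
  `RV_m = 100 − CUM_rVAR_m` quantify the *movement structure*;
- on `PA_k`, the zero-crossing count `N_k` (how often the net control
  action reverses) and the inter-crossing variability `σ_k` quantify
  *movement control*.

Supporting machinery: wide-CSV marker I/O; per-trial preprocessing
(PCA-based gap filling, left/right mirroring, spherical/cylindrical
coordinate transforms with azimuth unwrapping, zero-phase Butterworth
low-pass filtering, center-of-mass re-centering, anthropometric mass
weighting, MED/height/range normalization); validity diagnostics
(leave-one-out eigenvector stability angles, Welch PSD, filter-cutoff
sweeps); amplified single-PM marker reconstruction for animation; and a
seeded synthetic-cohort generator with planted orthonormal modes used as
ground truth throughout the tests.

## Worked example

Five synthetic 10-s trials built from three planted orthonormal modes with
amplitude variances 10:3:1 and 1 % measurement noise:

```r
library(pmkin)

lay   <- humanoid_layout()                       # 28-marker symmetric scaffold
modes <- random_orthonormal_modes(length(lay$posture), 3, seed = 42)
model <- planted_model(
  lay$posture, modes,
  list(amp_sinusoid(0.5, sqrt(20)),              # variance 10
       amp_sinusoid(1.3, sqrt(6)),               # variance 3
       amp_sinusoid(2.7, sqrt(2))),              # variance 1
  noise_sd = 0.01, sampling_rate = 100, duration = 10, seed = 7,
  marker_labels = lay$labels)
trials <- lapply(1:5, function(i) generate_trial(model, "S1", paste0("T", i)))

res <- pm_analyze(trials,
                  preprocess_config(normalization = "MED", filter_cutoff = 7),
                  m = 3)
res$space
#> posture_space: 84 components over N=84 columns
#>   rEV: 71.43% 21.42% 7.13% 0.00% 0.00% ...
```

The three planted modes surface as the first three components with
`rEV ≈ 10/14, 3/14, 1/14` — exactly the 10:3:1 variance split — and each
recovered `PC_k` is within 0.08° of its planted mode. Per-trial variables:

```r
subset(res$variables, variable %in% c("rVAR", "N", "sigma") &
                      trial_id == "T1" & component <= 3)
#>    component variable    value
#>            1     rVAR 71.44       # trial T1's movement structure (%)
#>            2     rVAR 21.42
#>            3     rVAR  7.13
#>            1        N 13          # control reversals in 10 s
#>            2        N 26
#>            3        N 54
#>            1    sigma  0.408      # inter-reversal variability (s)
#>            2    sigma  0.00219
#>            3    sigma  0.00137
```

`rVAR` sums to 100 per trial; faster, smaller components are corrected more
often (`N_k` grows with mode frequency). Basis stability by leave-one-out:

```r
prep <- lapply(trials, preprocess_trial,
               config = preprocess_config(normalization = "MED"))
loocv_angles(prep, K = 3)$summary
#>   component max_angle mean_angle
#> 1         1    0.0129     0.0118
#> 2         2    0.0232     0.0216
#> 3         3    0.0377     0.0364
```

All angles far below a degree: every component is cohort-stable, none is an
artifact of a single trial.

A command-line front end covering `synth`, `fit`, `loocv`, `psd` and
`sweep` ships in `inst/cli/pmkin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pmkin.R", package="pmkin"))')" \
  synth --out data --trials 5 --seed 1
```

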