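---
title: "Principal movement analysis: model, preprocessing and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal movement analysis: model, preprocessing and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmkin)
```

## The model

A motion-capture trial of $n$ markers is a matrix $D$ with $T$ frames as
rows and $N = 3n$ columns, the $(x,y,z)$ time-series $s_i(t)$ of each
marker. A frame is a point in *posture space* $\mathbb{R}^N$. Principal
movement analysis asks for the one-dimensional, correlated whole-body
displacement patterns that dominate a cohort of trials: the eigenvectors
$PC_k$ of the pooled covariance matrix of all (preprocessed, vertically
concatenated) trials, computed here by SVD. Each $PC_k$ defines a principal
movement $PM_k$; its eigenvalue $EV_k$ (sample covariance, divisor
$\mathrm{rows}-1$) is the pooled variance that pattern explains, reported as
relative eigenvalues $rEV_k = EV_k / \sum_j EV_j \cdot 100$.

Projecting a trial onto the basis gives score time-series, the *principal
positions* $PP_k(t) = D\,PC_k$: how strongly pattern $k$ is expressed at
each frame. Differentiating once and twice (central differences scaled by
the sampling rate, one-sided at the endpoints) gives principal velocities
$PV_k$ and accelerations $PA_k$. $PA_k$ is read as the net accelerating
action — gravity plus muscle forces — on that movement component, which is
what makes it a window on sensorimotor control.

Per trial, the package computes the movement-structure family

* $VAR_k = \mathrm{var}(PP_k)$, $totVAR = \sum_k VAR_k$,
  $rVAR_k = VAR_k / totVAR \cdot 100$ — the trial's composition across
  components (the per-trial analogue of $rEV_k$);
* $rSTD_k$, the same with standard deviations, which scales like the
  movement itself;
* cumulative sums $CUM\_rVAR_k$, $CUM\_rSTD_k$, and the residual variance
  $RV_m = 100 - CUM\_rVAR_m$ left unexplained by the first $m$ components
  (default $m = 3$);

and the movement-control pair on $PA_k$:

* $N_k$, the number of strict sign changes — each a reversal of the
  direction in which the control system drives the component;
* $\sigma_k$, the sample standard deviation (seconds) of the intervals
  between successive zero-crossings.

## Preprocessing and its fixed order

Pooling trials of different subjects only makes sense after removing mean
positioning and anthropometric scale. `preprocess_trial()` applies the
enabled steps in one fixed, logged order:

1. **Gap filling** — iterated low-rank SVD reconstruction (initialize gaps
   by linear interpolation, rebuild with the leading components, overwrite
   only the missing cells; default rank explains 99 % of the interpolated
   matrix variance, tolerance $10^{-6}$, 100 iterations).
2. **Mirroring** — negate one axis and swap left/right marker columns, so
   e.g. left-foot-front and right-foot-front stances share one posture
   space.
3. **Center-of-mass re-centering** — subtract the mass-weighted mean marker
   position per frame, so whole-body displacement is not itself a component.
4. **Coordinate transform** — per marker, $(x,y,z)\to(r,\varphi,\theta)$
   (spherical: azimuth from $+x$ in the $x$–$y$ plane, elevation from that
   plane) or $(\rho,\varphi,z)$ (cylindrical), azimuth unwrapped along time
   so the PCA never sees $2\pi$ branch cuts. Rotational movements become
   nearly linear in these coordinates and need fewer components.
5. **Low-pass filtering** — zero-phase (forward–backward) Butterworth,
   default order 4 per pass, applied column-wise. Zero phase matters because
   any lag would desynchronize markers and masquerade as coordination.
6. **Center, weight, normalize** — subtract column means; multiply column
   $i$ by its segment-mass fraction $w_i$ (linear, as the weighting matrix
   is written: weights multiply coordinates, so variances scale with
   $w_i^2$); divide the whole matrix by a trial normalization factor
   $d_{norm}$.

The narrative order of a typical analysis lists filtering after
normalization; for a linear zero-phase filter the two commute with
centering, and applying the geometric and signal-processing steps before
the statistical ones keeps every step acting on the representation it is
defined on. This ordering is this package's documented choice.

`d_{norm}` options: **MED**, the mean over frames of the Euclidean norm of
the centered (and weighted) posture row — after it, every trial contributes
mean posture-vector norm 1, so all trials weigh equally in the pooled
covariance; **height**, the subject's stature, a trial-independent
anthropometric scale; **range**, the largest per-column peak-to-peak
excursion along a chosen axis (exploratory). MED is computed on the same
matrix it divides, i.e. after weighting; the alternative (before weighting)
is not offered. Angle and radial columns produced by a coordinate transform
have different units but are treated identically by weighting and MED — no
unit-harmonization rule exists in the literature, so none is invented here.

Markers missing from a mass specification get weight 0 with a warning
rather than a silently assumed fraction. Units (mm/m) are metadata only;
normalization removes scale, so no automatic conversion is attempted.

## Validity diagnostics

* **Leave-one-out stability** (`loocv_angles`): refit the basis without each
  trial in turn and measure, per component, the angle between the original
  $PC_k$ and the refitted $PC'_k$ (absolute inner product, so sign-invariant
  and in $[0, 90]°$). Small angles justify interpreting a component
  cohort-wide; a component that swings when one trial is dropped describes
  that trial, not the group. Components are matched by rank order $k$ by
  default — the plainest reading of "the newly obtained $PC'_k$" — with an
  optional maximum-$|{\cdot}|$ best-match mode for near-degenerate spectra.
  No hard inclusion threshold is asserted (the literature cites but does not
  fix one); raw angles are always reported, with max and mean summaries
  across left-out trials since aggregation is equally unspecified.
* **Welch PSD** (`welch_psd`): averaged modified periodograms (default Hann
  window, 256-sample or $T/4$ segments, 50 % overlap, per-segment mean
  detrend) to check where signal power actually lives before choosing a
  cutoff.
* **Cutoff sweep** (`cutoff_sweep`): rerun the whole pipeline over a vector
  of cutoffs, writing per-cutoff folders and a combined variable-vs-cutoff
  table. $N_k$ and $\sigma_k$ are doubly differentiated and therefore
  sensitive to filtering; conclusions should be stable across plausible
  cutoffs.

## The synthetic world

No reference dataset ships with the package, so tests run against a seeded
generator (`planted_model`, `generate_trial`) whose ground truth is known:
marker rows are $b + \sum_k a_k(t)\,v_k^\top + \varepsilon(t)$ with a
28-marker bilaterally symmetric humanoid base posture $b$ (mm units,
left/right label pairs and an editable de Leva-style segment-mass table),
mutually orthonormal displacement modes $v_k$, sinusoidal or filtered-noise
amplitudes $a_k(t)$, and i.i.d. Gaussian noise.

The default test world: 5 trials of 10 s at 100 Hz, 3 modes with amplitude
variances 10:3:1 (sinusoids at 0.5, 1.3 and 2.7 Hz — whole cycle counts
over the trial, so sample variances are exact and the amplitude series are
empirically orthogonal), noise SD 1 % of the smallest mode's RMS. Those
values state the recovery problem the tests pose; they were chosen once as
a plausible quiet-stance-like regime (slow dominant sway, an order of
magnitude between largest and smallest retained mode, sub-millimetre
marker noise) and are not tuned. Amplitudes are zero-mean by construction
so per-trial centering is a near-no-op and recovery algebra stays clean.

What a green suite establishes: the algebra (eigendecomposition,
projection, variable identities, transform round-trips, filter gain/phase)
and the recovery of *planted linear* modes under isotropic noise. What it
does not establish: behavior on real data with soft-tissue artifact,
marker swaps, non-stationary amplitudes, or genuinely non-linear movement
strategies, which no synthetic fixture of this kind emulates.

## Numerical choices

* Covariance divisor is $\mathrm{rows}-1$ everywhere ($rEV$ and $rVAR$ are
  divisor-invariant, $EV$ is not); `movement_structure` uses the same
  convention so the single-trial identity $rVAR_k \equiv rEV_k$ holds
  exactly.
* $rEV_k$ percentages are always relative to the **full** spectrum, even
  when only $K$ components are retained; $rVAR_k$ is relative to the
  retained subspace and documented as such when $K < N$.
* Eigenvector sign: the largest-magnitude coefficient of each $PC_k$ is
  made positive (SVD signs are otherwise arbitrary; the LOOCV angle is
  sign-invariant regardless). Exact eigenvalue ties are ordered
  lexicographically by component vector.
* A residual grand mean is removed (and stored) before the SVD even though
  per-trial centering makes it $\approx 0$; projection subtracts the same
  stored vector so pooled and per-trial scores agree to machine precision.
* Zero samples in $PA_k$: a run of exact zeros counts as one crossing only
  when the flanking signs differ — a touch-and-return is not a change of
  direction. Crossing times are linearly interpolated between the
  bracketing non-zero samples (configurable to integer frames); $\sigma_k$
  uses the $n-1$ standard deviation and needs at least 3 crossings.
* One PCA per cohort. Per-trial bases are obtained by running the tool on a
  single trial; comparing score time-series across trials requires the
  shared basis.
* Degenerate inputs fail loudly: motionless trials under MED, zero radii at
  a transform origin, fully-missing columns in gap filling, cutoffs at or
  above Nyquist.

## Worked example

```{r}
lay <- humanoid_layout()
modes <- random_orthonormal_modes(length(lay$posture), 3, seed = 42)
model <- planted_model(
  lay$posture, modes,
  list(amp_sinusoid(0.5, sqrt(20)), amp_sinusoid(1.3, sqrt(6)),
       amp_sinusoid(2.7, sqrt(2))),
  noise_sd = 0.01, sampling_rate = 100, duration = 10, seed = 7,
  marker_labels = lay$labels)
trials <- lapply(1:5, function(i) generate_trial(model, "S1", paste0("T", i)))

res <- pm_analyze(trials,
                  preprocess_config(normalization = "MED", filter_cutoff = 7),
                  m = 3)
res$space
head(subset(res$variables, variable == "rVAR" & trial_id == "T1"))

prep <- lapply(trials, preprocess_trial,
               config = preprocess_config(normalization = "MED"))
loocv_angles(prep, K = 3)$summary
```

## Limitations

Principal movements are linear approximations; rotations and other
non-linear strategies need several components unless a coordinate
transform linearizes them first. The C3D binary format is not read —
trials arrive as wide delimited text. Excel export, video rendering,
moving (body-fixed) coordinate frames beyond center-of-mass re-centering,
and center-of-pressure linkage are out of scope.
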