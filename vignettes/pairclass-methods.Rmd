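---
title: "Paired-condition classification of resting-state fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-condition classification of resting-state fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairclass)
```

## The problem and the model

Paired resting-state designs measure the same subjects under two conditions
— here eyes closed (EC) and eyes open (EO). Univariate analysis handles the
pairing with paired t-tests; most multivariate (classifier-based) analyses
have not, treating the conditions as independent classes. The difficulty is
between-subject variability: the spatial pattern and overall level of BOLD
fluctuation amplitude differ between people by far more than they differ
between conditions within a person, so a classifier on raw condition maps
("UNPAIR") spends its capacity on subject identity rather than condition.

The PAIR scheme classifies *signed within-subject difference maps* instead.
For m subjects with per-condition feature vectors `C_i` (EC) and `O_i`
(EO), draw a balanced random sign vector `a` with half −1 and half +1 (for
odd m the smaller half is −1): subject i contributes the sample
`a_i (O_i − C_i)` with label `y_i = a_i`, so label −1 marks an EC−EO
difference and +1 an EO−EC difference. Subject baselines cancel inside
every sample, and the two classes are exact mirror images of each other —
a geometry a linear classifier handles well. The sign assignment is an
arbitrary labeling; the package exposes its seed, and a global sign flip
provably changes no accuracy (tested), though different *partitions* are
not theoretically guaranteed to be equivalent — the seed is recorded for
exactly this reason.

### ALFF

The per-voxel metric is the amplitude of low-frequency fluctuation: detrend
the time series linearly, take the FFT, square-root the power spectrum, and
average over a band. The amplitude convention is `(2/N)|X_k|` at interior
bins (`(1/N)` at DC and Nyquist), so a pure sinusoid of amplitude A at an
exact bin reads A — any global scale cancels after normalization, and this
convention makes test oracles exact. Bands are closed intervals; the named
slow bands share touching edges (0.027, 0.073, 0.198 Hz), so adjacent bands
can share at most one bin, and slow-2's upper edge (0.25 Hz) equals the
Nyquist frequency at TR = 2 s and is included. A band containing the DC bin
is rejected. No taper, window or zero padding is applied. Maps are
normalized to unit mean over the analysis mask (mALFF); the same
whole-brain-plus-eyeball mask is used for analysis and normalization (the
alternative — excluding the eyeballs from the normalizing mean — changes
all values by a common factor only).

### Feature selection

Voxel-wise paired t-statistics (equivalently, one-sample t of the
differences; zero-variance voxels are set to t = 0 with a logged count) are
thresholded two-sidedly at voxel p (default 0.01) and corrected by cluster
extent. Supra-threshold voxels of each sign are labeled separately by
26-connectivity connected components — sign separation overrides
connectivity, since positive and negative effects are distinct findings —
and components below the minimum extent are dropped. The default extent,
47 voxels, is the 1269 mm³ criterion on a 3 mm grid, read as
extent ≥ 47 (the printed mm³/voxel equivalence only holds if 47-voxel
clusters survive). Alternatively `monteCarloExtentThreshold()` calibrates
the extent in the AlphaSim style: simulate Gaussian noise on the mask grid,
smooth at an assumed FWHM (default 6 mm, the typical smoothing kernel —
supplied, not estimated from residuals), rescale to unit variance in the
mask, threshold at the same two-sided p, and take the smallest extent whose
exceedance probability is below alpha. Connectivity, smoothness and
iteration count are all explicit parameters because published descriptions
of this correction rarely pin them down.

Per cluster the peak (max |t|, ties to the lowest linear voxel index) and
its 5 mm spherical ROI define three feature sets: peak ALFF, ROI-mean ALFF,
and all ROI voxels (19 per interior ROI on a 3 mm grid; ROIs truncated by
the mask are kept, with a warning, rather than silently changing the
feature dimensionality). Clusters are ordered by descending extent, then
descending |peak t| — a stable rule, since cluster indices label reported
regions. Feature locations are fixed once per dataset from the full-sample
t-map; selecting features from the same data that are then classified is a
form of circular analysis, which is why cross-dataset validation (frozen
locations *and* frozen classifier applied to an independent dataset) is the
meaningful test, and within-dataset LOOCV numbers should be read
accordingly.

### Classification

The classifier is the linear soft-margin SVM with *squared* hinge loss and
an unregularized bias,

$$\min_{W,b,\xi}\ \tfrac12\|W\|_2^2 + \tfrac{C}{2}\sum_i \xi_i^2
\quad\text{s.t.}\quad y_i(W^\top X_i + b) + \xi_i \ge 1,$$

with C = 1 and no feature standardization (mALFF values are already on a
common scale). The unconstrained equivalent is smooth and convex, so it is
solved by BFGS with the analytic gradient to a relative tolerance of 1e-12;
tests verify the objective against an independent dual quadratic program
(solved with `quadprog`) to 1e-5. Decision ties (score exactly 0) predict
+1. Leave-one-out cross-validation holds out one *sample* per fold in
sample order, deterministically; under UNPAIR this leaves the held-out
subject's other-condition row in training — the standard protocol, whose
subject-level leakage is why `loocvBySubject()` is also provided.

A useful symmetry, tested and worth recording because it is easy to get
backwards: negating every row of X *and* every label maps the optimal
separating function f(x) = Wx + b to −f(−x), i.e. W is unchanged and b
flips sign (negating X alone mirrors W). Accuracies are invariant either
way.

## The synthetic world

`generatePairedDataset()` builds paired 4D datasets in which every
downstream claim can be checked against ground truth. Defaults state the
emulated world: a 24³ grid of 3 mm voxels, TR 2 s, 240 time points (10 to
be discarded downstream), m = 20 subjects — a typical single-site paired
resting-state group — 6 mm smoothing, and three planted regions echoing the
replicated EC/EO findings: a sensorimotor-like blob with higher EC
amplitude and occipital-like and eyeball-like regions with higher EO
amplitude (the eyeball effect in a high band, as blinking is fast). Head
geometry is a coarse ellipsoid plus two anterior-inferior spheres; topology
only, no anatomical realism.

Per subject and voxel, each condition's series is

> gain × (broadband Gaussian noise + in-band random-phase sinusoid mixture)
> \+ linear drift,

spatially smoothed per time point. Two choices matter:

* **Condition effects are amplitude modulations** of the band-limited
  component — a planted region multiplies its band's per-bin amplitude by
  (1 + effect) in the favored condition — never mean shifts, which ALFF
  cannot see (detrending removes them).
* **The subject baseline is multiplicative and spatially smooth.** A purely
  global lognormal gain would be cancelled *exactly* by mALFF normalization
  for both schemes, erasing the nuisance PAIR exists to suppress. The
  generator therefore draws, per subject, a scalar lognormal gain *and* a
  smooth lognormal spatial field (log-SD `subjectSd`, default 0.3), shared
  between that subject's EC and EO runs along with the drift; phases and
  noise are condition-specific. After normalization the field survives as a
  smooth spatial residue that inflates UNPAIR's within-class variance but
  cancels in within-subject differences — which is precisely the measured
  PAIR advantage, so the generator makes the method's premise explicit
  rather than smuggling it in.

`makeSitePair()` yields two datasets sharing region definitions but with
independent subjects and lognormal site-level shifts of signal and noise
amplitude (log-SD 0.2), mimicking two scanners.

What a green test on this world does *not* establish: robustness to
hemodynamic variability, physiological noise, head motion, registration
error, or anatomically realistic effect geometry — none of which are
simulated. The generator validates the *statistics* of the pipeline, not
its behavior on any particular scanner's artifacts.

## Numerical and scale choices

* NIfTI-1 I/O is implemented directly (no NIfTI reader exists in the
  package's dependency environment): maps are written as float64, so
  write/read round-trips are bitwise; masks as uint8. The sform affine is
  authoritative; qform is used as fallback when reading third-party files.
  Output is cross-checked against the `nibabel` reference reader in tests.
* Sphere membership (eyeball masks, ROIs) uses voxel-center distance with
  an inclusive boundary — this reproduces the canonical 19-voxel count for
  a 5 mm ROI on a 3 mm grid. The eyeball mask is generated analytically
  from the published centers (±36, 60, −40) and 20 mm radius rather than
  via an atlas tool; the unusually inferior z is used verbatim.
* Gaussian smoothing is separable with zero padding, kernel truncated at
  3.5 sigma. Monte-Carlo null volumes are rescaled by the masked SD before
  thresholding.
* Test-suite simulations run the generator at reduced problem size (16³
  grid, shorter series) to fit a desktop CPU budget; statistical parameters
  of each tested property (m, alpha, effect sizes in the stated units, run
  counts, tolerances) are used exactly as stated. At those settings the
  cluster correction measures conservative (no false-positive dataset in
  200 null runs at alpha 0.05), as expected when the map smoothness is at
  or below the assumed FWHM.
* Accuracies are stored as exact fractions and formatted to two decimals
  only for display.

## Known limitations

* The Monte-Carlo correction assumes stationary Gaussian smoothness at a
  supplied FWHM; residual-smoothness estimation is deliberately out of
  scope.
* LOOCV under a true null is slightly *pessimistic* (each held-out sample
  leaves its class as the training minority); tests assert the absence of
  optimistic bias rather than exact 50% chance level.
* `referenceRegionTable()` transcribes a published table verbatim. The
  correlation between its weight and t columns computes to −0.7170 (full)
  and −0.8065 (reduced), not the correlations published alongside it
  (−0.7242 / −0.7772); the table repeats one weight value for two distinct
  regions, suggesting a transcription slip in the source, whose printed r
  presumably used unrounded weights. The package reports what the printed
  numbers give.
* Preprocessing (slice timing, motion correction, normalization, smoothing
  of real data) is out of scope; the package consumes preprocessed,
  MNI-registered volumes.
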