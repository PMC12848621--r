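---
title: "Mueller-matrix polarimetry of tissue: models and methods in mmpolar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mueller-matrix polarimetry of tissue: models and methods in mmpolar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpolar)
```

## The measurement model

A linear optical sample maps the Stokes vector of incoming light,
$S_i = (s_0, s_1, s_2, s_3)^T$, to an outgoing one through its 4x4 Mueller
matrix, $S_o = M S_i$.  The components describe total intensity,
horizontal/vertical linear, +/-45 degree linear, and circular polarization.
A wide-field polarimeter probes $M$ by preparing six fully polarized input
states — H, V, P (+45), M (-45), R (right circular), L (left circular) —
through a polarization state generator, and analyzing the transmitted beam
through the same six states, producing 36 co-registered intensity images
$I_{GA}$ (first index: generator; second: analyzer).

Each Mueller element is a signed sum of exactly four of these images.
Writing the four state combinations $1: H+V$, $2: H-V$, $3: P-M$, $4: R-L$,
element $m_{ij}$ combines the generator pair of column $j$ with the analyzer
pair of row $i$; for example

$$m_{11} = HH + HV + VH + VV, \qquad
  m_{12} = HH + HV - VH - VV, \qquad
  m_{44} = RR - RL - LR + LL.$$

With ideal states this reconstruction returns $2M$ per pixel
(`reconstruct_mueller()`); the scale is removed by per-pixel $m_{11}$
normalization (`normalize_by_m11()`), which also masks pixels whose
unpolarized transmission falls below a configurable floor (default 1% of the
image maximum) so that noise-dominated divisions never reach later stages.

Two conventions are fixed package-wide because the measurement scheme does
not pin them down: right circular light carries $s_3 = +1$, and a
quarter-wave retarder at 45 degrees maps H to R.  Any consistent alternative
yields identical reconstructions; the choice only relabels signs in
intermediate algebra, and the forward simulator and the tests share it.
Only the 36-measurement scheme is implemented; reduced schemes with four
input states exist but use different, underdetermined element formulas.

## Polar decomposition

Each normalized pixel matrix is factorized in the canonical order
$M = M_\Delta M_R M_D$ (diattenuator applied first, depolarizer last) by
`decompose_mueller()`:

* diattenuation $D = \sqrt{m_{12}^2 + m_{13}^2 + m_{14}^2}$ from the first
  row, and the diattenuator factor
  $m_D = \sqrt{1-D^2}\,I + (1-\sqrt{1-D^2})\,\hat d \hat d^T$;
* $M' = M M_D^{-1}$, whose 3x3 block $m'$ holds retardance and
  depolarization; the depolarizer block is the signed symmetric square root
  $m_\Delta = \pm(m' m'^T)^{1/2}$ (sign of $\det m'$), giving the
  depolarization power $\Delta = 1 - |\mathrm{tr}\, m_\Delta| / 3 \in [0,1]$;
* the retarder block $m_R = m_\Delta^{-1} m'$, giving the total retardance
  $R = \arccos\!\big((\mathrm{tr}\, m_R + 1)/2 - 1\big) \in [0, \pi]$,
  reported in radians;
* polarizance $P = \sqrt{m_{21}^2 + m_{31}^2 + m_{41}^2}$ from the first
  column.

Numerical guards: eigenvalues of $m' m'^T$ are clamped at zero before the
square root (noise can push them slightly negative; occurrences are counted
in the processing log), and a polarizer-like pixel with $D \ge 1 - 10^{-6}$
takes a regularized inverse of $M_D$ (singular values floored at the same
epsilon) so that image-scale runs never crash; such pixels are flagged
`singular_diattenuator` and report $D = P = 1$.  `decompose_image()` runs
the identical algorithm in compiled code over all masked-in pixels; the two
paths are cross-checked against each other and against forward-composed
factors in the test suite.  The alternative scalar conventions in use
elsewhere (normalized retardance, depolarization indices built from
$\mathrm{tr}(M^T M)$) are deliberately not mixed in: one trace-based
$\Delta$ and radian-valued $R$ are used throughout.

## Moment statistics and age trends

Spatial distributions of a parameter map over the tissue region are
summarized by their first four moments in population ($1/N$) form:

$$\mu = \tfrac1N \sum x_i,\quad
  \sigma = \sqrt{\tfrac1N \sum (x_i-\mu)^2},\quad
  \mathrm{skew} = \frac{\sum (x_i-\mu)^3}{N\sigma^3},\quad
  \mathrm{kurt} = \frac{\sum (x_i-\mu)^4}{N\sigma^4}.$$

Kurtosis is non-excess (a Gaussian map gives 3).  No sample-size correction
is applied: with $10^3$–$10^5$ pixels per region the $N/(N-1)$ factors are
irrelevant, and the plain forms keep the statistics exactly reproducible.
The formulas are defined for any $N \ge 2$ with $\sigma > 0$; zero-spread
input yields `NA` rather than an arbitrary number.

Samples are grouped by age; group means of each moment are reported with the
across-sample standard deviation as the error bar.  Trends against age use
ordinary least squares for mean and standard deviation and a three-parameter
exponential $y = \alpha e^{\beta x} + c$ for skewness and kurtosis, fitted
by Levenberg–Marquardt from a log-linear starting point tried in both
orientations.  The offset term is required because skewness can be negative,
which a two-parameter exponential cannot cross.  Note the sign ambiguity of
this parameterization: an increasing saturating trend fits equally well with
$\alpha < 0, \beta < 0$; the fitted *rate* $\alpha\beta e^{\beta x}$, not
$\beta$ alone, carries the direction of change.  Fits are unweighted and by
default computed on the seven group means; fitting on all individual samples
is available (`fit_on = "samples"`) since either choice is defensible and
they agree in expectation.  The age axis is used in days, uncentered —
this affects $\alpha$ and $c$ but not the sign of $\beta$ or of the rate.

## The synthetic phantom

Measured brain-tissue images equivalent to the published ones are not
publicly available, so the package ships a synthetic generator that serves
two purposes: exact ground truth for every pipeline stage, and a cohort
emulator for the statistical layer.  It is an *effective per-pixel Mueller
model*, not photon-transport Monte Carlo: every pixel carries

$$M(x) = \mathrm{diag}(1, a_1, a_2, c)\; M_R(\delta, \theta)\; M_D(D),$$

i.e. exactly the canonical decomposition form, so the true $D$, $R$,
$\Delta = 1 - (a_1 + a_2 + c)/3$ and $P$ fields are available in closed
form.  Scattering regimes are encoded through the retention triple:

* **background tissue** $(a_1, a_2, c) = (0.80, 0.80, 0.60)$ — circular
  polarization decays faster than linear ($m_{22} \approx m_{33} > m_{44}$),
  the Rayleigh-like signature of fine sub-wavelength structure;
* **plaque cores** $c = 0.92$ — large scatterers preserve helicity
  ($m_{44} \ge m_{22}$, the Mie-like signature); $a_2$ is lowered to keep
  the core's total depolarizing power at the background level, so cores are
  pure circular-channel anomalies;
* **plaque rims** — a fixed-width (2 px) shell of elevated depolarization
  around each core (contrast $+0.06$ to $+0.09$ in $\Delta$, growing with
  age), representing the disordered tissue halo around a deposit;
* **heterogeneity patches** — symmetric $\pm$ offsets on $(a_2, c)$ over
  disk-shaped patches covering 15% of tissue at 75 days growing to 28% at
  225 days, representing increasing large-scale tissue disorder.

Plaque count density is zero until an onset at 45 days and then linear in
age (`default_age_schedule()`, 0.16 plaques per 1e4 px^2 per day), and
plaque radius matures linearly from 1.2 px to 2.2 px across the 75–225 day
ladder.  The default cohort is 7 ages (75 to 225 days in 25-day steps) times
3 replicates = 21 samples.  All per-pixel jitter is truncated Gaussian;
the truncation bounds, together with a per-pixel constructive clamp on the
core circular retention, *guarantee* the class orderings ($m_{44} \ge m_{22}$
at every core pixel, $m_{22} > m_{44}$ at every other tissue pixel) rather
than making them merely probable.  The simulated measurement applies ideal
generator/analyzer states, an exposure scale, a mount medium of low
transmittance (0.25) outside the elliptical tissue footprint, and additive
Gaussian noise of standard deviation signal/SNR (default SNR 50), clipped
at zero.

### Why this composition of mechanisms

The generator is built to *inject* the qualitative trend pattern the
statistical layer is designed to detect: skewness of $\Delta$ and of
$m_{44}$ increasing with age, kurtosis of $\Delta$ decreasing, mean and
standard deviation of $m_{22}$ flat.  A single growing tail cannot produce
that pattern: for a fixed-offset tail of weight $f$, offset $d$ over a
background of width $\sigma$, both skewness and kurtosis are humped
functions of $u = f d^2/\sigma^2$, with kurtosis peaking near $u \approx 1$
and skewness near $u \approx 2$, so over a six-fold density range the two
cannot move in opposite directions through one channel.  The design
therefore splits the mechanisms: the rim tail operates at $u < 1$ where its
growth drives skewness up; the symmetric patches contribute no skewness but
carry the kurtosis decline (a rare-patch distribution is heavy-tailed,
kurtosis $\sim 1/f$, so growing coverage flattens it); and radius maturation
makes the plaque area fraction convex in age, which keeps the late-age trend
identifiable against Poisson noise in the plaque counts.  Channel separation
keeps $m_{22}$ (the $a_1$ channel, identical in every class) flat by
construction.  Default magnitudes were calibrated once, at design time,
with a mixture-moment Monte Carlo at the reduced problem size; at that size
(64 x 64 px, 20 replicate cohorts) the full pipeline recovered all four
trend signs jointly in 99 of 100 cohorts.

Wavelength enters only through the background circular retention (0.54 /
0.57 / 0.60 at 445 / 532 / 632 nm — shorter wavelengths sit deeper in the
Rayleigh regime); paraffin embedding is emulated as a global 0.85 retention
scaling.  The phantom background retardance default is 0.30 rad — lower
than typical measured brain-tissue retardance (~0.6 rad) — because the
composed $m_{44}$ scales with $\cos\delta$ and larger retardance would
erase the Mie ordering the phantom is required to encode unambiguously;
this is a regime choice for the phantom, not a claim about tissue.

### What the phantom does and does not show

Because phantom pixels are exact canonical compositions, passing the
recovery tests demonstrates correctness of reconstruction, decomposition
and statistics — not realism of the optics.  Real tissue adds: genuine
radiative transport (the per-pixel model has no lateral coupling), mixed
retardance/diattenuation textures, instrument calibration error in the
generator/analyzer states (assumed ideal here), image registration error
(images assumed co-registered), shot noise and detector nonlinearity
(additive Gaussian noise only), and dispersion of the optics across
wavelength.  Scattering-theory quantities ($\mu_s$, $g$, particle-size
distributions) are intentionally not simulated; the Rayleigh/Mie language
refers to the encoded retention orderings, not to computed Mie
coefficients.

## Files and numerical storage

Intensity stacks are exchanged as 36 single-channel 16-bit TIFFs
(`<sample>_<G><A>.tif`) plus a `meta.yaml` carrying sample metadata and the
linear intensity scale; integer-valued 16-bit data round-trips exactly.
Mueller images and parameter maps are written as 32-bit TIFFs with the
value range recorded in a YAML sidecar (quantization ~2e-10 of the range;
the analysis itself runs in memory at double precision).  Reports are plain
CSV; reruns with an identical configuration are byte-identical, and all
randomness descends from explicit seeds without touching the caller's RNG
state.

## Problem sizes and runtime

Defaults are chosen so a full cohort analysis is interactive: a 21-sample
cohort at 256 x 256 px runs in well under a minute on one core, and the
repeated trend-recovery check uses 64 x 64 px cohorts (about 1.5 s each).
The compiled decomposition loop processes roughly 10^6 pixels per second.

## Known limitations

* The region-of-interest rule (default: pixels above the 50th percentile of
  $m_{11}$) is a stated convention, not a published segmentation standard;
  results over very sparse tissue should use the `fixed` rule instead.
* The exponential trend model is descriptive; no uncertainty is attached to
  $\beta$ beyond the residual norm, and hypothesis testing across age
  groups is out of scope.
* The decomposition is the canonical product order only; reverse-order,
  symmetric and differential decompositions are not implemented, nor is
  isotropic-depolarization filtering.
* Kurtosis magnitudes of the phantom's $m_{44}$ maps (10–15 at late ages)
  exceed those typical of measured tissue (2–4); the phantom's sparse
  high-contrast cores are deliberately more extreme than reality so that
  ordering checks have unambiguous margins.
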