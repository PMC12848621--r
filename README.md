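# mmpolar

Mueller-matrix polarimetry of tissue sections in R: image reconstruction
from six-state polarization measurements, Lu–Chipman polar decomposition,
and higher-order moment statistics of the resulting parameter maps across
sample age.

## The problem

Wide-field Mueller-matrix polarimetry probes how a thin tissue section
transforms polarized light.  Preparing six input polarization states
(H, V, ±45°, right/left circular) and analyzing the transmitted beam
through the same six states yields 36 co-registered intensity images per
sample, from which the per-pixel 4×4 Mueller matrix

```
S_out = M S_in,     M = (m_ij),  i, j = 1..4
```

is reconstructed: every element is a signed four-term sum of intensity
images (e.g. `m11 = HH + HV + VH + VV`, `m44 = RR − RL − LR + LL`; first
letter generator, second analyzer), normalized by `m11`.  The Lu–Chipman
factorization `M = M_Δ · M_R · M_D` then separates, pixel by pixel,
diattenuation **D**, polarizance **P**, retardance **R** (radians) and
depolarization power **Δ = 1 − |tr m_Δ|/3**.

In neurodegeneration studies the spatial *distributions* of these maps
carry the signal: growing amyloid-like deposits act as enlarged scattering
centers that preserve circular polarization (Mie-like, raising `m44`
against the Rayleigh-like background where `m22 ≈ m33 > m44`), which shifts
the *skewness* and *kurtosis* of depolarization-related maps long before
their means move.  The package computes the first four population moments

```
μ = Σx/N,  σ = √(Σ(x−μ)²/N),  skew = Σ(x−μ)³/(Nσ³),  kurt = Σ(x−μ)⁴/(Nσ⁴)
```

of each map over a tissue mask, aggregates them across samples by age
group, and fits linear (mean, σ) and three-parameter exponential
(`y = α·exp(βx) + c`; skewness, kurtosis) trends against age.

Because equivalent measured data are not public, the package includes a
first-class synthetic phantom generator: per-pixel effective Mueller
matrices in exact canonical form with Rayleigh-like background, Mie-like
plaque cores (with depolarizing rims) whose density follows a
plaque-deposition schedule (onset at 45 days, then linear in age), and
growing tissue heterogeneity — providing exact ground truth for every
pipeline stage.  See the methods vignette
(`vignettes/mmpolar-methods.Rmd`) for the model, conventions, calibration
and limitations.

## Worked example

Simulate the default-style cohort (7 ages × 3 replicates) at 128×128 px and
SNR 50, run the full chain, and print the age table:

```r
library(mmpolar)
cfg <- run_config(phantom = list(shape = c(128L, 128L), noise_snr = 50),
                  parameters = c("m22", "m44", "Delta"), seed = 42L)
res <- run_pipeline(cfg)
print(res)
#> pipeline_result: 21/21 samples, parameters m22, m44, Delta
#> parameter               75       100       125       150       175       200       225
#> m22        Mean      0.800     0.800     0.800     0.800     0.800     0.800     0.800
#> m22        Std       0.015     0.015     0.015     0.015     0.015     0.015     0.015
#> m44        Skew      0.794     1.122     1.903     2.411     2.275     2.258     2.257
#> m44        Kurt      9.059    10.732    13.027    14.869    12.611    11.396    10.201
#> Delta      Skew      0.164     0.234     0.304     0.612     0.538     0.530     0.635
#> Delta      Kurt      4.992     4.559     4.208     4.537     3.905     3.675     3.545
#> (full table has Mean/Std/Skew/Kurt rows for every parameter)
```

The phantom's injected structure is visible exactly as designed: `m22` mean
and spread are flat across age; skewness of `Delta` and `m44` climbs;
kurtosis of `Delta` falls.  The fitted trends quantify this:

```r
res$trends$Delta$fits$skewness
#> exponential fit (converged): alpha = -1.3504, beta = -0.010221, offset = 0.76214; residual norm 0.1806
res$trends$Delta$fits$kurtosis
#> linear fit (converged): slope = -0.009156, intercept = 5.5764; residual norm 0.4395
```

(The exponential rate of change is `α·β·exp(βx)` — positive here, an
increasing saturating trend; `slope < 0` is the kurtosis decline.)

Lower-level functions are exported individually: `reconstruct_mueller()`,
`normalize_by_m11()`, `tissue_mask()`, `decompose_mueller()` /
`decompose_image()`, `central_moments()`, `moments_by_group()`,
`fit_linear()` / `fit_exponential()`, `generate_phantom()`,
`forward_measure()`, `make_age_series()`, plus TIFF/YAML/CSV I/O
(`read_stack()`, `write_stack()`, `write_maps()`, `write_moments_csv()`).
A thin command-line front end with `simulate` / `reconstruct` /
`decompose` / `stats` / `pipeline` subcommands is installed at
`system.file("cli", "mmpolar", package = "mmpolar")`.

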