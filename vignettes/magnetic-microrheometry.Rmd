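---
title: "Magnetic microrheometry and Bayesian heterogeneity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetic microrheometry and Bayesian heterogeneity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magrheo)
```

## The measurement and its physics

A magnetic microrheometer drives micrometre-scale magnetic spheres embedded
in a hydrogel 3D cell-culture matrix with a slow sinusoidal force (drive
frequency $f$ = 0.05 Hz by default) and records each sphere's displacement
relative to non-magnetic reference spheres, which removes mounting and
environmental common-mode motion. The displacement track is fitted with

$$p(t) = \hat p \, \sin(2\pi f t - \phi),$$

where $\hat p$ is the displacement amplitude and $\phi$ the phase lag behind
the force: $\phi = 0^\circ$ for a purely elastic medium, $90^\circ$ for a
purely viscous one. Because the frequency is known, the fit is linear least
squares in a $\sin/\cos$ basis ($\hat p = \sqrt{a^2+b^2}$,
$\phi = \mathrm{atan2}(-b, a)$) with a constant offset always included and a
linear drift regressor on by default — convex, deterministic, and free of
initialization choices. The phase sign convention makes lag positive, so
viscoelastic media fall in $[0^\circ, 90^\circ]$; values outside that range
are flagged but never silently dropped.

The instrument is calibrated in a fluid of known dynamic viscosity $\mu$.
For a sphere of diameter $D$ oscillating in the Stokes regime, the drag
force is $3\pi\mu D \hat v$ with $\hat v = 2\pi f \hat p$, so the magnetic
force per unit sphere volume (the *volumetric force constant*) is

$$F^{\mathrm{vol}} = \frac{18\,\mu\,\hat v}{D^2}.$$

Rather than averaging per-sphere estimates, the calibration pools all
spheres through a no-intercept Bayesian regression
$\hat v \sim \mathcal N(\beta r^2, \sigma^2)$ with priors
$\beta \sim \mathcal N(0, 5000)$ and $\sigma = 10^{-8} x$,
$x \sim \mathrm{InvGamma}(0.5, 1)$ (priors stated on SI scales, m/s against
m²; the $10^{-8}$ factor is a configuration knob matching the prior to the
data scale, and the inverse gamma's second argument is read as a scale, with
a rate reading switchable — the two coincide at the default value 1). Then
$F^{\mathrm{vol}} = \tfrac92 \beta \mu$ draw-wise. Goodness of fit is a
draw-wise Bayesian $R^2$,
$\mathrm{var(fitted)}/(\mathrm{var(fitted)}+\sigma^2)$. In a matrix, the
same force constant converts an amplitude into the absolute shear modulus

$$|G| = \frac{F^{\mathrm{vol}} V}{3\pi D \hat p} = \frac{F^{\mathrm{vol}} D^2}{18\,\hat p},$$

and $E = 2(1+v)\,|G|$ gives Young's modulus over a Poisson-ratio range
($v \in [0.37, 0.50]$ by default, the range used for agarose). $|G|$ scales
with $D^2$ at fixed amplitude, which is why larger spheres extend the
measurable stiffness range, and also why the sphere diameter is the single
most consequential measured input.

A useful closed-form oracle follows from the same physics: running the
*entire* pipeline on tracks simulated in a Newtonian fluid must return
$|G| = 2\pi f \mu$ and $\phi = 90^\circ$. The test suite holds the pipeline
to that identity within 1%.

## The heterogeneity model

Each matrix type is measured over a nested design: samples, two holders per
sample, several imaged locations per holder, 1–3 spheres per location, and
at least two repeats per sphere. Per-sphere observations $y$ (either $|G|$
or $\phi$, z-score normalized) are modeled with a multilevel
variance-components model, written generatively in non-centered form:

$$
\begin{aligned}
\mu^{\mathrm{sample}}_{ms} &= \mu^{\mathrm{matrix}}_m + \alpha^{\mathrm{s}}_m z^{\mathrm{sample}}_{ms},\\
\mu^{\mathrm{holder}}_{msh} &= \mu^{\mathrm{sample}}_{ms} + \alpha^{\mathrm{h}}_m z^{\mathrm{holder}}_{msh},\\
\mu^{\mathrm{sphere}}_{msht} &= \mu^{\mathrm{holder}}_{msh} + \alpha^{\mathrm{t}}_m z^{\mathrm{sphere}}_{msht},\\
y_{mshtr} &\sim \mathcal N(\mu^{\mathrm{sphere}}_{msht}, \sigma_t),
\end{aligned}
$$

with standard-normal innovations $z$, half-normal(0, 1) priors on every
scale and on the noise hyperparameters, standard-normal priors on the matrix
means, and heteroscedastic per-sphere noise partially pooled through
$\sigma_t \sim \mathrm{InvGamma}(\sigma^\mu, \sigma^\sigma_m)$: the shape
$\sigma^\mu$ is shared across matrix types (one instrument, one mean noise
level) while the scale $\sigma^\sigma_m$ is matrix-specific. The package
names every scale by the level it scatters, which resolves a superscript
ambiguity that otherwise invites off-by-one-level mistakes:
`sample_within_matrix` ($\alpha^{\mathrm s}$), `holder_within_sample`
($\alpha^{\mathrm h}$) and `sphere_within_holder` ($\alpha^{\mathrm t}$).
The last is the headline *heterogeneity*: the magnitude of spatial variation
in viscoelasticity within one sample holder. `sample_within_matrix` is the
quantity comparable to the sample-to-sample coefficient of variation
reported by parallel-plate rheometry; `heterogeneity_summary()` exposes
either, so both readings of "sample-to-sample variation" are available
rather than asserting one.

**Normalization.** Observations are centered per matrix type (the property
magnitudes are irrelevant to heterogeneity) but divided by one SD shared
across matrix types, computed once from the pooled per-matrix-centered
data — this keeps the scatter scales comparable across matrices. The
constants are stored with the fit so the transform is invertible, and all
heterogeneity summaries are invariant under a common rescaling of the raw
data.

**Inverse-gamma reading.** The noise prior is implemented literally as
$\mathrm{InvGamma}(\mathrm{shape} = \sigma^\mu, \mathrm{scale} =
\sigma^\sigma_m)$. Because "mean noise level" is also a natural reading of
$\sigma^\mu$, a mean-parametrized alternative
($\mathrm{mean} = \sigma^\mu$, $\mathrm{SD} = \sigma^\sigma_m$, i.e.
shape $= 2 + (\sigma^\mu/\sigma^\sigma_m)^2$) is available via
`model_spec(noise_parametrization = "mean_sd")`. The literal form is the
default.

**Sampling.** Posteriors are drawn with JAGS (Gibbs/slice sampling) through
`rjags`. The non-centered parametrization that defines the model is the
right geometry for Hamiltonian samplers, but under conditional (Gibbs)
updates it mixes poorly — the innovations and their scales are strongly
coupled. The sampler therefore works on the mathematically equivalent
centered form ($\mu^{\mathrm{child}} \sim \mathcal N(\mu^{\mathrm{parent}},
\alpha)$), which is the efficient parametrization for this engine, and the
innovations $z$ are reported as derived quantities so the posterior object
still exposes the full non-centered state. Defaults are 4 chains, 1000
adaptation + 1000 burn-in iterations, 1000 kept draws per chain.
Convergence is judged by split-chain R-hat and effective sample size; a fit
is flagged (warning plus `converged = FALSE`) when any R-hat reaches 1.05.
Divergence counts are a Hamiltonian-specific diagnostic and are reported as
`NA`. Designs with a single child per level are permitted — the affected
scale is then prior-dominated, and the fit warns about identifiability.

**Model variants.** Five variants support model criticism:
`primary` (above); `location_level`, inserting a location tier between
holder and sphere (then the within-holder scale reflects location-to-location
variation, and spheres scatter within locations); `single_level`, keeping
only a matrix mean, one scatter scale and the pooled noise (expected to
*overestimate* heterogeneity, since its single scale absorbs sample- and
holder-level variance); `pooled_baseline`, a single matrix mean whose
scatter SD is the heterogeneity, with the pooled per-sphere noise retained
(its scatter SD and the noise term split the total variance, so only their
combination is well identified — the tests check exactly that identifiable
quantity); and `pooled_no_shared_noise`, the baseline without the pooled
noise term, whose single SD *is* the total scatter.

**Model comparison.** Out-of-sample performance is the expected log
pointwise predictive density with one magnetic sphere (all its repeats) left
out at a time. The held-out sphere's latent mean is integrated analytically:
given its noise SD, the repeats are jointly Gaussian with a
compound-symmetric covariance $\alpha^2 J + \sigma^2 I$ (any ancestors
missing from the training fit contribute additional Gaussian variance to the
compound term), so only the inverse-gamma noise SD is integrated by
simulation (40 draws per posterior draw by default). `method = "exact"`
refits the model per fold; `method = "importance"` reuses one full-data fit
with truncated importance sampling (weights capped at $\sqrt S$ times their
mean), flagging folds whose largest normalized weight exceeds 0.2. The two
agree closely on desk-scale data (the suite checks a mean absolute
pointwise gap below 0.5); the fast path is used where many replicate
comparisons are needed.

**Pairwise comparisons.** `pairwise_probability()` estimates
$P(\alpha_a > \alpha_b)$ from draws paired by iteration within a single
joint fit, the probability-value summary used to rank matrix types.

## The synthetic-data generator

Raw video tracks for the original experiments are not deposited, so the
package ships a generator that emulates the *statistical* structure the
analysis assumes, with ground truth recorded next to every dataset:

- **Calibration tracks**: spheres in a Newtonian fluid, noiseless
  displacement $\hat p \sin(2\pi f t - 90^\circ)$ with
  $\hat p = F^{\mathrm{vol}} D^2 / (18\mu \cdot 2\pi f)$, plus i.i.d.
  Gaussian tracking noise. Diameters are truncated-normal (at $\pm 3$ SD and
  at zero) — only nominal mean sizes are published, and truncation avoids
  non-physical sizes.
- **Hierarchical observations**: the exact generative chain of the model
  above, vectorized, then de-normalized with a configurable per-matrix raw
  mean and one shared raw SD (mirroring the analysis-side normalization).
  Default truth values for simulation studies are scatter scales
  (0.3, 0.2, 0.8) for sample/holder/sphere, noise shape 3 and scale 0.2
  (mean per-sphere noise SD 0.1 on the normalized scale — repeat
  measurements visibly noisy but far tighter than sphere-to-sphere scatter,
  which is what motivates repeats in the first place), and a raw scale of
  100 ± 20 Pa matching the softer matrices' published range.
- **Matrix tracks**: the rheology relation inverted,
  $\hat p = F^{\mathrm{vol}} D^2/(18|G|)$, sinusoid plus optional linear
  drift and Gaussian tracking noise — the simplest corruption model the
  reference correction and drift-aware fit must defeat.

Identical seeds give bit-identical outputs; the RNG call order inside the
generators is part of that contract. What the generator does *not* emulate:
spatial inhomogeneity of the magnetic field gradient across the field of
view, correlated tracking noise, sphere asphericity, or any dependence of
noise on stiffness. Passing recovery tests on these synthetic data therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not robustness to every instrumental artifact in real videos.

## Default problem sizes and numerical choices

Simulation studies in the test suite run at the study's design size
(3 samples × 2 holders × 3–5 locations × 1–3 spheres × 2 repeats) with 20
replicates for credible-interval coverage, 100 replicates for calibration
coverage, and 10 replicates for predictive model comparison — sizes chosen
to keep Monte-Carlo error well below the margins being asserted while the
full suite completes in a few minutes. Tracks default to one full drive
period (20 s at 0.05 Hz) sampled at 25 Hz: one period is the minimum
identifiable window for the amplitude/phase fit, and the fit degrades
gracefully with more.

Numerical details worth knowing: phases are wrapped to $[-180^\circ,
180^\circ)$ and reported in degrees (radians internally); a zero-variance
track yields amplitude 0 with the phase flagged undefined rather than an
arbitrary angle; inverse-gamma draws clamp the underlying gamma variate away
from exact zero so an underflow cannot produce an infinite noise SD; the QC
filter accepts `Inf` thresholds (reject everything) and `0` (accept
everything), and every rejection carries a machine-readable reason.

## Known limitations

- The sampler is Gibbs-based; posterior geometry pathologies that HMC
  diagnostics (divergences) would expose are only visible here through
  R-hat/ESS, so flagged fits deserve a second look rather than a rerun with
  a new seed.
- With 3 samples and 2 holders per sample, the sample- and holder-level
  scales are weakly identified by design; their posteriors lean on the
  half-normal prior, which is exactly the partial-pooling behavior intended,
  but it means those scales should be read as regularized estimates, not
  data-dominated measurements.
- The importance-sampling ELPD path inherits the usual heavy-tail risk of
  leave-one-group-out weights; flagged folds (> 0.2 normalized weight) are
  the signal to fall back to exact refits.
- Published calibration constants and matrix moduli from the original
  instrument cannot be reproduced here (they require the original raw
  tracks); the package instead verifies all closed-form arithmetic on the
  published summary tables and validates the inference machinery by
  simulation.
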