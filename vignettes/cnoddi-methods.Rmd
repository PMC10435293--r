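---
title: "Constrained NODDI: model, estimation and validation on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained NODDI: model, estimation and validation on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The signal model

A brain voxel's diffusion-weighted signal is modelled as three
non-exchanging water pools.  With unit gradient direction $g$ and weighting
$b$, the normalised signal is

$$A(b, g) = f_{in}\,S_{in} + f_{ex}\,S_{ex} + F_{iso}\,e^{-b d_{iso}},
\qquad f_{in} + f_{ex} + F_{iso} = 1 .$$

* **Intra-neurite** ($S_{in}$): a stick with parallel diffusivity $d_\parallel$
  and zero perpendicular diffusivity, averaged over neurite orientations $n$
  drawn from a Watson distribution
  $W(n) \propto \exp(\kappa\,(\mu\cdot n)^2)$ with mean axis $\mu$ and
  concentration $\kappa$:
  $S_{in} = \int W(n)\, e^{-b d_\parallel (g\cdot n)^2}\, dn$.
* **Extra-neurite** ($S_{ex}$): an axially symmetric Gaussian tensor whose
  perpendicular diffusivity is tortuosity-coupled to the *tissue-normalised*
  neurite fraction $\nu = f_{in}/(f_{in}+f_{ex})$ as
  $d_\perp = d_\parallel (1-\nu)$.  The tensor (not the signal) is averaged
  over the Watson distribution, using the second moment
  $\tau = E[(\mu\cdot n)^2]$, and the Gaussian signal of the mean tensor is
  taken.  Averaging signals instead of tensors is a defensible alternative;
  the tensor convention was chosen for fidelity to the established NODDI
  implementations that this package mirrors.
* **Isotropic** (CSF): free diffusion at $d_{iso}$.

Dispersion is reported as $\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)$, the
convention of the original NODDI toolbox; the neurite density index (NDI)
reported by default is the tissue-normalised fraction $\nu$, with the raw
$f_{in}$ emitted alongside (`fin_raw`), since published work is ambiguous
about which of the two is meant by "NDI".

### Relaxation weighting and the apparent CSF fraction

With per-compartment relaxation times the full (un-normalised) signal is

$$S = S_0 \sum_c f_c\, e^{-TE/T_{2,c}} (1 - e^{-TR/T_{1,c}})\, S_{D,c},$$

with volume fractions $f_c$.  The package assumes one transverse time for
intra- and extra-cellular water ($T_{2,in/ex}$), the assumption that defines
the constrained model.  Normalising by the measured $b=0$ signal turns the
volume fractions into *apparent signal* fractions; because CSF
($T_{2,iso} \approx 1500$ ms) decays far more slowly than tissue
($\approx 70$ ms), the apparent isotropic fraction

$$F_{iso}(TE) = \frac{f_{iso}\, r(TE)}{1 - f_{iso} + f_{iso}\, r(TE)},
\qquad r(TE) = e^{-TE/T_{2,iso} + TE/T_{2,in/ex}},$$

grows with echo time (`apparent_fiso()`; at finite TR the $T_1$ saturation
factors enter the ratio as well, and the generator uses the exact
expression).  This is the mechanism behind both the CSF-fraction
overestimation and the TE dependence of NDI that motivate the constrained
fit.

## C-NODDI: constraining the isotropic fraction

The constrained fit takes $F_{iso}$ as a known per-voxel input and estimates
only $(\nu, \kappa, \mu)$ under $f_{in} + f_{ex} = 1 - F_{iso}$.  The input
map normally comes from the package's own segmentation of the T2-weighted
$b=0$ image, but any externally produced map can be supplied (CLI `--fiso`).

The segmentation is a three-class Gaussian mixture on the b = 0 intensities
with a hidden-Markov-random-field spatial prior: seeded EM (quantile-spread
k-means-style initialisation, variance floor, log-likelihood monotone)
followed by rounds in which one iterated-conditional-modes sweep under a
6-neighbour Potts prior is interleaved with a parameter update from the
regularised posteriors.  CSF is identified as the brightest class and
$F_{iso}$ is taken to be its posterior probability.  This is an *emulation*
of a partial-volume segmenter with posterior probabilities, not a full
partial-volume-estimation model, and it contains no bias-field correction —
both are out of scope, and the phantom simulator generates no bias field.

## Estimation

Per voxel, signals are normalised by the mean of the $b=0$ volumes, the
orientation is initialised from a log-linear tensor fit on the low-b shell
(principal eigenvector; degenerate spectra fall back to $+z$ with a flag),
and estimation proceeds in two stages:

1. **Coarse grid** over $(\nu, \kappa[, F_{iso}])$ at the fixed initial
   orientation; default 8 points per axis, $\kappa$ gridded uniformly in ODI.
   Ties are broken toward the lowest $\kappa$ (the flatter, less committed
   solution).
2. **Derivative-based refinement** (`nlminb`) of all parameters through
   smooth bijections: fractions through logistic maps, $\kappa$ through a
   bounded positive map with clamp $\kappa_{max} = 128$ — at the supported
   protocol an ODI below ~0.005 is not resolvable, so larger concentrations
   are observationally equivalent.  Convergence: relative objective change
   $< 10^{-6}$ or 200 iterations.

The default objective is Gaussian least squares; a Rician maximum-likelihood
objective is available (`noise_model = "rician"`), with the noise level
supplied or estimated from the least-squares residuals.  Least squares is
the default for speed and for comparability with common practice, but note
that on magnitude data it inherits the Rician floor bias at low SNR (see
below).  Voxels with $F_{iso} > 0.95$ carry essentially no tissue signal and
are emitted as missing with a flag rather than fitted.

Fixed constants default to $d_\parallel = 1.7\times10^{-3}$ mm²/s and
$d_{iso} = 3.0\times10^{-3}$ mm²/s, the standard in-vivo values; both are
configurable.

## Numerical core

The Watson-dispersed stick is evaluated without spherical-harmonic series:
the integrand is $\exp(n^\top B n)$ with
$B = \kappa\mu\mu^\top - b d_\parallel g g^\top$, so the spherical mean
depends only on the eigenvalues of $B$ (two from a closed-form 2×2 problem,
one zero).  Averaging over azimuth yields a modified Bessel $I_0$ factor and
reduces the integral to one dimension, evaluated with 64-point
Gauss–Legendre quadrature; the largest eigenvalue is assigned to the polar
axis, where the nodes cluster.  The reduction is exact and the quadrature is
accurate to machine precision up to the $\kappa$ clamp; $I_0$ uses the
classical rational approximations (relative error $<2\times10^{-7}$), far
inside the $10^{-4}$ agreement contract that the test suite enforces against
brute-force spherical integration.  The Watson normalisation and second
moment use the same quadrature; the closed error-function forms serve as
independent oracles in the tests (the `erfi` implementation available in R
turned out to be the *less* accurate route, off by ~$10^{-9}$ at
$\kappa \approx 16$).

The `sphere_quadrature()` rule exposed to users is a Gauss–Legendre ×
uniform-azimuth product rule with positive weights summing to one; constants
and low-order polynomials are integrated exactly.

## The synthetic data and what it does (and does not) show

The phantom is a nested-box (or concentric-shell) geometry: a 2-voxel CSF
rim ($F_{iso}=1$), a 2-voxel GM band (NDI 0.4, ODI 0.6) and a WM core
(NDI 0.6, ODI 0.2, $F_{iso}=0$), b0 intensities 340/420/880 with CSF
brightest, default grid 24×24×16.  The deep-WM mask (WM at least 3 voxels
from any other class) is the analogue of the eroded ROIs used in human
studies to suppress partial-volume effects.  Tissue values are plausibility
presets — no ground-truth histology exists for them — and all are
configurable.

Noise is Rician (magnitude of a complex Gaussian perturbation), default
SNR 30 at $b=0$, a typical clinical diffusion EPI figure.  In the multi-TE
simulator the thermal noise level is fixed across echo times at
$S_{b0}(TE_{min})/\mathrm{SNR}$, as for a scanner whose noise does not
depend on TE: the effective SNR therefore falls with TE, as in real
acquisitions.  All randomness is driven by a single integer seed per
simulator call; repeated calls are bit-identical.

Simulated cohorts draw ages uniformly on 21–83 years, give each subject an
NDI on an inverted-U age curve (peak 42 years, curvature
$-2\times10^{-5}$/yr², subject deviation SD 0.02) plus region noise, and
couple log-NfL negatively to the subject's NDI.  The subject-level
deviation matters: it is the component of NDI variance that survives age
adjustment, without which an NfL–NDI association could not be recovered by
the very regression that controls for age.

What passing the suite shows: the estimator recovers the parameters of its
own generating model under Rician noise at the study protocol; the
constrained fit is unbiased given the correct $F_{iso}$; the free fit
reproduces the known pathologies (CSF-fraction overestimation under the T2
mismatch, TE-dependent NDI); the segmentation recovers the phantom's
composition.  What it cannot show: robustness to the many properties of
real data the phantom lacks — crossing fibres, exchange, genuinely distinct
intra/extra T2, gradient nonlinearity, motion, eddy currents, susceptibility
distortion, bias fields — nor the validity of the biophysical model itself.

### On the TE-dependence experiment

With a shared tissue T2 in the generator, the *noiseless* normalised tissue
signal is TE-invariant, so the TE dependence of the free fit in this
simulation is noise-mediated: as TE grows the effective SNR falls, the
Rician floor inflates the high-b signal, and the free fit — whose isotropic
fraction is pinned at its zero bound in clean WM — converts the excess into
neurite density faster than the constrained fit does.  Consistently,
switching both fits to the Rician likelihood largely removes the trend.
The experiment therefore reproduces the *phenomenology* reported for real
data (free-fit NDI rising with TE, constrained NDI much flatter), while in
vivo an additional contribution from genuinely different compartment T2
values is likely.  The acceptance experiment measures mean NDI over the default phantom's
whole 2048-voxel WM core (a large CSF-free WM region, the analogue of the
lobar WM masks used in vivo) at TE 78/90/100/120 ms.

## Problem sizes and runtime

The test suite and the acceptance script use: 500 single-voxel replicates
for recovery statistics; 200 voxels for the ODI-equivalence sweep; 150
CSF-contaminated WM voxels for the T2-mismatch ordering; the 2048-voxel WM
core across 4 echo times for TE dependence; the full 9216-voxel phantom for
segmentation; cohorts of 200 subjects (20 replicates) for the peak-age and
NfL statistics.  These sizes put Monte-Carlo error comfortably inside the
asserted margins while keeping a full run at a few minutes on a single
core.  The TE-range ratio is the tightest margin of the suite: it compares
4-point ranges of noisy means, which is why the largest available WM region
is used for it.

## Known limitations

* $F_{iso}$ as a CSF posterior probability is a soft-classification proxy
  for a true partial-volume fraction; near tissue boundaries it saturates
  faster than a mixel model would.
* The constrained fit is only as good as its $F_{iso}$ input; a biased
  segmentation propagates directly into NDI.
* Gaussian least squares on magnitude data biases NDI upward at low SNR
  (use the Rician objective when the noise level is known).
* The Watson distribution models a single dispersed fibre population;
  crossing-fibre voxels violate the model for both variants.
* Peak ages from the quadratic age model use the vertex formula and are
  only meaningful for concave fits with an interior maximum.
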