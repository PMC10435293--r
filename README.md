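# cnoddi

Constrained NODDI modelling of white matter microstructure from multi-shell
diffusion MRI.

## The problem

Neurite orientation dispersion and density imaging (NODDI) decomposes the
diffusion-weighted MR signal of a brain voxel into three compartments —
intra-neurite water (a stick dispersed by a Watson distribution),
extra-neurite water (a hindered axially symmetric tensor coupled to the
neurite fraction by tortuosity) and isotropically diffusing CSF — and reports
two scalar maps: the neurite density index (NDI) and the orientation
dispersion index (ODI).  The normalised signal model is

    A(b, g) = f_in * S_in(b, g; mu, kappa) + f_ex * S_ex(b, g; mu, kappa, nu)
              + F_iso * exp(-b * d_iso),

with `f_in + f_ex + F_iso = 1`, `S_in` the Watson-averaged stick with
parallel diffusivity `d_par`, `S_ex` the Gaussian signal of the
Watson-averaged tensor with perpendicular diffusivity `d_par * (1 - nu)`
(`nu` the tissue-normalised neurite fraction) and
`ODI = (2/pi) * atan(1/kappa)`.

Fitting all of this per voxel is ill-conditioned: the residual surface is
flat, and in practice the fitted CSF fraction `F_iso` is overestimated in
white matter, dragging NDI to implausibly high values and making it depend on
the echo time of the acquisition (CSF T2 is ~20x longer than tissue T2, so
the *apparent* CSF signal fraction grows with TE).

**C-NODDI** removes `F_iso` from the fit: it is estimated once per voxel from
the T2-weighted b = 0 image by a hidden-Markov-random-field Gaussian-mixture
segmentation (WM / GM / CSF) and then held fixed, reducing the model to a
bicomponent tissue fit with `f_in + f_ex = 1 - F_iso`.  The package
implements both variants, the segmentation, a relaxation-weighted forward
simulator for TE-dependence experiments, digital phantoms with Rician noise,
and the downstream region-of-interest statistics (quadratic age models with
FDR control across regions, and the association of NDI with plasma
neurofilament light chain).  It is aimed at diffusion-MRI methodologists who
want a fully reproducible, phantom-validated implementation that runs from R
or from a shell.

## Worked example

Simulate the study protocol (b = 0/700/2000 s/mm², 32 directions per shell)
for one white-matter-like voxel, add Rician noise at SNR 30, and fit both
models:

```r
library(cnoddi)
scheme <- build_scheme(c(0, 700, 2000), c(1, 32, 32), seed = 1)
truth  <- tissue_params(ndi = 0.6, odi = 0.2, fiso = 0.1)
signal <- add_noise(signal_composite(truth, scheme), sd = 1/30,
                    "rician", seed = 42)

fit_voxel_cnoddi(signal, scheme, fiso = 0.1)[c("ndi", "odi")]
#> $ndi
#> [1] 0.5987139
#> $odi
#> [1] 0.1996076

fit_voxel_noddi(signal, scheme)[c("ndi", "odi", "fiso")]
#> $ndi
#> [1] 0.5603799
#> $odi
#> [1] 0.1955677
#> $fiso
#> [1] 0.06156018
```

The constrained fit, given the true CSF fraction, lands on the generating
values (NDI 0.6, ODI 0.2).  The free fit misses the isotropic fraction on
this noisy draw (0.06 against a true 0.10) and drags the neurite density
with it — the per-voxel instability of the coupled (NDI, F_iso) estimate
that C-NODDI is designed to remove.  Both fits agree closely on ODI, which
is insensitive to the fraction split.

The same pipeline runs on whole volumes and from the shell
(`exec/cnoddi`):

```sh
cnoddi simulate --preset phantom --out-dir sim --seed 1
cnoddi segment  --b0 sim/b0_true.nii.gz --out sim/fiso.nii.gz
cnoddi fit      --model cnoddi --dwi sim/dwi.nii.gz --bval sim/dwi.bval \
                --bvec sim/dwi.bvec --fiso sim/fiso.nii.gz --out-dir maps
cnoddi stats    --table cohort.tsv --metric ndi --nfl --out report
```

All stages are seeded and bit-reproducible.

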