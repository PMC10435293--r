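#' Digital phantom specification
#'
#' Describes a simple brain-like digital phantom with a CSF rim, a
#' grey-matter band and a white-matter core, used to exercise every stage of
#' the pipeline with known ground truth.  Class presets are plausibility
#' values for 3 T in vivo tissue; all are configurable.
#'
#' @param shape voxel grid dimensions (length 3).
#' @param geometry `"nested_boxes"` (rectangular rim/band/core) or
#'   `"concentric_shells"` (ellipsoidal).
#' @param wm,gm,csf per-class parameter lists with elements `ndi`, `odi`,
#'   `fiso`, `b0` (T2-weighted b = 0 intensity; CSF is brightest).
#' @param fiber_field orientation rule for the neurite axis: `"constant_z"`,
#'   `"radial"` (pointing away from the volume centre) or `"random"`
#'   (seeded per-voxel axes).
#' @param rim thickness in voxels of the CSF rim and of the GM band.
#' @param seed integer seed used by the `"random"` fibre field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 24, 16),
                         geometry = c("nested_boxes", "concentric_shells"),
                         wm = list(ndi = 0.6, odi = 0.2, fiso = 0, b0 = 340),
                         gm = list(ndi = 0.4, odi = 0.6, fiso = 0, b0 = 420),
                         csf = list(ndi = 0, odi = 1, fiso = 1, b0 = 880),
                         fiber_field = c("constant_z", "radial", "random"),
                         rim = 2L, seed = 1) {
  geometry <- match.arg(geometry)
  fiber_field <- match.arg(fiber_field)
  if (length(shape) != 3L || any(shape < 2 * (2 * rim + 1)))
    stop("shape must have 3 dimensions large enough for the rim structure")
  structure(list(shape = as.integer(shape), geometry = geometry,
                 wm = wm, gm = gm, csf = csf, fiber_field = fiber_field,
                 rim = as.integer(rim), seed = seed),
            class = "phantom_spec")
}

#' Build a digital phantom
#'
#' Returns voxelwise parameter maps, a tissue label volume (1 = WM, 2 = GM,
#' 3 = CSF; the labels partition the grid), a noiseless T2-weighted b = 0
#' intensity volume, and a deep-white-matter mask (WM voxels at least 3
#' voxels from any non-WM voxel) where the true isotropic fraction is exactly
#' zero.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `labels`, `ndi`, `odi`, `kappa`, `fiso`, `mu`
#'   (4D, last dimension 3), `b0`, `deep_wm`, `mask` (all TRUE), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  rim <- spec$rim
  if (spec$geometry == "nested_boxes") {
    edge <- pmin(ix - 1, d[1] - ix, iy - 1, d[2] - iy, iz - 1, d[3] - iz)
    labels <- array(1L, d)
    labels[edge < 2 * rim] <- 2L
    labels[edge < rim] <- 3L
    wm_depth <- edge - 2 * rim  # voxels inside the WM core boundary
  } else {
    cx <- (d + 1) / 2
    r <- sqrt(((ix - cx[1]) / (d[1] / 2))^2 + ((iy - cx[2]) / (d[2] / 2))^2 +
                ((iz - cx[3]) / (d[3] / 2))^2)
    labels <- array(3L, d)
    labels[r < 0.75] <- 2L
    labels[r < 0.55] <- 1L
    wm_depth <- (0.55 - r) * min(d) / 2
  }
  deep_wm <- labels == 1L & wm_depth >= 2

  cls <- list(spec$wm, spec$gm, spec$csf)
  pick <- function(fld) {
    v <- array(0, d)
    for (k in 1:3) v[labels == k] <- cls[[k]][[fld]]
    v
  }
  ndi <- pick("ndi"); odi <- pick("odi"); fiso <- pick("fiso"); b0 <- pick("b0")
  kappa <- array(kappa_from_odi(pmax(odi, 1e-6)), d)
  kappa[odi >= 1] <- 0

  mu <- array(0, c(d, 3))
  if (spec$fiber_field == "constant_z") {
    mu[, , , 3] <- 1
  } else if (spec$fiber_field == "radial") {
    cx <- (d + 1) / 2
    vx <- ix - cx[1]; vy <- iy - cx[2]; vz <- iz - cx[3]
    ctr <- vx == 0 & vy == 0 & vz == 0
    vz[ctr] <- 1  # centre voxel gets the +z axis
    nrm <- sqrt(vx^2 + vy^2 + vz^2)
    mu[, , , 1] <- vx / nrm; mu[, , , 2] <- vy / nrm; mu[, , , 3] <- vz / nrm
  } else {
    set.seed(spec$seed)
    v <- matrix(rnorm(3 * prod(d)), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    mu <- array(v, c(prod(d), 3))
    dim(mu) <- c(d, 3)
  }
  list(labels = labels, ndi = ndi, odi = odi, kappa = kappa, fiso = fiso,
       mu = mu, b0 = b0, deep_wm = deep_wm, mask = array(TRUE, d), spec = spec)
}

#' Add Rician or Gaussian noise to a signal array
#'
#' Rician noise is realised as the magnitude of a complex Gaussian
#' perturbation with standard deviation `sd` on each channel, the standard
#' model for MRI magnitude images; it produces the familiar positive noise
#' floor at low signal.
#'
#' @param signal numeric array of noiseless signals.
#' @param sd noise standard deviation (scalar or array conformable with
#'   `signal`).
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param seed integer seed.
#' @return noisy array, same shape (Gaussian output clamped at 0).
#' @export
add_noise <- function(signal, sd, noise_model = c("rician", "gaussian", "none"),
                      seed = 1) {
  noise_model <- match.arg(noise_model)
  if (noise_model == "none") return(signal)
  set.seed(seed)
  n <- length(signal)
  e1 <- rnorm(n) * sd
  if (noise_model == "gaussian") {
    out <- signal + e1
    out[out < 0] <- 0
    return(out)
  }
  e2 <- rnorm(n) * sd
  sqrt((signal + e1)^2 + e2^2)
}

#' Simulate a multi-shell DWI dataset from parameter maps
#'
#' The noiseless channel is exactly the composite forward model scaled by the
#' per-voxel b = 0 intensity; Rician noise uses per-voxel standard deviation
#' `b0 / snr` (i.e. `snr` is the b = 0 signal-to-noise ratio).
#'
#' @param maps parameter maps as returned by [make_phantom()] (elements
#'   `ndi`, `kappa`, `fiso`, `mu`, `b0`, `mask`).
#' @param scheme an [acq_scheme].
#' @param snr signal-to-noise ratio at b = 0 (ignored for `"none"`).
#' @param noise_model `"rician"` (default), `"gaussian"` or `"none"`.
#' @param seed integer seed; the output is reproducible bit for bit.
#' @param consts a [diffusivity_constants].
#' @return a [dwi_volume]; the generating maps are attached as
#'   `attr(, "truth")`.
#' @export
simulate_dwi <- function(maps, scheme, snr = 30,
                         noise_model = c("rician", "gaussian", "none"),
                         seed = 1, consts = diffusivity_constants()) {
  noise_model <- match.arg(noise_model)
  if (noise_model != "none" && snr <= 0) stop("snr must be positive")
  d <- dim(maps$ndi)
  nvol <- n_volumes(scheme)
  sig <- matrix(0, prod(d), nvol)
  mu_mat <- matrix(maps$mu, prod(d), 3)
  vox <- which(maps$mask %||% array(TRUE, d))
  for (v in vox) {
    tp <- tissue_params(ndi = maps$ndi[v], kappa = maps$kappa[v],
                        fiso = maps$fiso[v], mu = mu_mat[v, ],
                        s0 = maps$b0[v])
    sig[v, ] <- maps$b0[v] * signal_composite(tp, scheme, consts)
  }
  arr <- array(sig, c(d, nvol))
  if (noise_model != "none") {
    sdv <- array(rep(maps$b0 / snr, nvol), c(d, nvol))
    arr <- add_noise(arr, sdv, noise_model, seed = seed)
  }
  out <- dwi_volume(arr, scheme, mask = maps$mask %||% array(TRUE, d))
  attr(out, "truth") <- maps
  out
}

#' Simulate a multi-echo-time DWI series
#'
#' Generates one DWI dataset per echo time with the relaxation-weighted
#' forward model, so the differential T2 weighting between tissue and CSF is
#' present in the data.  The phantom fractions are interpreted as *volume*
#' fractions and the phantom `b0` intensities as proton-density scale (TE = 0
#' signal); the TE contrast comes entirely from the relaxation model.  The
#' noise standard deviation is set from the b = 0 signal of the *shortest*
#' echo time (`sd = S_b0(TE_min) / snr`) and held fixed across TEs, as for a
#' scanner whose thermal noise does not depend on TE -- so the effective SNR
#' decreases at longer TE, as in real acquisitions.
#'
#' For every TE the per-voxel apparent isotropic fraction (the value a model
#' normalising by the measured b = 0 signal estimates, see [apparent_fiso()])
#' is emitted alongside as ground truth for the constrained fit.
#'
#' @param maps parameter maps ([make_phantom()]; fractions in volume sense).
#' @param relax a [relax_params].
#' @param te_list echo times in ms.
#' @param scheme_base an [acq_scheme] whose TE is replaced per series.
#' @param snr b = 0 signal-to-noise ratio at the shortest TE.
#' @param seed integer seed.
#' @param consts a [diffusivity_constants].
#' @param noise_model noise model as in [simulate_dwi()].
#' @return list with `volumes` (list of [dwi_volume], one per TE),
#'   `fiso_apparent` (list of 3D maps), `te_list`, `sd` (noise level used).
#' @export
simulate_multi_te <- function(maps, relax = relax_params(),
                              te_list = c(78, 90, 100, 120),
                              scheme_base, snr = 30, seed = 1,
                              consts = diffusivity_constants(),
                              noise_model = "rician") {
  d <- dim(maps$ndi)
  mu_mat <- matrix(maps$mu, prod(d), 3)
  vox <- which(maps$mask %||% array(TRUE, d))
  nvol <- n_volumes(scheme_base)
  volumes <- vector("list", length(te_list))
  fiso_app <- vector("list", length(te_list))
  sd_noise <- NULL
  for (i in seq_along(te_list)) {
    te <- te_list[i]
    scheme <- scheme_base
    scheme$echo_time <- te
    sig <- matrix(0, prod(d), nvol)
    for (v in vox) {
      tp <- tissue_params(ndi = maps$ndi[v], kappa = maps$kappa[v],
                          fiso = maps$fiso[v], mu = mu_mat[v, ])
      sig[v, ] <- signal_relaxation_weighted(tp, relax, scheme, consts,
                                             s0 = maps$b0[v])
    }
    arr <- array(sig, c(d, nvol))
    if (i == 1L) {
      b0_first <- arr[, , , which(scheme$bvals == 0)[1]]
      sd_noise <- mean(b0_first[vox]) / snr
    }
    if (noise_model != "none")
      arr <- add_noise(arr, sd_noise, noise_model, seed = seed + i)
    volumes[[i]] <- dwi_volume(arr, scheme,
                               mask = maps$mask %||% array(TRUE, d))
    fa <- array(NA_real_, d)
    fa[vox] <- apparent_fiso(maps$fiso[vox], te, relax,
                             tr = scheme$repetition_time)
    fiso_app[[i]] <- fa
  }
  list(volumes = volumes, fiso_apparent = fiso_app, te_list = te_list,
       sd = sd_noise)
}

#' Simulate a study cohort of ROI summary values
#'
#' Draws per-subject ages and sexes, gives each subject a neurite density on
#' a quadratic (inverted-U) trajectory in age with the stated peak age and
#' curvature plus a subject-level Gaussian deviation (individual differences
#' in axonal density beyond age), and each region-of-interest that subject
#' value plus region noise.  Optionally a plasma neurofilament light chain
#' (NfL) concentration is generated with a negative linear dependence of
#' log-NfL on the subject's NDI plus log-normal noise, so lower neurite
#' density maps to higher NfL also after age adjustment.  Dispersion is
#' generated flat in age.  All parameters are returned alongside so
#' downstream recovery can be checked in closed loop.
#'
#' @param n_subjects number of subjects (>= 10).
#' @param age_range sampling range of ages, years.
#' @param peak_age age of maximum NDI, years.
#' @param curvature quadratic coefficient of NDI in age, per year^2
#'   (negative for an inverted U).
#' @param sex_effect additive NDI offset for sex = 1.
#' @param noise_sd subject-level NDI standard deviation about the age curve.
#' @param roi_noise_sd additional region-level NDI noise (default half of
#'   `noise_sd`).
#' @param seed integer seed.
#' @param rois character vector of ROI names.
#' @param ndi_peak NDI value at the peak age.
#' @param odi_mean,odi_sd flat ODI level and noise.
#' @param nfl generate NfL values?
#' @param nfl_base NfL level (pg/mL) at NDI = `ndi_peak`.
#' @param nfl_coupling slope of log-NfL per unit NDI (negative: lower NDI,
#'   higher NfL).
#' @param nfl_noise_sd log-scale NfL noise.
#' @return data frame with one row per subject x ROI: `subject_id`, `roi`,
#'   `age`, `sex` (0/1), `mean_ndi`, `mean_odi`, and `nfl` if requested; the
#'   generating parameters are attached as `attr(, "truth")`.
#' @export
make_cohort <- function(n_subjects = 58, age_range = c(21, 83), peak_age = 42,
                        curvature = -2e-5, sex_effect = 0, noise_sd = 0.02,
                        seed = 1, rois = c("WB", "FL", "PL", "TL", "OL"),
                        roi_noise_sd = noise_sd / 2,
                        ndi_peak = 0.62, odi_mean = 0.25, odi_sd = 0.02,
                        nfl = TRUE, nfl_base = 10, nfl_coupling = -5,
                        nfl_noise_sd = 0.3) {
  if (n_subjects < 10) stop("need at least 10 subjects")
  set.seed(seed)
  age <- runif(n_subjects, age_range[1], age_range[2])
  sex <- rbinom(n_subjects, 1, 0.5)
  ndi_subject <- ndi_peak + curvature * (age - peak_age)^2 +
    sex_effect * sex + rnorm(n_subjects, sd = noise_sd)
  rows <- vector("list", length(rois))
  for (r in seq_along(rois)) {
    ndi_r <- ndi_subject + rnorm(n_subjects, sd = roi_noise_sd)
    odi_r <- odi_mean + rnorm(n_subjects, sd = odi_sd)
    rows[[r]] <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                            roi = rois[r], age = age, sex = sex,
                            mean_ndi = ndi_r, mean_odi = odi_r,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (nfl) {
    lognfl <- log(nfl_base) +
      nfl_coupling * (ndi_subject - ndi_peak) +
      rnorm(n_subjects, sd = nfl_noise_sd)
    tab$nfl <- exp(lognfl)[match(tab$subject_id,
                                 sprintf("S%03d", seq_len(n_subjects)))]
  }
  rownames(tab) <- NULL
  attr(tab, "truth") <- list(peak_age = peak_age, curvature = curvature,
                             sex_effect = sex_effect, ndi_peak = ndi_peak,
                             nfl_coupling = nfl_coupling)
  tab
}
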