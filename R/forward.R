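#' Fixed diffusivity constants
#'
#' The intrinsic parallel diffusivity of the neurite compartment and the free
#' (CSF) diffusivity are held fixed during fitting, the usual in-vivo
#' convention for this model class.
#'
#' @param d_par intrinsic parallel diffusivity, mm^2/s (default 1.7e-3).
#' @param d_iso isotropic CSF diffusivity, mm^2/s (default 3.0e-3).
#' @return object of class `diffusivity_constants`.
#' @export
diffusivity_constants <- function(d_par = 1.7e-3, d_iso = 3.0e-3) {
  if (d_par <= 0 || d_iso <= 0) stop("diffusivities must be positive")
  structure(list(d_par = d_par, d_iso = d_iso), class = "diffusivity_constants")
}

#' Compartmental relaxation times
#'
#' T1/T2 values used by the relaxation-weighted simulator.  The intra- and
#' extra-cellular pools share a single transverse relaxation time
#' (`t2_in_ex`), the central assumption of the constrained model; CSF has a
#' much longer T2.  T1 values only matter at short repetition times.
#'
#' @param t2_in_ex shared intra/extracellular T2, ms.
#' @param t2_iso CSF T2, ms.
#' @param t1_in,t1_ex,t1_iso longitudinal times, ms.
#' @return object of class `relax_params`.
#' @export
relax_params <- function(t2_in_ex = 70, t2_iso = 1500,
                         t1_in = 1000, t1_ex = 1000, t1_iso = 4000) {
  vals <- c(t2_in_ex, t2_iso, t1_in, t1_ex, t1_iso)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("relaxation times must be positive")
  structure(list(t2_in_ex = t2_in_ex, t2_iso = t2_iso,
                 t1_in = t1_in, t1_ex = t1_ex, t1_iso = t1_iso),
            class = "relax_params")
}

#' Per-voxel tissue parameters
#'
#' Microstructure state of one voxel.  `ndi` is the tissue-normalised
#' intra-neurite fraction f_in / (f_in + f_ex); the absolute fractions are
#' f_in = ndi * (1 - fiso) and f_ex = (1 - ndi) * (1 - fiso), so
#' f_in + f_ex + fiso = 1 by construction.
#'
#' @param ndi tissue-normalised intra-neurite fraction in \[0, 1\].
#' @param odi orientation dispersion index in (0, 1\]; exactly one of `odi`
#'   and `kappa` must be given.
#' @param kappa Watson concentration >= 0.
#' @param fiso isotropic (CSF) signal fraction in \[0, 1\].
#' @param mu unit 3-vector mean neurite axis.
#' @param s0 signal at b = 0, arbitrary units.
#' @return object of class `tissue_params` with fields `f_in`, `f_ex`,
#'   `fiso`, `ndi`, `watson`, `s0`.
#' @export
tissue_params <- function(ndi, odi = NULL, kappa = NULL, fiso = 0,
                          mu = c(0, 0, 1), s0 = 1) {
  if (is.null(kappa) == is.null(odi))
    stop("supply exactly one of odi and kappa")
  if (is.null(kappa)) kappa <- kappa_from_odi(odi)
  if (ndi < 0 || ndi > 1 || fiso < 0 || fiso > 1)
    stop("ndi and fiso must lie in [0, 1]")
  f_in <- ndi * (1 - fiso)
  f_ex <- (1 - ndi) * (1 - fiso)
  structure(list(f_in = f_in, f_ex = f_ex, fiso = fiso, ndi = ndi,
                 watson = watson_params(mu, kappa), s0 = s0),
            class = "tissue_params")
}

#' Isotropic (CSF) compartment attenuation
#'
#' @param b b-value(s), s/mm^2.
#' @param d_iso isotropic diffusivity, mm^2/s.
#' @return exp(-b * d_iso), in (0, 1].
#' @export
signal_iso <- function(b, d_iso = 3.0e-3) {
  if (any(b < 0)) stop("b must be non-negative")
  exp(-b * d_iso)
}

#' Intra-neurite (Watson-dispersed stick) attenuation
#'
#' Spherical average of the stick signal exp(-b d_par (g . n)^2) under the
#' Watson orientation distribution.
#'
#' @param b b-value(s), s/mm^2.
#' @param g unit gradient direction, a 3-vector or an n x 3 matrix matching `b`.
#' @param watson a [watson_params].
#' @param d_par parallel diffusivity, mm^2/s.
#' @return attenuation(s) in (0, 1].
#' @export
signal_intra <- function(b, g, watson, d_par = 1.7e-3) {
  g <- if (is.matrix(g)) g else matrix(g, ncol = 3)
  if (nrow(g) == 1L && length(b) > 1L) g <- g[rep(1, length(b)), , drop = FALSE]
  cosg <- as.vector(g %*% watson$mu)
  .stick_attenuation_cpp(b * d_par, cosg, watson$kappa)
}

#' Extra-neurite (hindered tensor) attenuation
#'
#' The axially symmetric tensor with intrinsic perpendicular diffusivity
#' d_par * (1 - ndi) (tortuosity coupling on the tissue-normalised neurite
#' fraction) is averaged over the Watson distribution *as a tensor* and the
#' Gaussian signal of the mean tensor is returned, matching the convention of
#' the original model this package extends.
#'
#' @inheritParams signal_intra
#' @param ndi tissue-normalised neurite fraction in \[0, 1\].
#' @return attenuation(s) in (0, 1].
#' @export
signal_extra <- function(b, g, watson, d_par = 1.7e-3, ndi = 0.5) {
  if (ndi < 0 || ndi > 1) stop("ndi must lie in [0, 1]")
  g <- if (is.matrix(g)) g else matrix(g, ncol = 3)
  if (nrow(g) == 1L && length(b) > 1L) g <- g[rep(1, length(b)), , drop = FALSE]
  cosg <- as.vector(g %*% watson$mu)
  tau <- watson_second_moment(watson$kappa)
  d_perp <- d_par * (1 - ndi)
  dpar_avg <- d_perp + (d_par - d_perp) * tau
  dperp_avg <- d_perp + (d_par - d_perp) * (1 - tau) / 2
  exp(-b * (dperp_avg + (dpar_avg - dperp_avg) * cosg^2))
}

#' Composite three-compartment attenuation
#'
#' A = f_in * S_in + f_ex * S_ex + fiso * S_iso per volume; equals 1 at every
#' b = 0 volume.
#'
#' @param params a [tissue_params].
#' @param scheme an [acq_scheme].
#' @param consts a [diffusivity_constants].
#' @return attenuation vector, one value per scheme volume.
#' @export
signal_composite <- function(params, scheme, consts = diffusivity_constants()) {
  fsum <- params$f_in + params$f_ex + params$fiso
  if (abs(fsum - 1) > 1e-9)
    stop("signal fractions must sum to 1 (got ", format(fsum), ")")
  a_in <- signal_intra(scheme$bvals, scheme$dirs, params$watson, consts$d_par)
  a_ex <- signal_extra(scheme$bvals, scheme$dirs, params$watson, consts$d_par,
                       params$ndi)
  a_iso <- signal_iso(scheme$bvals, consts$d_iso)
  a <- params$f_in * a_in + params$f_ex * a_ex + params$fiso * a_iso
  a[scheme$bvals == 0] <- 1  # guard against fraction-sum rounding
  a
}

#' Relaxation-weighted signal
#'
#' Full signal with per-compartment T2 decay and T1 saturation:
#' S = s0 * sum_c f_c * exp(-TE/T2_c) * (1 - exp(-TR/T1_c)) * S_D,c.
#' Here the fractions of `params` are interpreted as *volume* fractions.  At
#' long TR the T1 terms vanish; normalising by the tissue-weighted b = 0
#' signal then reproduces the apparent-fraction composite model in which the
#' CSF fraction is inflated by exp(-TE/T2_iso + TE/T2_in_ex) (see
#' [apparent_fiso()]).
#'
#' @param params a [tissue_params] (volume-fraction sense).
#' @param relax a [relax_params].
#' @param scheme an [acq_scheme]; its `echo_time`/`repetition_time` are used.
#' @param consts a [diffusivity_constants].
#' @param s0 signal at TE = 0, TR = Inf, b = 0.
#' @return signal vector, one value per scheme volume.
#' @export
signal_relaxation_weighted <- function(params, relax, scheme,
                                       consts = diffusivity_constants(),
                                       s0 = 1) {
  if (!inherits(relax, "relax_params")) stop("relax must be a relax_params")
  te <- scheme_te(scheme)
  tr <- scheme$repetition_time
  w_in <- params$f_in * exp(-te / relax$t2_in_ex) * (1 - exp(-tr / relax$t1_in))
  w_ex <- params$f_ex * exp(-te / relax$t2_in_ex) * (1 - exp(-tr / relax$t1_ex))
  w_iso <- params$fiso * exp(-te / relax$t2_iso) * (1 - exp(-tr / relax$t1_iso))
  a_in <- signal_intra(scheme$bvals, scheme$dirs, params$watson, consts$d_par)
  a_ex <- signal_extra(scheme$bvals, scheme$dirs, params$watson, consts$d_par,
                       params$ndi)
  a_iso <- signal_iso(scheme$bvals, consts$d_iso)
  s0 * (w_in * a_in + w_ex * a_ex + w_iso * a_iso)
}

#' Apparent isotropic signal fraction at a given echo time
#'
#' With distinct T2 values for tissue and CSF the isotropic *signal* fraction
#' seen at echo time TE exceeds the volume fraction:
#' `fiso * exp(-TE/T2_iso + TE/T2_in_ex)` when the signal is referenced to the
#' tissue T2 weighting, or, with `renormalize = TRUE` (default), the same
#' quantity renormalised so that the three apparent fractions sum to 1 --
#' which is what a model fitted to data normalised by the measured b = 0
#' signal estimates.
#'
#' @param fiso CSF volume fraction in \[0, 1\].
#' @param te echo time, ms.
#' @param relax a [relax_params].
#' @param renormalize return the sum-to-one apparent fraction (default) or the
#'   raw T2-ratio-scaled value.
#' @param tr repetition time in ms.  At the default `Inf` the longitudinal
#'   terms vanish and the closed T2-ratio expression applies exactly; a finite
#'   `tr` additionally weights each compartment by its T1 saturation factor
#'   `1 - exp(-tr/T1)`, matching the full relaxation-weighted generator.
#' @return apparent isotropic fraction; strictly increasing in `te` whenever
#'   `t2_iso > t2_in_ex` and `0 < fiso < 1`.
#' @export
apparent_fiso <- function(fiso, te, relax = relax_params(),
                          renormalize = TRUE, tr = Inf) {
  if (any(fiso < 0 | fiso > 1)) stop("fiso must lie in [0, 1]")
  # tissue saturation uses t1_in; exact whenever t1_in == t1_ex (the presets)
  sat_t <- if (is.finite(tr)) 1 - exp(-tr / relax$t1_in) else 1
  sat_i <- if (is.finite(tr)) 1 - exp(-tr / relax$t1_iso) else 1
  r <- exp(-te / relax$t2_iso + te / relax$t2_in_ex) * sat_i / sat_t
  raw <- fiso * r
  if (!renormalize) return(raw)
  raw / (1 - fiso + raw)
}
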