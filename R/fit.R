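#' Fitting configuration
#'
#' @param model `"cnoddi"` (isotropic fraction supplied per voxel and held
#'   fixed) or `"noddi"` (isotropic fraction estimated along with the tissue
#'   parameters).
#' @param grid_resolution points per parameter axis in the coarse grid stage.
#' @param tol relative objective tolerance of the refinement stage.
#' @param max_iter maximum refinement iterations.
#' @param noise_model `"gaussian_lsq"` (least squares, default) or `"rician"`
#'   (maximum likelihood; the noise level is taken from `sigma`, or estimated
#'   from the least-squares residuals when `sigma` is `NULL`).
#' @param kappa_max upper clamp on the Watson concentration.  ODI below about
#'   0.005 is not resolvable with a 2-shell protocol, so concentrations above
#'   128 are indistinguishable in practice and are clamped to keep the
#'   optimisation bounded.
#' @param seed integer seed (the fit is deterministic; kept for interface
#'   uniformity with the stochastic stages).
#' @param sigma Rician noise standard deviation on the normalised signal
#'   scale, or `NULL` to estimate it.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(model = c("cnoddi", "noddi"), grid_resolution = 8,
                       tol = 1e-6, max_iter = 200,
                       noise_model = c("gaussian_lsq", "rician"),
                       kappa_max = 128, seed = 1, sigma = NULL) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  if (grid_resolution < 2) stop("grid_resolution must be at least 2")
  if (tol <= 0) stop("tol must be positive")
  structure(list(model = model, grid_resolution = grid_resolution, tol = tol,
                 max_iter = max_iter, noise_model = noise_model,
                 kappa_max = kappa_max, seed = seed, sigma = sigma),
            class = "fit_config")
}

#' Initial fibre orientation from a log-linear tensor fit
#'
#' Fits a diffusion tensor to the b = 0 and lowest non-zero shell volumes by
#' log-linear least squares and returns the principal eigenvector (axis,
#' sign-invariant; the returned vector has non-negative z).
#'
#' @param voxel_signal normalised attenuation vector (one per scheme volume).
#' @param scheme an [acq_scheme] with at least 6 distinct low-b directions.
#' @return list with `mu` (unit 3-vector) and `degenerate` (TRUE when the
#'   leading eigenvalue gap is below 1e-9, in which case `mu` is +z).
#' @export
estimate_mean_orientation <- function(voxel_signal, scheme) {
  b <- scheme$bvals
  g <- scheme$dirs
  bpos <- sort(unique(b[b > 0]))
  if (length(bpos) == 0) stop("scheme has no diffusion-weighted volumes")
  use <- b == 0 | b == bpos[1]
  if (sum(b[use] > 0) < 6)
    stop("need at least 6 directions on the lowest shell for the tensor fit")
  s <- pmax(voxel_signal[use], 1e-6)
  bb <- b[use]
  gg <- g[use, , drop = FALSE]
  X <- cbind(1, -bb * gg[, 1]^2, -bb * gg[, 2]^2, -bb * gg[, 3]^2,
             -2 * bb * gg[, 1] * gg[, 2], -2 * bb * gg[, 1] * gg[, 3],
             -2 * bb * gg[, 2] * gg[, 3])
  beta <- qr.solve(X, log(s))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  degenerate <- (e$values[1] - e$values[2]) < 1e-9
  mu <- if (degenerate) c(0, 0, 1) else e$vectors[, 1]
  if (mu[3] < 0 || (mu[3] == 0 && (mu[1] < 0 || (mu[1] == 0 && mu[2] < 0))))
    mu <- -mu
  list(mu = mu, degenerate = degenerate)
}

# spherical angles <-> unit vector
sph_to_vec <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
vec_to_sph <- function(v) c(theta = acos(max(-1, min(1, v[3]))),
                            phi = atan2(v[2], v[1]))

# negative Rician log-likelihood on the normalised signal scale
rician_nll <- function(s, a, sigma) {
  x <- s * a / sigma^2
  sum((s^2 + a^2) / (2 * sigma^2) -
        log(besselI(x, 0, expon.scaled = TRUE)) - x)
}

# coarse grid search over (ndi, kappa[, fiso]) at fixed orientation;
# ties are broken toward the lowest kappa (ascending outer loop + strict <)
grid_stage <- function(s, scheme, mu, fiso_fixed, config, consts) {
  G <- config$grid_resolution
  b <- scheme$bvals
  cosg <- as.vector(scheme$dirs %*% mu)
  ndi_grid <- seq(0.05, 0.95, length.out = G)
  kappa_grid <- sort(kappa_from_odi(seq(0.04, 0.95, length.out = G)))
  kappa_grid <- pmin(kappa_grid, config$kappa_max)
  fiso_grid <- if (is.null(fiso_fixed)) seq(0, 0.95, length.out = G)
               else fiso_fixed
  a_iso <- exp(-b * consts$d_iso)
  best <- list(rss = Inf)
  for (k in seq_along(kappa_grid)) {
    kap <- kappa_grid[k]
    a_in <- .stick_attenuation_cpp(b * consts$d_par, cosg, kap)
    tau <- .watson_tau_cpp(kap)
    d_perp <- consts$d_par * (1 - ndi_grid)
    dpar_avg <- d_perp + (consts$d_par - d_perp) * tau
    dperp_avg <- d_perp + (consts$d_par - d_perp) * (1 - tau) / 2
    # N x G matrix of extracellular attenuations over the ndi grid
    a_ex <- exp(-outer(b, dperp_avg) - outer(b * cosg^2, dpar_avg - dperp_avg))
    tis <- outer(a_in, ndi_grid) + a_ex * rep(1 - ndi_grid, each = length(b))
    for (fiso in fiso_grid) {
      A <- tis * (1 - fiso) + fiso * a_iso
      rss <- colSums((A - s)^2)
      j <- which.min(rss)
      if (rss[j] < best$rss)
        best <- list(rss = rss[j], ndi = ndi_grid[j], kappa = kap, fiso = fiso)
    }
  }
  best
}

# shared voxelwise fit; fiso_fixed = NULL frees the isotropic fraction
fit_voxel <- function(voxel_signal, scheme, config, consts, fiso_fixed = NULL) {
  s <- voxel_signal
  na_result <- list(ndi = NA_real_, fin_raw = NA_real_, odi = NA_real_,
                    kappa = NA_real_, fiso = fiso_fixed %||% NA_real_,
                    mu = c(NA_real_, NA_real_, NA_real_),
                    theta = NA_real_, phi = NA_real_, rss = NA_real_,
                    converged = FALSE, n_iter = 0L, tissue_reliable = FALSE,
                    degenerate = NA)
  if (any(!is.finite(s)) || all(s <= 0)) return(na_result)
  if (!is.null(fiso_fixed)) {
    if (fiso_fixed < 0 || fiso_fixed > 1) stop("fiso must lie in [0, 1]")
    if (fiso_fixed > 0.95) {
      # essentially pure CSF: the bicomponent tissue fit is degenerate
      na_result$fiso <- fiso_fixed
      na_result$rss <- sum((signal_iso(scheme$bvals, consts$d_iso) * fiso_fixed +
                              (1 - fiso_fixed) - s)^2)
      return(na_result)
    }
  }

  init <- estimate_mean_orientation(s, scheme)
  g0 <- grid_stage(s, scheme, init$mu, fiso_fixed, config, consts)
  ang <- vec_to_sph(init$mu)

  b <- scheme$bvals
  dirs <- scheme$dirs
  clamp01 <- function(x, lo = 1e-4) pmin(pmax(x, lo), 1 - lo)
  kmx <- config$kappa_max
  free_fiso <- is.null(fiso_fixed)

  unpack <- function(x) {
    x <- unname(x)
    ndi <- plogis(x[1])
    kappa <- kmx * plogis(x[2])
    fiso <- if (free_fiso) plogis(x[3]) else fiso_fixed
    io <- if (free_fiso) 3L else 2L
    mu <- sph_to_vec(x[io + 1L], x[io + 2L])
    list(ndi = ndi, kappa = kappa, fiso = fiso, mu = mu)
  }
  obj_gauss <- function(x) {
    p <- unpack(x)
    a <- .composite_attenuation_cpp(b, dirs, p$mu, p$ndi, p$fiso, p$kappa,
                                    consts$d_par, consts$d_iso)
    sum((a - s)^2)
  }
  start <- c(qlogis(clamp01(g0$ndi)),
             qlogis(clamp01(g0$kappa / kmx)),
             if (free_fiso) qlogis(clamp01(g0$fiso)),
             ang["theta"], ang["phi"])
  ctl <- list(iter.max = config$max_iter, eval.max = 4L * config$max_iter,
              rel.tol = config$tol)
  opt <- nlminb(start, obj_gauss, control = ctl)
  n_iter <- opt$iterations
  converged <- opt$convergence == 0

  if (config$noise_model == "rician") {
    p0 <- unpack(opt$par)
    a0 <- .composite_attenuation_cpp(b, dirs, p0$mu, p0$ndi, p0$fiso, p0$kappa,
                                     consts$d_par, consts$d_iso)
    sigma <- config$sigma %||%
      sqrt(sum((a0 - s)^2) / max(1, length(s) - length(opt$par)))
    sigma <- max(sigma, 1e-6)
    obj_ric <- function(x) {
      p <- unpack(x)
      a <- .composite_attenuation_cpp(b, dirs, p$mu, p$ndi, p$fiso, p$kappa,
                                      consts$d_par, consts$d_iso)
      rician_nll(s, a, sigma)
    }
    opt2 <- nlminb(opt$par, obj_ric, control = ctl)
    n_iter <- n_iter + opt2$iterations
    converged <- opt2$convergence == 0
    opt$par <- opt2$par
  }

  p <- unpack(opt$par)
  a <- .composite_attenuation_cpp(b, dirs, p$mu, p$ndi, p$fiso, p$kappa,
                                  consts$d_par, consts$d_iso)
  mu <- p$mu
  if (mu[3] < 0) mu <- -mu
  list(ndi = p$ndi, fin_raw = p$ndi * (1 - p$fiso), odi = odi_from_kappa(p$kappa),
       kappa = p$kappa, fiso = p$fiso, mu = mu,
       theta = acos(max(-1, min(1, mu[3]))), phi = atan2(mu[2], mu[1]),
       rss = sum((a - s)^2), converged = converged, n_iter = n_iter,
       tissue_reliable = p$fiso <= 0.95, degenerate = init$degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the unconstrained three-compartment model in one voxel
#'
#' Two-stage estimation of (ndi, kappa, fiso, mu): a coarse grid over the
#' scalar parameters at the tensor-derived orientation, then derivative-based
#' refinement of all parameters through smooth bijections (fractions via
#' logistic maps, concentration via a bounded positive map).  Grid ties are
#' broken toward the lowest concentration.
#'
#' @param voxel_signal attenuation vector normalised by the b = 0 signal.
#' @param scheme an [acq_scheme].
#' @param config a [fit_config].
#' @param consts a [diffusivity_constants].
#' @return list with elements `ndi` (tissue-normalised), `fin_raw`
#'   (= ndi * (1 - fiso)), `odi`, `kappa`, `fiso`, `mu`, `theta`, `phi`,
#'   `rss`, `converged`, `n_iter`, `tissue_reliable` (FALSE when the fitted
#'   isotropic fraction exceeds 0.95), `degenerate`.
#' @export
fit_voxel_noddi <- function(voxel_signal, scheme,
                            config = fit_config("noddi"),
                            consts = diffusivity_constants()) {
  fit_voxel(voxel_signal, scheme, config, consts, fiso_fixed = NULL)
}

#' Fit the constrained model in one voxel
#'
#' As [fit_voxel_noddi()] but with the isotropic signal fraction supplied and
#' held fixed, so only (ndi, kappa, mu) are estimated under the constraint
#' f_in + f_ex = 1 - fiso.  With `fiso = 0` the model reduces exactly to the
#' two-compartment tissue model.  Voxels with `fiso > 0.95` carry too little
#' tissue signal and are returned as missing with `tissue_reliable = FALSE`.
#'
#' @inheritParams fit_voxel_noddi
#' @param fiso isotropic signal fraction in \[0, 1\] for this voxel.
#' @return as [fit_voxel_noddi()]; `fiso` is echoed unchanged.
#' @export
fit_voxel_cnoddi <- function(voxel_signal, scheme, fiso,
                             config = fit_config("cnoddi"),
                             consts = diffusivity_constants()) {
  fit_voxel(voxel_signal, scheme, config, consts, fiso_fixed = fiso)
}

#' Fit a whole volume
#'
#' Applies the voxelwise fit over the mask.  Signals are normalised by the
#' mean of the b = 0 volumes before fitting.  For the constrained model a
#' per-voxel isotropic-fraction map is required (from [segment_fiso()] or an
#' external source) and is echoed unchanged in the output.
#'
#' @param dwi a [dwi_volume].
#' @param config a [fit_config].
#' @param fiso_map 3D array of isotropic fractions (required for
#'   `model = "cnoddi"`, ignored for `"noddi"`).
#' @param consts a [diffusivity_constants].
#' @param verbose print progress.
#' @return object of class `fit_result`: parameter maps `ndi_map`,
#'   `raw_fin_map`, `odi_map`, `kappa_map`, `fiso_map`, `mu_theta_map`,
#'   `mu_phi_map`, plus diagnostics `residual_map`, `converged_map`,
#'   `n_iter_map`, and the `config`/`affine` used.
#' @export
fit_volume <- function(dwi, config = fit_config(), fiso_map = NULL,
                       consts = diffusivity_constants(), verbose = FALSE) {
  if (!inherits(dwi, "dwi_volume")) stop("dwi must be a dwi_volume")
  dims <- dim(dwi$signal)[1:3]
  if (config$model == "cnoddi") {
    if (is.null(fiso_map))
      stop("model 'cnoddi' requires a fiso_map (run segment_fiso or pass --fiso)")
    if (!identical(dim(fiso_map), dims))
      stop("fiso_map dimensions do not match the DWI volume")
  }
  set.seed(config$seed)
  b0_idx <- which(dwi$scheme$bvals == 0)
  nvol <- n_volumes(dwi$scheme)
  sig <- matrix(dwi$signal, prod(dims), nvol)
  vox <- which(dwi$mask)

  empty <- function(val = NA_real_) array(val, dims)
  maps <- list(ndi_map = empty(), raw_fin_map = empty(), odi_map = empty(),
               kappa_map = empty(), fiso_map = empty(),
               mu_theta_map = empty(), mu_phi_map = empty(),
               residual_map = empty(), converged_map = empty(NA),
               n_iter_map = empty())
  for (i in seq_along(vox)) {
    v <- vox[i]
    s0 <- mean(sig[v, b0_idx])
    if (!is.finite(s0) || s0 <= 0) next
    s <- sig[v, ] / s0
    res <- if (config$model == "cnoddi")
      fit_voxel_cnoddi(s, dwi$scheme, fiso_map[v], config, consts)
    else
      fit_voxel_noddi(s, dwi$scheme, config, consts)
    maps$ndi_map[v] <- res$ndi
    maps$raw_fin_map[v] <- res$fin_raw
    maps$odi_map[v] <- res$odi
    maps$kappa_map[v] <- res$kappa
    maps$fiso_map[v] <- res$fiso
    maps$mu_theta_map[v] <- res$theta
    maps$mu_phi_map[v] <- res$phi
    maps$residual_map[v] <- res$rss
    maps$converged_map[v] <- res$converged
    maps$n_iter_map[v] <- res$n_iter
    if (verbose && i %% 200 == 0)
      message("fitted ", i, " / ", length(vox), " voxels")
  }
  structure(c(maps, list(config = config, affine = dwi$affine,
                         mask = dwi$mask)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  n <- sum(!is.na(x$ndi_map))
  cat("Fit result (", x$config$model, "): ", n, " voxels\n", sep = "")
  if (n > 0)
    cat("  median ndi ", signif(stats::median(x$ndi_map, na.rm = TRUE), 3),
        ", median odi ", signif(stats::median(x$odi_map, na.rm = TRUE), 3),
        "\n", sep = "")
  invisible(x)
}

#' Write all maps of a fit result as NIfTI files
#'
#' @param fit a `fit_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fit_result <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(ndi_map = "ndi.nii.gz", raw_fin_map = "fin_raw.nii.gz",
             odi_map = "odi.nii.gz", kappa_map = "kappa.nii.gz",
             fiso_map = "fiso.nii.gz", residual_map = "rss.nii.gz",
             converged_map = "converged.nii.gz")
  for (nm in names(files)) {
    vals <- fit[[nm]]
    if (nm == "converged_map") vals <- array(as.numeric(vals), dim(vals))
    write_map(vals, fit$affine, file.path(out_dir, files[[nm]]))
  }
  invisible(out_dir)
}
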