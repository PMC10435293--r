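#' Gaussian-mixture EM segmentation of a masked 3D image
#'
#' Plain (spatially unregularised) expectation-maximisation for a K-class
#' Gaussian mixture on the voxel intensities inside a mask.  Used as the
#' initial stage of the hidden-Markov-random-field segmentation that estimates
#' the isotropic (CSF) fraction from the T2-weighted b = 0 image.  Classes are
#' ordered by increasing mean; with three classes and T2-weighted contrast the
#' brightest class is CSF.
#'
#' @param intensities 3D numeric array.
#' @param mask logical 3D array; defaults to all finite voxels.
#' @param n_classes number of tissue classes (3 for WM/GM/CSF).
#' @param tol relative log-likelihood tolerance for termination.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed for the k-means initialisation (the result is
#'   deterministic given the seed).
#' @param var_floor minimum class variance as a fraction of the total
#'   intensity variance; degenerate variances are floored with a warning.
#' @return An object of class `seg_result` with elements `class_means`,
#'   `class_vars`, `mixing`, `posteriors` (voxels-in-mask x K), `labels`
#'   (3D integer array, NA outside the mask), `loglik_trace`, `mask`, `dims`,
#'   and the masked intensities `y` (kept for the MRF stage).
#' @export
em_gmm <- function(intensities, mask = NULL, n_classes = 3, tol = 1e-6,
                   max_iter = 100, seed = 1, var_floor = 1e-6) {
  dims <- dim(intensities)
  if (length(dims) != 3L) stop("intensities must be a 3D array")
  if (is.null(mask)) mask <- array(is.finite(intensities), dims)
  if (!any(mask)) stop("mask is empty")
  y <- intensities[mask]
  if (length(unique(y)) < n_classes)
    stop("fewer distinct intensities than classes")

  set.seed(seed)
  # k-means-style initialisation: quantile-spread centres (robust to the very
  # unequal class widths of a b0 image, where CSF is much broader than
  # WM/GM) followed by nearest-centre hard assignment
  ctr0 <- unname(stats::quantile(unique(y),
                                 probs = (2 * seq_len(n_classes) - 1) /
                                   (2 * n_classes)))
  for (it in 1:10) {
    grp <- max.col(-abs(outer(y, ctr0, "-")), ties.method = "first")
    ctr1 <- vapply(seq_len(n_classes), function(k) {
      if (any(grp == k)) mean(y[grp == k]) else ctr0[k]
    }, numeric(1))
    if (max(abs(ctr1 - ctr0)) < 1e-10 * max(abs(ctr1), 1)) break
    ctr0 <- ctr1
  }
  ord <- order(ctr0)
  mu <- ctr0[ord]
  grp <- match(grp, ord)
  floor_val <- var_floor * max(var(y), .Machine$double.eps)
  sg2 <- vapply(seq_len(n_classes), function(k) {
    if (sum(grp == k) > 1) max(var(y[grp == k]), floor_val) else floor_val
  }, numeric(1))
  pifl <- pmax(tabulate(grp, n_classes), 1) / length(y)

  ll_trace <- numeric(0)
  post <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(n_classes),
                   function(k) pifl[k] * dnorm(y, mu[k], sqrt(sg2[k])),
                   numeric(length(y)))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    post <- dens / tot
    nk <- colSums(post)
    mu <- colSums(post * y) / nk
    sg2_new <- colSums(post * (outer(y, mu, "-"))^2) / nk
    if (any(sg2_new < floor_val)) {
      warning("degenerate class variance floored")
      sg2_new <- pmax(sg2_new, floor_val)
    }
    sg2 <- sg2_new
    pifl <- nk / length(y)
    if (it > 1 &&
        abs(ll_trace[it] - ll_trace[it - 1]) <
          tol * (abs(ll_trace[it - 1]) + .Machine$double.eps)) break
  }

  labels <- array(NA_integer_, dims)
  labels[mask] <- max.col(post)
  structure(list(class_means = mu, class_vars = sg2, mixing = pifl,
                 posteriors = post, labels = labels,
                 loglik_trace = ll_trace, mask = mask, dims = dims, y = y,
                 beta = 0, energy_trace = numeric(0)),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat("Segmentation:", length(x$class_means), "classes over", length(x$y),
      "voxels\n")
  cat("  means:", paste(signif(x$class_means, 4), collapse = ", "), "\n")
  cat("  beta:", x$beta, "\n")
  invisible(x)
}

# shift a 3D array by one voxel along a dimension, zero-filled
shift3 <- function(a, dim, by) {
  d <- dim(a)
  out <- array(0L, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[dim]
  if (by == 1L) {
    idx_dst[[dim]] <- 2:n; idx_src[[dim]] <- 1:(n - 1)
  } else {
    idx_dst[[dim]] <- 1:(n - 1); idx_src[[dim]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# per-class neighbour agreement counts and in-mask neighbour totals
neighbour_counts <- function(lab, n_classes) {
  d <- dim(lab)
  same <- array(0L, c(d, n_classes))
  n_nb <- array(0L, d)
  for (dd in 1:3) for (by in c(1L, -1L)) {
    sh <- shift3(lab, dd, by)
    inm <- sh > 0L
    n_nb <- n_nb + inm
    for (k in seq_len(n_classes))
      same[, , , k] <- same[, , , k] + (sh == k)
  }
  list(same = same, n_nb = n_nb)
}

# Potts + Gaussian posterior energy of a labelling
potts_energy <- function(y, lab_vec, lab_arr, mask, mu, sg2, beta) {
  data_term <- -sum(dnorm(y, mu[lab_vec], sqrt(sg2[lab_vec]), log = TRUE))
  nc <- neighbour_counts(lab_arr, length(mu))
  # neighbours whose label differs from the voxel's own label
  same_mat <- matrix(0L, sum(mask), length(mu))
  for (k in seq_along(mu)) same_mat[, k] <- nc$same[, , , k][mask]
  same_own <- same_mat[cbind(seq_along(lab_vec), lab_vec)]
  pair_term <- beta * sum(nc$n_nb[mask] - same_own) / 2
  data_term + pair_term
}

#' Iterated-conditional-modes refinement under a Potts prior
#'
#' Refines the labels of an [em_gmm()] result with a 6-neighbour Potts prior
#' of coupling `beta`, holding the Gaussian class parameters fixed.  Updates
#' proceed in checkerboard order so each sweep cannot increase the posterior
#' energy; `beta = 0` reproduces the maximum-likelihood labels exactly.
#' Posterior probabilities are re-evaluated with the neighbour energy
#' included.
#'
#' @param result a `seg_result` from [em_gmm()].
#' @param beta non-negative MRF coupling (dimensionless).
#' @param n_sweeps number of full ICM sweeps.
#' @return the updated `seg_result`, with `energy_trace` holding the posterior
#'   energy after each sweep (non-increasing).
#' @export
hmrf_icm <- function(result, beta = 1.0, n_sweeps = 5) {
  if (beta < 0) stop("beta must be non-negative")
  K <- length(result$class_means)
  mu <- result$class_means
  sg2 <- result$class_vars
  mask <- result$mask
  d <- result$dims
  y <- result$y
  yarr <- array(0, d); yarr[mask] <- y

  lab <- result$labels
  lab[is.na(lab)] <- 0L
  # ML data cost per class, fixed throughout
  cost_data <- array(Inf, c(d, K))
  for (k in seq_len(K)) {
    ck <- array(Inf, d)
    ck[mask] <- -dnorm(y, mu[k], sqrt(sg2[k]), log = TRUE)
    cost_data[, , , k] <- ck
  }

  parity <- (slice.index(lab, 1) + slice.index(lab, 2) + slice.index(lab, 3)) %% 2L
  energy <- numeric(n_sweeps)
  for (sw in seq_len(n_sweeps)) {
    for (p in 0:1) {
      nc <- neighbour_counts(lab, K)
      total <- array(Inf, c(d, K))
      for (k in seq_len(K))
        total[, , , k] <- cost_data[, , , k] + beta * (nc$n_nb - nc$same[, , , k])
      cost_mat <- matrix(total, prod(d), K)
      best <- max.col(-cost_mat, ties.method = "first")
      upd <- mask & parity == p
      lab[upd] <- best[as.vector(upd)]
    }
    lab_vec <- lab[mask]
    energy[sw] <- potts_energy(y, lab_vec, lab, mask, mu, sg2, beta)
  }

  # MRF-regularised posteriors given the final labelling
  nc <- neighbour_counts(lab, K)
  logp <- matrix(0, length(y), K)
  for (k in seq_len(K))
    logp[, k] <- dnorm(y, mu[k], sqrt(sg2[k]), log = TRUE) -
      beta * (nc$n_nb[mask] - nc$same[, , , k][mask])
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)

  labels <- array(NA_integer_, d)
  labels[mask] <- lab[mask]
  result$labels <- labels
  result$posteriors <- post
  result$beta <- beta
  result$energy_trace <- c(result$energy_trace, energy)
  result
}

#' Isotropic-fraction map from a 3-class segmentation
#'
#' Identifies CSF as the class with the highest mean intensity on the
#' T2-weighted b = 0 image and returns its per-voxel posterior probability as
#' the isotropic signal fraction.  This is a posterior-probability emulation
#' of a partial-volume segmentation, not a re-implementation of one; it is
#' near zero in deep white matter and near one in pure CSF.
#'
#' @param result a 3-class `seg_result`.
#' @return 3D array in \[0, 1\] (NA outside the mask).
#' @export
fiso_from_segmentation <- function(result) {
  if (length(result$class_means) != 3L)
    stop("fiso extraction requires exactly 3 classes (WM, GM, CSF)")
  csf <- which.max(result$class_means)
  fiso <- array(NA_real_, result$dims)
  fiso[result$mask] <- pmin(pmax(result$posteriors[, csf], 0), 1)
  fiso
}

#' Estimate the isotropic fraction from a b = 0 image
#'
#' The full HMRF-EM loop: a seeded EM Gaussian-mixture fit, then `n_sweeps`
#' rounds in which one ICM sweep under the Potts prior is interleaved with a
#' re-estimation of the class means and variances from the regularised
#' posteriors.
#'
#' @param b0 3D array, the T2-weighted b = 0 image.
#' @param mask logical 3D array.
#' @param beta MRF coupling (default 1.0).
#' @param n_sweeps interleaved ICM/parameter-update rounds (default 5).
#' @inheritParams em_gmm
#' @return a `seg_result` with an additional `fiso_map` element.
#' @export
segment_fiso <- function(b0, mask = NULL, beta = 1.0, n_sweeps = 5,
                         n_classes = 3, tol = 1e-6, max_iter = 100, seed = 1) {
  res <- em_gmm(b0, mask = mask, n_classes = n_classes, tol = tol,
                max_iter = max_iter, seed = seed)
  for (sw in seq_len(n_sweeps)) {
    res <- hmrf_icm(res, beta = beta, n_sweeps = 1)
    if (beta > 0) {
      nk <- colSums(res$posteriors)
      res$class_means <- colSums(res$posteriors * res$y) / nk
      res$class_vars <- pmax(
        colSums(res$posteriors * (outer(res$y, res$class_means, "-"))^2) / nk,
        1e-6 * max(var(res$y), .Machine$double.eps))
    }
  }
  res$fiso_map <- fiso_from_segmentation(res)
  res
}
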