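# Brute-force spherical integration oracles, built directly on
# pracma::gaussLegendre and independent of the package's signal kernels.

oracle_grid <- function(order = 64) {
  gl <- pracma::gaussLegendre(order, -1, 1)
  n_az <- 2L * order
  phi <- (seq_len(n_az) - 0.5) * 2 * pi / n_az
  ct <- rep(gl$x, each = n_az)
  st <- sqrt(pmax(0, 1 - ct^2))
  list(nodes = cbind(st * rep(cos(phi), order), st * rep(sin(phi), order), ct),
       weights = rep(gl$w / 2, each = n_az) / n_az)
}

# mean over the sphere of f(n)
oracle_sphere_mean <- function(f, order = 64) {
  q <- oracle_grid(order)
  sum(q$weights * f(q$nodes))
}

# Watson-weighted mean of f(n); the Watson normalisation itself comes from
# the same grid so the oracle is self-contained
oracle_watson_mean <- function(f, mu, kappa, order = 64) {
  q <- oracle_grid(order)
  w <- exp(kappa * as.vector(q$nodes %*% mu)^2)
  sum(q$weights * w * f(q$nodes)) / sum(q$weights * w)
}

# dispersed stick attenuation by brute force
oracle_stick <- function(b, g, mu, kappa, d_par, order = 64) {
  oracle_watson_mean(function(n) exp(-b * d_par * as.vector(n %*% g)^2),
                     mu, kappa, order)
}

# hindered compartment: Watson-average the axially symmetric tensor, then
# take the Gaussian signal of the mean tensor
oracle_hindered <- function(b, g, mu, kappa, d_par, ndi, order = 64) {
  d_perp <- d_par * (1 - ndi)
  q <- oracle_grid(order)
  w <- exp(kappa * as.vector(q$nodes %*% mu)^2)
  w <- q$weights * w / sum(q$weights * w)
  Dbar <- diag(rep(d_perp, 3))
  for (i in seq_along(w))
    Dbar <- Dbar + (d_par - d_perp) * w[i] * tcrossprod(q$nodes[i, ])
  exp(-b * as.numeric(t(g) %*% Dbar %*% g))
}

# seeded random unit vector / rotation matrix
rand_unit <- function(seed) {
  set.seed(seed)
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
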