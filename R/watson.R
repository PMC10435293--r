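#' Watson distribution parameters
#'
#' The Watson distribution is the antipodally symmetric analogue of a Gaussian
#' on the sphere: density proportional to exp(kappa * (mu . n)^2) about a mean
#' axis mu.  kappa = 0 is uniform; large kappa concentrates on +/- mu.
#'
#' @param mu unit 3-vector mean axis (sign-invariant).
#' @param kappa concentration, dimensionless, >= 0.
#' @return object of class `watson_params`.
#' @export
watson_params <- function(mu = c(0, 0, 1), kappa = 1) {
  mu <- as.numeric(mu)
  if (length(mu) != 3 || abs(sqrt(sum(mu^2)) - 1) > 1e-9)
    stop("mu must be a unit 3-vector (within 1e-9)")
  if (!is.finite(kappa) || kappa < 0)
    stop("kappa must be non-negative")
  structure(list(mu = mu, kappa = kappa), class = "watson_params")
}

#' Watson normalisation integral
#'
#' M(kappa) = integral_0^1 exp(kappa t^2) dt, the confluent hypergeometric
#' 1F1(1/2; 3/2; kappa).  Evaluated by fixed-order Gauss-Legendre quadrature,
#' which is accurate to machine precision over the supported range
#' (kappa <= ~700 before overflow; fitting clamps at 128).
#'
#' @param kappa concentration(s) >= 0.
#' @return M(kappa), same length as `kappa`.
#' @export
watson_normalization <- function(kappa) {
  vapply(kappa, function(k) {
    if (k < 0) stop("kappa must be non-negative")
    .watson_m_cpp(k)
  }, numeric(1))
}

#' Watson density on the sphere
#'
#' Density per steradian; integrates to 1 over the full sphere and satisfies
#' W(n) = W(-n).
#'
#' @param direction unit 3-vector (or matrix of row vectors).
#' @param params a [watson_params].
#' @return density value(s).
#' @export
watson_density <- function(direction, params) {
  if (!inherits(params, "watson_params"))
    stop("params must be a watson_params object")
  d <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3)
  if (any(abs(sqrt(rowSums(d^2)) - 1) > 1e-6))
    stop("directions must be unit vectors")
  ct <- as.vector(d %*% params$mu)
  exp(params$kappa * ct^2) / (4 * pi * watson_normalization(params$kappa))
}

#' Map Watson concentration to the orientation dispersion index
#'
#' ODI = (2/pi) * arctan(1/kappa), the convention of the original NODDI
#' toolbox: ODI = 1 at kappa = 0 (uniform) and ODI -> 0 as kappa -> Inf.
#'
#' @param kappa concentration(s) >= 0.
#' @return ODI in (0, 1].
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' Inverse of [odi_from_kappa()]
#'
#' @param odi dispersion index in (0, 1].
#' @return concentration kappa >= 0.
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0 | odi > 1)) stop("odi must lie in (0, 1]")
  ifelse(odi == 1, 0, 1 / tan(odi * pi / 2))
}

#' Watson second moment about the mean axis
#'
#' E\[(mu . n)^2\] under Watson(kappa): 1/3 at kappa = 0, increasing to 1 as the
#' distribution concentrates.  Computed from the closed form
#' exp(kappa) / (2 kappa M(kappa)) - 1 / (2 kappa), with a series expansion
#' near zero for numerical stability.
#'
#' @param kappa concentration(s) >= 0.
#' @return value(s) in \[1/3, 1).
#' @export
watson_second_moment <- function(kappa) {
  vapply(kappa, function(k) {
    if (k < 0) stop("kappa must be non-negative")
    .watson_tau_cpp(k)
  }, numeric(1))
}

# orders for which product spherical quadrature rules are provided
.quad_orders <- c(4L, 8L, 16L, 24L, 32L, 48L, 64L, 96L, 128L)

#' Spherical quadrature rule
#'
#' Product rule combining Gauss-Legendre nodes in the polar cosine with a
#' uniform azimuthal grid (2 * order points).  Weights are positive and sum to
#' 1 (mean-over-sphere convention), constants are integrated exactly, and the
#' rule is exact for spherical polynomials up to high degree.
#'
#' @param order polar order, one of 4, 8, 16, 24, 32, 48, 64, 96, 128.
#' @return list with `nodes` (n x 3 unit vectors) and `weights` (sum 1).
#' @export
sphere_quadrature <- function(order = 64) {
  if (!order %in% .quad_orders)
    stop("unsupported quadrature order ", order, "; choose one of ",
         paste(.quad_orders, collapse = ", "))
  gl <- pracma::gaussLegendre(order, -1, 1)
  n_az <- 2L * order
  phi <- (seq_len(n_az) - 0.5) * 2 * pi / n_az
  ct <- rep(gl$x, each = n_az)
  st <- sqrt(pmax(0, 1 - ct^2))
  cp <- rep(cos(phi), times = order)
  sp <- rep(sin(phi), times = order)
  nodes <- cbind(st * cp, st * sp, ct)
  weights <- rep(gl$w / 2, each = n_az) / n_az
  list(nodes = nodes, weights = weights)
}

#' Integrate a function over the sphere
#'
#' @param f function taking an n x 3 matrix of unit vectors, returning n values.
#' @param order quadrature order, see [sphere_quadrature()].
#' @return mean-over-sphere of f times 4*pi, i.e. the surface integral divided
#'   by 4*pi is the mean; here the *mean* is returned (multiply by 4*pi for the
#'   surface integral).
#' @export
sphere_mean <- function(f, order = 64) {
  q <- sphere_quadrature(order)
  sum(q$weights * f(q$nodes))
}
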