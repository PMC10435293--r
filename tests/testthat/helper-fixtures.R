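# study protocol scheme (b = 0/700/2000, 32 directions per shell), built once
std_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- build_scheme(c(0, 700, 2000), c(1, 32, 32),
                                           seed = 1)
    sch
  }
})

# small rectangular parameter-map set for volume fits (not via phantom_spec,
# which enforces a minimum size for its rim structure)
tiny_maps <- function(nx = 6, ny = 6, nz = 2, ndi = 0.6, odi = 0.2,
                      fiso = 0.1, b0 = 500) {
  d <- c(nx, ny, nz)
  mu <- array(0, c(d, 3)); mu[, , , 3] <- 1
  list(ndi = array(ndi, d), odi = array(odi, d),
       kappa = array(kappa_from_odi(odi), d), fiso = array(fiso, d),
       mu = mu, b0 = array(b0, d), mask = array(TRUE, d))
}
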