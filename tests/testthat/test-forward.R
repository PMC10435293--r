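test_that("isotropic compartment is the closed-form exponential", {
  expect_equal(signal_iso(0), 1)
  expect_equal(signal_iso(2000, 3.0e-3), exp(-6), tolerance = 1e-12)
  expect_true(all(diff(signal_iso(c(0, 700, 2000))) < 0))
  expect_error(signal_iso(-5), "non-negative")
})

test_that("stick attenuation has the undispersed and uniform limits", {
  d_par <- 1.7e-3
  wz <- watson_params(c(0, 0, 1), 128)   # fitting clamp ~ delta on the axis
  par_ <- signal_intra(2000, c(0, 0, 1), wz, d_par)
  expect_lt(abs(par_ - exp(-3.4)), 2e-3)
  perp <- signal_intra(2000, c(1, 0, 0), wz, d_par)
  expect_equal(perp, 1, tolerance = 2e-2)
  # kappa = 0: orientational average reduces to a 1D integral
  w0 <- watson_params(c(0, 0, 1), 0)
  got <- signal_intra(2000, c(1, 0, 0), w0, d_par)
  ref <- pracma::integral(function(t) exp(-2000 * d_par * t^2), 0, 1)
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("hindered compartment closes to free diffusion and to 1 at b = 0", {
  w <- watson_params(c(0, 0, 1), 4)
  g <- rand_unit(11)
  expect_equal(signal_extra(700, g, w, 1.7e-3, ndi = 0), exp(-700 * 1.7e-3),
               tolerance = 1e-12)
  expect_equal(signal_extra(0, g, w, 1.7e-3, ndi = 0.6), 1)
  # quadrature oracle at the example operating point (45 degrees to the axis)
  g45 <- c(sin(pi / 4), 0, cos(pi / 4))
  got <- signal_extra(700, g45, w, 1.7e-3, ndi = 0.6)
  ref <- oracle_hindered(700, g45, c(0, 0, 1), 4, 1.7e-3, 0.6)
  expect_equal(got, ref, tolerance = 1e-4)
})

test_that("composite signal is the exact convex combination of compartments", {
  sch <- std_scheme()
  consts <- diffusivity_constants()
  tp <- tissue_params(ndi = 0.6, odi = 0.2, fiso = 0.1)
  a <- signal_composite(tp, sch, consts)
  by_hand <- tp$f_in * signal_intra(sch$bvals, sch$dirs, tp$watson, consts$d_par) +
    tp$f_ex * signal_extra(sch$bvals, sch$dirs, tp$watson, consts$d_par, tp$ndi) +
    tp$fiso * signal_iso(sch$bvals, consts$d_iso)
  expect_lt(max(abs(a - by_hand)), 1e-12)
  expect_true(all(a > 0 & a <= 1))
  expect_equal(a[sch$bvals == 0], 1)
  # pure CSF and pure extracellular reductions
  csf <- tissue_params(ndi = 0, kappa = 0, fiso = 1)
  expect_lt(max(abs(signal_composite(csf, sch, consts) -
                      signal_iso(sch$bvals, consts$d_iso))), 1e-12)
  ex <- tissue_params(ndi = 0, kappa = 2, fiso = 0)
  expect_lt(max(abs(signal_composite(ex, sch, consts) -
                      signal_extra(sch$bvals, sch$dirs, ex$watson,
                                   consts$d_par, 0))), 1e-12)
  # tampered fractions are rejected
  bad <- tp; bad$f_in <- bad$f_in + 0.05
  expect_error(signal_composite(bad, sch, consts), "sum to 1")
})

test_that("signals are invariant under joint rotation of gradients and axis", {
  sch <- build_scheme(c(0, 700, 2000), c(1, 8, 8), seed = 3)
  tp <- tissue_params(ndi = 0.55, odi = 0.3, fiso = 0.12, mu = rand_unit(21))
  base <- signal_composite(tp, sch)
  for (s in 1:5) {
    R <- rand_rotation(100 + s)
    sch_r <- sch
    sch_r$dirs <- sch$dirs %*% t(R)
    tp_r <- tissue_params(ndi = 0.55, odi = 0.3, fiso = 0.12,
                          mu = as.vector(R %*% tp$watson$mu))
    expect_lt(max(abs(signal_composite(tp_r, sch_r) - base)), 1e-10)
  }
})

test_that("relaxation weighting vanishes at TE ~ 0 and long TR", {
  sch <- build_scheme(c(0, 700, 2000), c(1, 6, 6), seed = 5,
                      echo_time = 1e-9, repetition_time = 1e9)
  relax <- relax_params()
  tp <- tissue_params(ndi = 0.6, odi = 0.25, fiso = 0.15)
  s <- signal_relaxation_weighted(tp, relax, sch, s0 = 2.5)
  plain <- 2.5 * signal_composite(tp, sch)
  expect_lt(max(abs(s - plain)), 1e-6)
})

test_that("equal compartmental T2 cancels on normalisation", {
  relax_eq <- relax_params(t2_in_ex = 80, t2_iso = 80)
  tp <- tissue_params(ndi = 0.6, odi = 0.25, fiso = 0.15)
  norm_at <- function(te) {
    sch <- build_scheme(c(0, 700, 2000), c(1, 6, 6), seed = 5, echo_time = te)
    s <- signal_relaxation_weighted(tp, relax_eq, sch)
    s / s[1]
  }
  expect_lt(max(abs(norm_at(78) - norm_at(120))), 1e-10)
})

test_that("apparent isotropic fraction follows the T2-ratio expression", {
  relax <- relax_params(t2_in_ex = 70, t2_iso = 1500)
  tp <- tissue_params(ndi = 0.6, odi = 0.25, fiso = 0.1)
  for (te in c(78, 90, 100, 120)) {
    # TR far beyond every T1, the regime in which the closed form is exact
    sch <- build_scheme(c(0, 700, 2000), c(1, 6, 6), seed = 5, echo_time = te,
                        repetition_time = 1e9)
    s <- signal_relaxation_weighted(tp, relax, sch)
    # decompose the measured b0 into tissue and CSF weights
    w_t <- (tp$f_in + tp$f_ex) * exp(-te / relax$t2_in_ex)
    w_i <- tp$fiso * exp(-te / relax$t2_iso)
    expect_equal(s[1], w_t + w_i, tolerance = 1e-10)
    expect_equal(w_i / (w_t + w_i), apparent_fiso(0.1, te, relax),
                 tolerance = 1e-10)
    # referencing to the tissue T2 weighting gives the raw expression
    expect_equal(w_i / exp(-te / relax$t2_in_ex),
                 apparent_fiso(0.1, te, relax, renormalize = FALSE),
                 tolerance = 1e-10)
  }
  fapp <- apparent_fiso(0.1, c(78, 90, 100, 120), relax)
  expect_true(all(diff(fapp) > 0))
})
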