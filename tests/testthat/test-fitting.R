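test_that("tensor initialisation recovers the fibre axis", {
  sch <- std_scheme()
  tp <- tissue_params(ndi = 0.6, kappa = 16, fiso = 0, mu = c(0, 0, 1))
  a <- signal_composite(tp, sch)
  est <- estimate_mean_orientation(a, sch)
  expect_false(est$degenerate)
  expect_lt(acos(min(abs(sum(est$mu * c(0, 0, 1))), 1)) * 180 / pi, 2)
  # isotropic voxel flags degeneracy and falls back to +z
  iso <- signal_iso(sch$bvals)
  est_iso <- estimate_mean_orientation(iso, sch)
  expect_true(est_iso$degenerate)
  expect_equal(est_iso$mu, c(0, 0, 1))
  # stable under noise: 20 seeded repeats stay within a few degrees
  tp2 <- tissue_params(ndi = 0.6, kappa = 16, fiso = 0, mu = c(0, 0, 1))
  a2 <- signal_composite(tp2, sch)
  angs <- vapply(1:20, function(i) {
    s <- add_noise(a2, sd = 1 / 30, "rician", seed = 400 + i)
    e <- estimate_mean_orientation(s, sch)
    acos(min(abs(sum(e$mu * c(0, 0, 1))), 1)) * 180 / pi
  }, numeric(1))
  expect_lt(max(angs), 5)
  expect_lt(median(angs), 2)
})

test_that("constrained fit recovers noiseless voxels almost exactly", {
  sch <- std_scheme()
  cases <- list(c(0.6, 0.2, 0.1), c(0.4, 0.5, 0.3), c(0.75, 0.1, 0.05))
  for (cs in cases) {
    tp <- tissue_params(ndi = cs[1], odi = cs[2], fiso = cs[3],
                        mu = rand_unit(31))
    a <- signal_composite(tp, sch)
    r <- fit_voxel_cnoddi(a, sch, fiso = cs[3])
    expect_lt(abs(r$ndi - cs[1]), 0.005)
    expect_lt(abs(r$odi - cs[2]), 0.005)
    expect_identical(r$fiso, cs[3])
  }
})

test_that("unconstrained fit recovers noiseless voxels", {
  sch <- std_scheme()
  tp <- tissue_params(ndi = 0.6, kappa = 4, fiso = 0.1)
  a <- signal_composite(tp, sch)
  r <- fit_voxel_noddi(a, sch)
  expect_lt(abs(r$ndi - 0.6), 0.01)
  expect_lt(abs(r$odi - odi_from_kappa(4)), 0.01)
  expect_lt(abs(r$fiso - 0.1), 0.02)
  expect_equal(r$fin_raw, r$ndi * (1 - r$fiso))
})

test_that("degenerate CSF voxels are flagged by both models", {
  sch <- std_scheme()
  csf <- signal_iso(sch$bvals)
  rn <- fit_voxel_noddi(csf, sch)
  expect_gte(rn$fiso, 0.95)
  expect_false(rn$tissue_reliable)
  rc <- fit_voxel_cnoddi(csf, sch, fiso = 1)
  expect_true(is.na(rc$ndi))
  expect_false(rc$tissue_reliable)
  expect_identical(rc$fiso, 1)
})

test_that("the two models agree on a CSF-free voxel", {
  sch <- std_scheme()
  tp <- tissue_params(ndi = 0.62, odi = 0.25, fiso = 0)
  a <- signal_composite(tp, sch)
  rn <- fit_voxel_noddi(a, sch)
  rc <- fit_voxel_cnoddi(a, sch, fiso = 0)
  expect_lt(abs(rn$ndi - rc$ndi), 0.01)
  expect_lt(abs(rn$odi - rc$odi), 0.01)
  expect_lt(rn$fiso, 0.02)
})

test_that("the free isotropic fraction overshoots under a T2 mismatch", {
  # data carry more apparent CSF signal than the volume fraction because
  # CSF decays much more slowly over the echo time
  sch <- std_scheme()
  relax <- relax_params(t2_in_ex = 70, t2_iso = 1500)
  tp <- tissue_params(ndi = 0.6, odi = 0.2, fiso = 0.1)
  S <- signal_relaxation_weighted(tp, relax, sch)
  fis <- vapply(1:40, function(i) {
    sn <- add_noise(S, sd = S[1] / 30, "rician", seed = 600 + i)
    fit_voxel_noddi(sn / sn[1], sch)$fiso
  }, numeric(1))
  expect_gt(median(fis), 0.1)
})

test_that("volume fit recovers a noiseless phantom and is deterministic", {
  maps <- tiny_maps(6, 6, 2, ndi = 0.6, odi = 0.2, fiso = 0.1)
  sch <- std_scheme()
  dwi <- simulate_dwi(maps, sch, noise_model = "none")
  cfg <- fit_config("cnoddi", seed = 7)
  fit1 <- fit_volume(dwi, cfg, fiso_map = maps$fiso)
  expect_lt(max(abs(fit1$ndi_map - 0.6)), 0.01)
  expect_identical(fit1$fiso_map, maps$fiso)  # echoed exactly
  expect_true(all(fit1$converged_map))
  fit2 <- fit_volume(dwi, cfg, fiso_map = maps$fiso)
  expect_identical(fit1$ndi_map, fit2$ndi_map)
  expect_identical(fit1$odi_map, fit2$odi_map)
  # configuration errors and the empty mask edge case
  expect_error(fit_volume(dwi, fit_config("cnoddi")), "fiso_map")
  dwi0 <- dwi; dwi0$mask <- array(FALSE, dim(maps$ndi))
  f0 <- fit_volume(dwi0, cfg, fiso_map = maps$fiso)
  expect_true(all(is.na(f0$ndi_map)))
})
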