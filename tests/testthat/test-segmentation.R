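test_that("EM recovers a single class and a separated 3-class mixture", {
  set.seed(1)
  d <- c(10, 10, 10)
  y1 <- array(100 + rnorm(prod(d), sd = 0.1), d)
  r1 <- em_gmm(y1, n_classes = 1, seed = 1)
  expect_equal(r1$class_means, mean(y1), tolerance = 1e-6)

  set.seed(2)
  truth <- sample(1:3, prod(d) * 10, replace = TRUE)
  mu_t <- c(100, 200, 600)
  y3 <- array(rnorm(length(truth), mu_t[truth], 20), c(10, 10, 100))
  r3 <- em_gmm(y3, n_classes = 3, seed = 1)
  for (k in 1:3) {
    nk <- sum(truth == k)
    expect_lt(abs(r3$class_means[k] - mu_t[k]), 3 * 20 / sqrt(nk))
  }
  # posteriors are a proper probability table
  expect_true(all(r3$posteriors >= 0))
  expect_lt(max(abs(rowSums(r3$posteriors) - 1)), 1e-9)
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(3)
  y <- array(rnorm(4000, rep(c(0, 5), each = 2000)), c(20, 20, 10))
  r <- em_gmm(y, n_classes = 2, seed = 2, tol = 0, max_iter = 40)
  expect_true(all(diff(r$loglik_trace) > -1e-8))
  expect_error(em_gmm(array(1, c(4, 4, 4)), mask = array(FALSE, c(4, 4, 4))),
               "empty")
})

test_that("ICM with beta 0 keeps maximum-likelihood labels", {
  set.seed(4)
  y <- array(rnorm(2000, rep(c(0, 6), each = 1000)), c(10, 10, 20))
  r <- em_gmm(y, n_classes = 2, seed = 1)
  r0 <- hmrf_icm(r, beta = 0, n_sweeps = 3)
  expect_identical(r0$labels, r$labels)
})

test_that("ICM corrects implanted contrarian labels and lowers energy", {
  # two homogeneous blocks; a sprinkling of voxels is given an ambiguous
  # intensity slightly favouring the wrong class, so only the spatial prior
  # can fix them
  d <- c(12, 12, 6)
  half <- array(rep(c(1L, 2L), each = prod(d) / 2), d)
  set.seed(5)
  y <- array(rnorm(prod(d), c(100, 200)[half], 10), d)
  # flips on one checkerboard parity are mutually non-adjacent; restrict to
  # the homogeneous interior, away from the class boundary at z = 3|4
  idx <- arrayInd(which(half == 1L), d)
  ok <- rowSums(idx) %% 2 == 0 & idx[, 1] %in% 2:11 & idx[, 2] %in% 2:11 &
    idx[, 3] <= 2
  par0 <- which(half == 1L)[ok]
  flip <- sample(par0, round(0.05 * sum(half == 1L)))
  y[flip] <- 155  # marginally closer to class 2
  mask <- array(TRUE, d)
  res <- structure(list(class_means = c(100, 200), class_vars = c(100, 100),
                        mixing = c(0.5, 0.5), posteriors = NULL,
                        labels = NULL, loglik_trace = numeric(0),
                        mask = mask, dims = d, y = y[mask], beta = 0,
                        energy_trace = numeric(0)),
                   class = "seg_result")
  ml <- 1L + (dnorm(y, 200, 10) > dnorm(y, 100, 10))
  res$labels <- array(as.integer(ml), d)
  expect_true(all(res$labels[flip] == 2L))  # ML gets them wrong
  out <- hmrf_icm(res, beta = 1.5, n_sweeps = 5)
  expect_gte(mean(out$labels[flip] == 1L), 0.9)
  expect_true(all(diff(out$energy_trace) <= 1e-8))
})

test_that("isotropic fraction from the phantom segmentation is accurate", {
  ph <- make_phantom()
  b0 <- add_noise(ph$b0, sd = ph$b0 / 30, "rician", seed = 7)
  seg <- segment_fiso(b0, beta = 1.0, seed = 3)
  expect_equal(length(seg$class_means), 3L)
  fiso <- seg$fiso_map
  expect_true(all(fiso >= 0 & fiso <= 1, na.rm = TRUE))
  # pure CSF voxels carry fractions near one
  expect_gte(min(fiso[ph$labels == 3L]), 0.95)
  # near zero in the deep white matter core
  expect_lt(median(fiso[ph$deep_wm]), 0.02)
  # voxelwise error in pure-tissue voxels
  pure <- ph$labels %in% c(1L, 2L)
  expect_lt(mean(abs(fiso[pure] - ph$fiso[pure])), 0.05)
  expect_error(fiso_from_segmentation(em_gmm(b0, n_classes = 2, seed = 1)),
               "3 classes")
})
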