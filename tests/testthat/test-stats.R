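test_that("roi means are exact on constructed maps", {
  lab <- array(rep(1:2, each = 4), c(2, 2, 2))
  m <- array(0.5, c(2, 2, 2))
  expect_equal(unname(roi_means(m, lab)), c(0.5, 0.5))
  m2 <- array(c(0.2, 0.6, rep(NA, 6)), c(2, 2, 2))
  lab2 <- array(c(1L, 1L, rep(0L, 6)), c(2, 2, 2))
  expect_warning(r <- roi_means(m2, array(c(1L, 1L, 2L, rep(0L, 5)),
                                          c(2, 2, 2))), "no usable")
  expect_equal(unname(r[1]), 0.4)
  expect_true(is.na(r[2]))
})

test_that("quadratic age fit interpolates an exact parabola", {
  set.seed(6)
  n <- 40
  age <- seq(20, 80, length.out = n)
  sex <- rep(c(0, 1), n / 2)
  ma <- mean(age)
  y <- 0.6 - 2e-5 * (age - 45)^2 + 0.01 * sex
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n), roi = "WB",
                    age = age, sex = sex, mean_ndi = y)
  rep_ <- quadratic_age_fit(tab, "ndi")
  # reconstruct the generating coefficients in centred coordinates
  expect_equal(rep_$beta_age2, -2e-5, tolerance = 1e-10)
  expect_equal(rep_$beta_age, -2 * 2e-5 * (ma - 45), tolerance = 1e-10)
  expect_equal(rep_$beta_sex, 0.01, tolerance = 1e-10)
  expect_equal(rep_$peak_age, 45, tolerance = 1e-6)
  # beta_age = 0 with concavity puts the peak at the cohort mean age
  tab$mean_ndi <- 0.6 - 2e-5 * (tab$age - ma)^2
  expect_equal(quadratic_age_fit(tab, "ndi")$peak_age, ma, tolerance = 1e-6)
  # convex fit reports no peak
  tab$mean_ndi <- 0.6 + 2e-5 * (tab$age - ma)^2
  expect_true(is.na(quadratic_age_fit(tab, "ndi")$peak_age))
  # collinear design names the culprit
  tab$sex <- 0
  expect_error(quadratic_age_fit(tab, "ndi"), "sex")
})

test_that("OLS agrees with a normal-equations oracle on a small fixture", {
  set.seed(7)
  n <- 10
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n), roi = "WB",
                    age = runif(n, 20, 80), sex = rep(c(0, 1), 5),
                    mean_ndi = runif(n, 0.4, 0.7))
  rep_ <- quadratic_age_fit(tab, "ndi")
  ac <- tab$age - mean(tab$age)
  X <- cbind(1, ac, ac^2, tab$sex)
  beta <- solve(t(X) %*% X, t(X) %*% tab$mean_ndi)
  expect_equal(c(rep_$intercept, rep_$beta_age, rep_$beta_age2, rep_$beta_sex),
               as.vector(beta), tolerance = 1e-8)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
               rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5))$p_adjusted, rep(0.2, 5))
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    adj <- fdr_adjust(p)$p_adjusted
    expect_equal(adj, bh_brute(p))
    expect_true(all(diff(adj[order(p)]) > -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_length(fdr_adjust(numeric(0))$p_adjusted, 0)
})

test_that("peak age is recovered from simulated cohorts", {
  peaks <- vapply(1:20, function(i) {
    tab <- make_cohort(n_subjects = 200, peak_age = 42, curvature = -1e-5,
                       noise_sd = 0.01, seed = 300 + i, rois = "WB",
                       nfl = FALSE)
    quadratic_age_fit(tab, "ndi")$peak_age
  }, numeric(1))
  expect_lt(abs(median(peaks) - 42), 3)
})

test_that("NfL association finds the built-in negative coupling", {
  tab <- make_cohort(n_subjects = 200, seed = 11)
  r <- nfl_association(tab, "WB")
  expect_lt(r$beta_ndi, 0)
  expect_lt(r$p_ndi, 0.05)
  # z-scores standardise exactly
  d <- tab[tab$roi == "WB", ]
  z <- (log(d$nfl) - mean(log(d$nfl))) / sd(log(d$nfl))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # non-positive NfL excluded with a warning
  d2 <- tab; d2$nfl[1] <- -1
  expect_warning(nfl_association(d2, "WB"), "excluded")
  # null coupling: the confidence interval covers zero at the nominal rate
  cover <- vapply(1:100, function(i) {
    t0 <- make_cohort(n_subjects = 80, nfl_coupling = 0, seed = 5000 + i,
                      rois = "WB")
    f <- lm(scale(log(nfl)) ~ scale(mean_ndi) + age + sex,
            data = t0[t0$roi == "WB", ])
    ci <- confint(f)[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
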