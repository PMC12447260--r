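test_that("reduced chi-squared closed forms", {
  expect_equal(reduced_chi2(rep(0, 10), rep(1, 10), 3), 0)
  sg <- runif(20, 0.5, 2)
  expect_equal(reduced_chi2(sg, sg, 6), 20 / (20 - 6), tolerance = 1e-12)
  expect_error(reduced_chi2(rep(1, 3), rep(1, 3), 3),
               class = "steamdiff_domain_error")
})

test_that("noiseless recovery is exact for every successful multi-start", {
  d <- generate_dataset(group_preset("control"))
  f <- fit_two_pool(d, n_starts = 8, seed = 5)
  truth <- group_preset("control")$params
  for (nm in c("m_i0", "r", "k_ie", "d_e_app", "s0", "r1_e")) {
    expect_lt(abs(f$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
  }
  # r1_i is non-identifiable: the truth is 0 and the estimate must be ~0
  expect_lt(f$params$r1_i, 0.01)
  # every start that reached (near-)zero objective recovered the optimum
  ok <- f$starts$deviance < 1e-6
  expect_gte(sum(ok), 1)
  expect_true(all(f$starts$deviance[ok] >= f$objective - 1e-9))
})

test_that("fit is invariant to joint rescaling of signal and sigma", {
  d <- generate_dataset(group_preset("apoptotic"),
                        noise = noise_spec("gaussian", snr = 80, seed = 2))
  f1 <- fit_two_pool(d, n_starts = 6, seed = 3)
  scale <- 37.5
  d2 <- signal_dataset(d$protocol, d$signal * scale, d$sigma * scale,
                       group = d$group, sample_id = d$sample_id)
  f2 <- fit_two_pool(d2, n_starts = 6, seed = 3)
  expect_equal(f2$params$s0 / f1$params$s0, scale, tolerance = 1e-3)
  for (nm in c("m_i0", "r", "k_ie", "d_e_app", "r1_e")) {
    expect_equal(f2$params[[nm]], f1$params[[nm]], tolerance = 1e-3)
  }
  expect_equal(f2$chi2_reduced, f1$chi2_reduced, tolerance = 1e-6)
})

test_that("single-pool data leaves the exchange rate unidentifiable and flagged", {
  p1 <- suppressWarnings(
    two_pool_params(r = 4.2, k_ie = 4, m_i0 = 1, d_e_app = 0.95, r1_e = 2.9))
  d <- generate_dataset(list(name = "control", params = p1))
  f <- fit_two_pool(d, n_starts = 6, seed = 2)
  expect_true("k_ie" %in% unlist(f$flags))
  expect_gt(f$params$m_i0, 0.999)
})

test_that("fit validates its preconditions", {
  pr <- acquisition_protocol(b = c(0, 1000, 3000, 5000), delta_sep = 80)
  d <- signal_dataset(pr, signal = c(1, 0.8, 0.5, 0.3), sigma = 0.01)
  expect_error(fit_two_pool(d), class = "steamdiff_validation_error")
  d2 <- generate_dataset(group_preset("control"))
  expect_error(fit_two_pool(d2, fixed = list(bogus = 1)),
               class = "steamdiff_validation_error")
})

test_that("contour interval matches the analytic F ellipse on a linear model", {
  set.seed(31)
  n <- 40
  X <- cbind(1, seq(0, 1, length.out = n), runif(n))
  beta_true <- c(1, 2, -0.5)
  sigma <- 0.1
  y <- as.numeric(X %*% beta_true) + rnorm(n, 0, sigma)
  bhat <- as.numeric(solve(crossprod(X), crossprod(X, y)))
  resid_fn <- function(th) (as.numeric(X %*% th) - y) / sigma
  ssr0 <- sum(resid_fn(bhat)^2)
  nP <- 3
  dof <- n - nP
  conf <- 0.68
  threshold <- (ssr0 / dof) * (1 + nP / dof * qf(conf, nP, dof))
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10, maxiter = 200)
  lower <- rep(-100, 3)
  upper <- rep(100, 3)
  XtX_inv <- solve(crossprod(X))
  for (idx in c(2, 3)) {
    # profiled objective: obj0 + (delta^2) / (sigma^2 h_ii), h = (X'X)^-1
    half_analytic <- sqrt(XtX_inv[idx, idx] * sigma^2 * ssr0 *
                            nP / dof * qf(conf, nP, dof))
    up <- steamdiff:::.profile_bound(resid_fn, bhat, idx, +1, threshold,
                                     lower, upper, dof, ctl)
    lo <- steamdiff:::.profile_bound(resid_fn, bhat, idx, -1, threshold,
                                     lower, upper, dof, ctl)
    expect_false(up$open)
    expect_false(lo$open)
    expect_equal(up$bound - bhat[idx], half_analytic, tolerance = 0.01)
    expect_equal(bhat[idx] - lo$bound, half_analytic, tolerance = 0.01)
  }
})

test_that("contour intervals collapse on noiseless data and cover the truth on noisy data", {
  d <- generate_dataset(group_preset("control"))
  f <- fit_two_pool(d, n_starts = 6, seed = 1)
  ci <- contour_interval(f, d, c("m_i0", "k_ie"), confidence = 0.68,
                         n_grid = 0)
  expect_lt(diff(ci$interval["m_i0", ]), 1e-3)
  expect_lt(diff(ci$interval["k_ie", ]), 1e-2)
  expect_true(all(ci$interval["m_i0", 1] <= 0.55,
                  0.55 <= ci$interval["m_i0", 2]))

  covered <- 0
  seeds <- 1:5
  for (sd_i in seeds) {
    dn <- generate_dataset(group_preset("control"),
                           noise = noise_spec("rician", snr = 50, seed = sd_i))
    fn <- fit_two_pool(dn, n_starts = 6, seed = 1)
    cin <- contour_interval(fn, dn, c("m_i0", "k_ie"), confidence = 0.95,
                            n_grid = 0)
    if (cin$interval["m_i0", 1] <= 0.55 && 0.55 <= cin$interval["m_i0", 2]) {
      covered <- covered + 1
    }
  }
  # 95% coverage with binomial slack over 5 seeds
  expect_gte(covered, 4)
})
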