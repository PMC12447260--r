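test_that("detailed balance gives the expected reverse rate", {
  expect_equal(k_ei_from_balance(4.0, 0.55), 4.888889, tolerance = 1e-6)
  expect_equal(two_pool_params(r = 4.2, k_ie = 4, m_i0 = 0.55,
                               d_e_app = 0.95)$k_ei,
               4 * 0.55 / 0.45, tolerance = 1e-12)
  expect_warning(k_ei_from_balance(4, 1), "exchange disabled")
  expect_equal(suppressWarnings(k_ei_from_balance(4, 1)), 0)
})

test_that("the generator conserves magnetization under pure exchange", {
  p0 <- two_pool_params(r = 4.2, k_ie = 0, m_i0 = 0.55, d_e_app = 0.95)
  A0 <- karger_generator(p0, q = 0, t_d = 100, include_relaxation = FALSE)
  expect_equal(A0, matrix(0, 2, 2))
  set.seed(42)
  for (i in 1:20) {
    p <- random_two_pool_params()
    A <- karger_generator(p, q = 0, t_d = runif(1, 5, 800),
                          include_relaxation = FALSE)
    expect_equal(colSums(A), c(0, 0), tolerance = 1e-15)
    # equilibrium fractions are stationary under the exchange generator
    expect_equal(as.numeric(A %*% c(p$m_i0, 1 - p$m_i0)), c(0, 0),
                 tolerance = 1e-15)
  }
})

test_that("signal reduces to s0 at b = 0 without relaxation and to the decoupled biexponential without exchange", {
  pr <- default_protocol()
  ctrl <- group_preset("control")$params
  s <- steam_signal(ctrl, pr, include_relaxation = FALSE)
  expect_equal(s[pr$b == 0], rep(ctrl$s0, 9), tolerance = 1e-12)

  p0 <- two_pool_params(r = 4.2, k_ie = 0, m_i0 = 0.55, d_e_app = 0.95,
                        s0 = 2.5)
  s0 <- steam_signal(p0, pr, include_relaxation = FALSE)
  dia <- sphere_dapp(4.2, 1.7, pr$td)
  biexp <- 2.5 * (0.55 * exp(-pr$b * dia) + 0.45 * exp(-pr$b * 0.95))
  expect_equal(s0, biexp, tolerance = 1e-12)
})

test_that("matrix-exponential signal matches adaptive ODE integration", {
  pr <- default_protocol(b_values = c(0, 2500, 5000),
                         deltas = c(16, 150, 800))
  set.seed(7)
  for (i in 1:5) {
    p <- random_two_pool_params()
    s <- steam_signal(p, pr)
    so <- ode_signal(p, pr)
    expect_lt(max(abs(s - so) / so), 1e-8)
  }
})

test_that("signal is positive, monotone in b, and shifts down with Delta at b = 0", {
  pr <- default_protocol()
  for (grp in c("control", "apoptotic")) {
    p <- group_preset(grp)$params
    s <- steam_signal(p, pr)
    expect_true(all(s > 0))
    for (ds in unique(pr$delta_sep)) {
      expect_true(all(diff(s[pr$delta_sep == ds]) < 0))
    }
    # with relaxation on, the unweighted level drops as Delta (hence the
    # evolution time) grows; at nonzero b the Delta-curves may cross
    expect_true(all(diff(s[pr$b == 0]) < 0))
  }
})

test_that("initial log-slope in b equals the fraction-weighted mean diffusivity", {
  p <- group_preset("control")$params
  for (ds in c(16, 150, 800)) {
    td <- ds - 4 / 3
    dbar <- p$m_i0 * sphere_dapp(p$r, p$d_i, td) +
      (1 - p$m_i0) * p$d_e_app
    eps <- 1e-6
    pr <- acquisition_protocol(b = c(eps, 2 * eps), delta_sep = ds,
                               b_units = "ms/um2")
    s <- steam_signal(p, pr, include_relaxation = FALSE)
    slope <- -(log(s[2]) - log(s[1])) / eps
    expect_equal(slope, dbar, tolerance = 1e-4)
  }
})
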