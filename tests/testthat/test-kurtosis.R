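test_that("the cumulant fit is self-inverse on data generated from it", {
  b <- seq(0.8333, 5, length.out = 6)
  s <- 1.3 * exp(-b * 1.0 + b^2 * 1.0^2 * 0.8 / 6)
  kp <- fit_adc_kurtosis(s, b)
  expect_equal(kp$adc, 1.0, tolerance = 1e-10)
  expect_equal(kp$kurtosis, 0.8, tolerance = 1e-9)
  expect_equal(kp$s0_fit, 1.3, tolerance = 1e-10)
  # K = 0 generator: pure log-linear decay
  k0 <- fit_adc_kurtosis(2 * exp(-b * 0.6), b)
  expect_equal(k0$kurtosis, 0, tolerance = 1e-9)
  expect_error(fit_adc_kurtosis(c(1, 0.5), c(1, 2)),
               class = "steamdiff_domain_error")
})

test_that("ADC from two-pool signals decreases with gradient separation", {
  for (grp in c("control", "apoptotic")) {
    ks <- kurtosis_series(generate_dataset(group_preset(grp)))
    adc_16 <- ks$adc[ks$delta_sep == 16]
    adc_250 <- ks$adc[ks$delta_sep == 250]
    expect_lt(adc_250, adc_16)
    # strict decrease over the short separations; the apoptotic curve
    # plateaus earlier than the control curve
    expect_true(all(diff(ks$adc[ks$delta_sep <= 80]) < 0))
    expect_equal(which.max(ks$adc), 1L)
  }
})

test_that("kurtosis exchange model limits and special values", {
  k0 <- 2.3
  tau <- 210
  kinf <- 0.4
  expect_equal(kurtosis_exchange_model(1e12, k0, tau, kinf), kinf,
               tolerance = 1e-6)
  expect_equal(kurtosis_exchange_model(tau * 1e-6, k0, tau, kinf), k0 + kinf,
               tolerance = 1e-5)
  expect_equal(kurtosis_exchange_model(tau, k0, tau, kinf),
               2 * exp(-1) * k0 + kinf, tolerance = 1e-12)
  # K(t) - K_inf is nonnegative and decreasing
  t <- seq(1, 2000, by = 7)
  k <- kurtosis_exchange_model(t, k0, tau, kinf)
  expect_true(all(k - kinf >= 0))
  expect_true(all(diff(k) < 0))
})

test_that("exchange-time fits recover the generating parameters from clean samples", {
  td <- c(200, 250, 500, 800) - 4 / 3
  ctrl <- kurtosis_exchange_model(td, 2.3, 210, 0)
  fx <- fit_kurtosis_exchange(data.frame(t_d = td, kurtosis = ctrl))
  expect_equal(fx$tau_ex, 210, tolerance = 1e-4)
  expect_equal(fx$k0, 2.3, tolerance = 1e-4)
  apo <- kurtosis_exchange_model(td, 1.2, 130, 0.1)
  fa <- fit_kurtosis_exchange(data.frame(t_d = td, kurtosis = apo))
  expect_equal(fa$tau_ex, 130, tolerance = 1e-3)
  expect_equal(fa$k0, 1.2, tolerance = 1e-3)
  # flat series: k0 -> 0 and k_inf equals the mean kurtosis
  fl <- fit_kurtosis_exchange(data.frame(t_d = td, kurtosis = rep(0.7, 4)))
  expect_equal(fl$k0 * kurtosis_exchange_model(400, 1, fl$tau_ex, 0), 0,
               tolerance = 1e-4)
  expect_equal(fl$k_inf + fl$k0 * mean(kurtosis_exchange_model(td, 1, fl$tau_ex, 0)),
               0.7, tolerance = 1e-3)
  expect_error(fit_kurtosis_exchange(data.frame(t_d = td[1:2],
                                                kurtosis = ctrl[1:2])),
               class = "steamdiff_domain_error")
})

test_that("exchange-rate inversion and reporting-scale rounding", {
  expect_equal(exchange_rate_from_tau(130), 1000 / 130, tolerance = 1e-12)
  expect_equal(exchange_rate_from_tau(210), 4.7619, tolerance = 1e-4)
  expect_lt(exchange_rate_from_tau(1e12), 1e-6)
  expect_error(exchange_rate_from_tau(0), class = "steamdiff_domain_error")
})

test_that("water fraction from K0, with its inverse as identity", {
  expect_equal(lee_fraction(2.3), 2.3 / 5.3, tolerance = 1e-12)
  expect_equal(round(lee_fraction(2.3), 2), 0.43)
  expect_equal(lee_fraction(0), 0)
  expect_equal(lee_fraction(1.2), 0.2857143, tolerance = 1e-6)
  f <- seq(0, 0.95, by = 0.05)
  expect_equal(lee_fraction(3 * f / (1 - f)), f, tolerance = 1e-12)
})

test_that("kurtosis-peak radius relations follow the printed chain", {
  res <- lee_radius(t_peak = 150, tau_ex = 210, f = 0.434, d_i = 1.7)
  expect_equal(res$t_r, 210 / (1 - 0.434), tolerance = 1e-12)
  expect_equal(res$t_c, (5 * 150 / 6)^2 / res$t_r, tolerance = 1e-12)
  expect_equal(res$radius, 8.46, tolerance = 1e-2)
  # f = 0: residence time equals the exchange time exactly
  expect_equal(lee_radius(150, 210, 0, 1.7)$t_r, 210)
  # doubling the peak time quadruples the correlation time
  expect_equal(lee_radius(300, 210, 0.4, 1.7)$t_c /
                 lee_radius(150, 210, 0.4, 1.7)$t_c, 4, tolerance = 1e-12)
  expect_error(lee_radius(150, 210, 1, 1.7),
               class = "steamdiff_domain_error")
})

test_that("peak location: interior maxima, boundary flags, refinement", {
  grid <- c(16, 30, 50, 80, 150, 200, 250, 500, 800)
  k <- exp(-(log(grid / 150))^2)  # single interior maximum at 150
  pk <- find_kurtosis_peak(data.frame(delta_sep = grid, kurtosis = k))
  expect_equal(pk$t_peak, 150)
  expect_false(pk$boundary)
  expect_warning(
    pk2 <- find_kurtosis_peak(data.frame(delta_sep = grid,
                                         kurtosis = seq_along(grid))),
    "boundary")
  expect_true(pk2$boundary)
  expect_equal(pk2$t_peak, 800)
  # control-preset simulation has an interior peak
  ks <- kurtosis_series(generate_dataset(group_preset("control")))
  pk3 <- find_kurtosis_peak(ks)
  expect_false(pk3$boundary)
  expect_true(pk3$t_peak %in% grid[2:8])
})

test_that("total exchange rate from the kurtosis route is within an order of magnitude of the generator's", {
  ks <- kurtosis_series(generate_dataset(group_preset("control")))
  fx <- fit_kurtosis_exchange(ks)
  rate_kurt <- exchange_rate_from_tau(fx$tau_ex)
  p <- group_preset("control")$params
  rate_gen <- p$k_ie + p$k_ei
  ratio <- rate_kurt / rate_gen
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
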