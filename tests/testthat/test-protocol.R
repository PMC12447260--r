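test_that("diffusion time follows Delta - delta/3 with the narrow-pulse limit", {
  expect_equal(diffusion_time(16, 4), 16 - 4 / 3, tolerance = 1e-12)
  expect_equal(round(diffusion_time(16, 4), 3), 14.667)
  expect_equal(diffusion_time(800, 1e-9), 800, tolerance = 1e-9)
  expect_equal(diffusion_time(4, 4), 8 / 3, tolerance = 1e-12)
  expect_error(diffusion_time(1, 4), class = "steamdiff_validation_error")
})

test_that("q is recovered from (b, td) and reproduces b*D exactly", {
  expect_identical(q_from_b(0, 100), 0)
  expect_equal(q_from_b(5, 500), 0.1, tolerance = 1e-12)
  # algebraic identity exp(-q^2 D t) == exp(-b D)
  b <- c(0.5, 2, 5)
  td <- c(14.7, 78.7, 798.7)
  q <- q_from_b(b, td)
  D <- 0.95
  expect_equal(exp(-q^2 * D * td), exp(-b * D), tolerance = 1e-15)
})

test_that("unit conversion happens exactly once at ingest", {
  p <- acquisition_protocol(b = c(0, 5000), delta_sep = 80)
  expect_equal(max(p$b), 5.0)
  expect_equal(max(p$b_si), 5000)
  p2 <- acquisition_protocol(b = c(0, 5.0), delta_sep = 80, b_units = "ms/um2")
  expect_equal(max(p2$b), 5.0)
})

test_that("protocol invariants are enforced and rows sort stably by (Delta, b)", {
  expect_error(acquisition_protocol(b = -1, delta_sep = 80),
               class = "steamdiff_validation_error")
  expect_error(acquisition_protocol(b = 1000, delta_sep = 3, delta_pulse = 4),
               class = "steamdiff_validation_error")
  expect_error(acquisition_protocol(b = c(0, 0), delta_sep = 80),
               class = "steamdiff_validation_error")
  p <- acquisition_protocol(b = c(5000, 0, 2500, 5000, 0, 2500),
                            delta_sep = c(80, 80, 80, 16, 16, 16))
  expect_equal(p$delta_sep, c(16, 16, 16, 80, 80, 80))
  expect_equal(p$b_si, c(0, 2500, 5000, 0, 2500, 5000))
  # sorting again is the identity (stable, deterministic)
  p2 <- acquisition_protocol(b = p$b_si, delta_sep = p$delta_sep)
  expect_equal(p2$b, p$b)
  expect_equal(p2$delta_sep, p$delta_sep)
})

test_that("dataset validation: signal/sigma invariants and b0 sigma imputation", {
  pr <- acquisition_protocol(b = c(0, 2500, 5000), delta_sep = 80)
  expect_error(signal_dataset(pr, signal = c(-1, 1, 1), sigma = 1),
               class = "steamdiff_validation_error")
  expect_error(signal_dataset(pr, signal = c(1, 1, 1), sigma = 0),
               class = "steamdiff_validation_error")
  expect_error(signal_dataset(pr, signal = c(1, 1)),
               class = "steamdiff_validation_error")
  # missing per-point sigma: filled from the b=0 rows
  d <- signal_dataset(pr, signal = c(1, 0.5, 0.2),
                      sigma = c(0.03, NA, NA))
  expect_equal(d$sigma, c(0.03, 0.03, 0.03))
  expect_error(signal_dataset(pr, signal = c(1, 0.5, 0.2)),
               class = "steamdiff_validation_error")
})
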