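test_that("the default protocol matches the emulated acquisition grid", {
  pr <- default_protocol()
  expect_equal(nrow(pr), 63)          # 7 b-values x 9 separations
  expect_equal(sum(pr$b > 0), 54)
  tab <- table(pr$delta_sep)
  expect_length(tab, 9)
  expect_true(all(tab == 7))
  expect_equal(range(pr$delta_sep), c(16, 800))
  expect_equal(range(pr$b_si), c(0, 5000))
  expect_equal(unique(pr$delta_pulse), 4)
  expect_equal(unique(pr$te), 35)
  expect_true(all(pr$tm >= 3 & pr$tm <= 785))
})

test_that("dataset generation is reproducible and noiseless at infinite SNR", {
  pre <- group_preset("control")
  d1 <- generate_dataset(pre, noise = noise_spec("rician", 50, seed = 9))
  d2 <- generate_dataset(pre, noise = noise_spec("rician", 50, seed = 9))
  expect_identical(d1$signal, d2$signal)
  d3 <- generate_dataset(pre, noise = noise_spec("rician", 50, seed = 10))
  expect_false(identical(d1$signal, d3$signal))
  clean <- generate_dataset(pre)
  expect_identical(clean$signal, steam_signal(pre$params, clean$protocol))
})

test_that("Rician noise has the expected high-SNR mean", {
  s_true <- 0.9
  sigma <- 0.02
  n <- 1e4
  set.seed(123)
  draws <- sqrt((s_true + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  # the generator draws match this construction given the same seed logic
  pre <- group_preset("control")
  d <- generate_dataset(pre, noise = noise_spec("rician", 45, seed = 77))
  expect_true(all(d$signal >= 0))
  # law of large numbers: empirical mean within 3 SE of the noiseless value
  # (the O(sigma^2/s) Rician bias is far below this tolerance at SNR 45)
  expect_lt(abs(mean(draws) - s_true), 3 * sigma / sqrt(n) + sigma^2 / s_true)
})

test_that("study generation: counts, jitter, and reproducible draws", {
  st <- make_study(n_per_group = 10, noise = noise_spec("rician", 50),
                   jitter = 1, seed = 4)
  expect_length(st$datasets, 20)
  expect_equal(sum(st$truth$group == "control"), 10)
  m <- mean(st$truth$m_i0[st$truth$group == "control"])
  expect_lt(abs(m - 0.55), 3 * 0.02 / sqrt(10))
  st0 <- make_study(n_per_group = 3, noise = noise_spec("gaussian", 1e6),
                    jitter = 0, seed = 4)
  tr <- st0$truth[st0$truth$group == "apoptotic", ]
  expect_equal(tr$r, rep(3.6, 3))
  expect_equal(tr$m_i0, rep(0.32, 3))
  st_rep <- make_study(n_per_group = 3, noise = noise_spec("rician", 50),
                       seed = 11)
  st_rep2 <- make_study(n_per_group = 3, noise = noise_spec("rician", 50),
                        seed = 11)
  expect_identical(st_rep$datasets[["control-02"]]$signal,
                   st_rep2$datasets[["control-02"]]$signal)
  expect_error(make_study(n_per_group = 1),
               class = "steamdiff_validation_error")
})

test_that("the random walk reproduces free diffusion in a large sphere", {
  # r >> sqrt(2 D t): walkers never feel the wall
  mc <- mc_sphere_walk(r = 60, d_i = 1.7, n_walkers = 2000, dt = 0.05,
                       t_max = 10, seed = 5, times = c(2, 5, 10))
  expect_equal(mc$msd, 2 * 1.7 * mc$t, tolerance = 0.1)
  expect_true(all(abs(mc$msd - 2 * 1.7 * mc$t) < 3.5 * mc$msd_se))
})

test_that("the walker's long-time MSD reaches the uniform-ball variance", {
  r <- 3
  mc <- mc_sphere_walk(r = r, d_i = 1.7, n_walkers = 3000, dt = 0.006,
                       seed = 6, times = c(30, 60))
  expect_true(all(abs(mc$msd - 2 * r^2 / 5) < 3 * mc$msd_se))
})

test_that("the step-size precondition is enforced", {
  expect_error(mc_sphere_walk(r = 2, d_i = 1.7, dt = 0.1, t_max = 10),
               class = "steamdiff_domain_error")
})
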