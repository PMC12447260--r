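# Independent oracles used across tests.

# Adaptive ODE integration of the two-pool Bloch equations, independent of
# the closed-form matrix-exponential path in steam_signal().
ode_signal <- function(params, proto, include_relaxation = TRUE,
                       rtol = 1e-11, atol = 1e-13) {
  vapply(seq_len(nrow(proto)), function(i) {
    td <- proto$td[i]
    q2 <- proto$b[i] / td
    dia <- sphere_dapp(params$r, params$d_i, td)
    kie <- params$k_ie / 1000
    kei <- params$k_ei / 1000
    if (params$m_i0 >= 1) kie <- kei <- 0
    r1i <- if (include_relaxation) params$r1_i / 1000 else 0
    r1e <- if (include_relaxation) params$r1_e / 1000 else 0
    A <- matrix(c(-q2 * dia - r1i - kie, kie,
                  kei, -q2 * params$d_e_app - r1e - kei), 2)
    y0 <- params$s0 * c(params$m_i0, 1 - params$m_i0)
    out <- deSolve::ode(y0, c(0, td), function(t, y, p) list(A %*% y),
                        NULL, method = "lsoda", rtol = rtol, atol = atol)
    sum(out[2, 2:3])
  }, numeric(1))
}

# Random valid two-pool parameter draws for property tests.
random_two_pool_params <- function() {
  two_pool_params(
    r = runif(1, 1, 10),
    k_ie = exp(runif(1, log(0.2), log(30))),
    m_i0 = runif(1, 0.05, 0.95),
    d_i = runif(1, 0.5, 2.5),
    d_e_app = runif(1, 0.2, 2.5),
    s0 = exp(runif(1, log(0.2), log(5))),
    r1_i = runif(1, 0, 2),
    r1_e = runif(1, 0, 5)
  )
}

# Pooled-variance two-sample t statistic, by the textbook formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
}
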