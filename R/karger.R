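#' Two-pool exchange model parameters
#'
#' Parameter set for the two-pool (intracellular sphere / extracellular)
#' water-exchange signal model. The intracellular pool is a reflecting
#' sphere of radius `r` with intrinsic diffusivity `d_i`; the extracellular
#' pool has a constant apparent diffusivity `d_e_app` (tortuosity is folded
#' in, not a separate parameter). Water exchanges from the intracellular to
#' the extracellular pool at rate `k_ie`; the reverse rate is derived from
#' detailed balance at the equilibrium fractions,
#' \eqn{k_{EI} = k_{IE} m_{I0} / (1 - m_{I0})}, so that the equilibrium
#' magnetization split (`m_i0`, `1 - m_i0`) is stationary under pure
#' exchange. Longitudinal relaxation rates `r1_i`, `r1_e` act on each pool
#' (STEAM stores magnetization longitudinally, so only R1 enters); `s0` is
#' the overall normalization absorbing spin density, scanner scaling and any
#' TE-dependent transverse decay.
#'
#' Rates are user-facing in s\eqn{^{-1}} (the reporting convention);
#' lengths in \eqn{\mu m}, diffusivities in \eqn{\mu m^2}/ms.
#'
#' @param r sphere radius (\eqn{\mu m}), > 0.
#' @param k_ie intracellular-to-extracellular exchange rate (s\eqn{^{-1}}).
#' @param m_i0 equilibrium intracellular water fraction in \[0, 1\].
#' @param d_i intrinsic intracellular diffusivity (\eqn{\mu m^2}/ms).
#' @param d_e_app apparent extracellular diffusivity (\eqn{\mu m^2}/ms).
#' @param s0 signal normalization.
#' @param r1_i,r1_e longitudinal relaxation rates (s\eqn{^{-1}}).
#' @return list of class `two_pool_params` including the derived `k_ei`.
#' @export
#' @examples
#' two_pool_params(r = 4.2, k_ie = 4, m_i0 = 0.55, d_e_app = 0.95)$k_ei
two_pool_params <- function(r, k_ie, m_i0, d_i = 1.7, d_e_app,
                            s0 = 1, r1_i = 0, r1_e = 0) {
  if (r <= 0) stop_validation("r must be > 0")
  if (m_i0 < 0 || m_i0 > 1) stop_validation("m_i0 must be in [0, 1]")
  if (k_ie < 0 || r1_i < 0 || r1_e < 0) stop_validation("rates must be >= 0")
  if (d_i <= 0 || d_e_app <= 0) stop_validation("diffusivities must be > 0")
  if (s0 <= 0) stop_validation("s0 must be > 0")
  k_ei <- k_ei_from_balance(k_ie, m_i0)
  structure(
    list(r = r, k_ie = k_ie, k_ei = k_ei, m_i0 = m_i0, d_i = d_i,
         d_e_app = d_e_app, s0 = s0, r1_i = r1_i, r1_e = r1_e),
    class = "two_pool_params"
  )
}

#' Extracellular-to-intracellular rate from mass balance
#'
#' \eqn{k_{EI} = k_{IE} m_{I0}/(1-m_{I0})}. At `m_i0 = 1` there is no
#' extracellular pool: `k_ei` is defined as 0 and exchange is disabled in
#' the signal model, with a warning.
#'
#' @param k_ie intracellular exchange rate (s\eqn{^{-1}}).
#' @param m_i0 intracellular fraction.
#' @return k_ei in s\eqn{^{-1}}.
#' @export
k_ei_from_balance <- function(k_ie, m_i0) {
  if (m_i0 >= 1) {
    if (k_ie > 0) {
      warning("m_i0 = 1: no extracellular pool, exchange disabled (k_ei = 0)")
    }
    return(0)
  }
  k_ie * m_i0 / (1 - m_i0)
}

#' @export
print.two_pool_params <- function(x, ...) {
  cat(sprintf(
    paste0("Two-pool exchange parameters:\n",
           "  r = %.4g um, m_i0 = %.4g, k_ie = %.4g s^-1 (k_ei = %.4g)\n",
           "  d_i = %.4g, d_e_app = %.4g um^2/ms; r1_i = %.4g, r1_e = %.4g s^-1; s0 = %.4g\n"),
    x$r, x$m_i0, x$k_ie, x$k_ei, x$d_i, x$d_e_app, x$r1_i, x$r1_e, x$s0
  ))
  invisible(x)
}

#' Exchange-relaxation-attenuation generator matrix
#'
#' The 2x2 rate matrix A (ms\eqn{^{-1}}) governing the coupled evolution of
#' the pool magnetizations \eqn{(M_I, M_E)} under diffusion attenuation at
#' wavevector q, longitudinal relaxation, and first-order exchange:
#' \deqn{A = \begin{pmatrix} -q^2 D_I^{app} - R_{1I} - k_{IE} & k_{EI} \\
#'   k_{IE} & -q^2 D_E^{app} - R_{1E} - k_{EI} \end{pmatrix}}
#' with \eqn{D_I^{app}} the restricted-sphere apparent diffusivity
#' [sphere_dapp()] evaluated at the evolution time `t_d`. With q = 0 and
#' relaxation off, columns sum to zero (exchange conserves magnetization).
#'
#' @param params a [two_pool_params()].
#' @param q wavevector (1/\eqn{\mu m}).
#' @param t_d evolution (diffusion) time (ms) at which the intracellular
#'   apparent diffusivity is evaluated.
#' @param include_relaxation include the R1 terms?
#' @return 2x2 numeric matrix in ms\eqn{^{-1}}; state ordering (intra, extra).
#' @export
karger_generator <- function(params, q, t_d, include_relaxation = TRUE) {
  stopifnot(inherits(params, "two_pool_params"))
  if (q < 0) stop_validation("q must be >= 0")
  di_app <- sphere_dapp(params$r, params$d_i, t_d)
  kie <- params$k_ie * .PER_S_TO_PER_MS
  kei <- params$k_ei * .PER_S_TO_PER_MS
  if (params$m_i0 >= 1) {
    kie <- 0
    kei <- 0
  }
  r1i <- if (include_relaxation) params$r1_i * .PER_S_TO_PER_MS else 0
  r1e <- if (include_relaxation) params$r1_e * .PER_S_TO_PER_MS else 0
  matrix(c(
    -q^2 * di_app - r1i - kie, kie,
    kei, -q^2 * params$d_e_app - r1e - kei
  ), nrow = 2)
}

#' STEAM two-pool exchange signal
#'
#' Forward signal for each protocol point: the initial state
#' \eqn{(M_I, M_E) = s_0 (m_{I0}, 1-m_{I0})} is evolved by the matrix
#' exponential \eqn{\exp(A t_D)} of the generator [karger_generator()] over
#' the diffusion time \eqn{t_D = \Delta - \delta/3}, and the returned signal
#' is \eqn{M_I + M_E}. The matrix exponential uses the closed-form 2x2
#' eigen-solution
#' \eqn{e^{At} = e^{\mu t}[\cosh(\gamma t) I + \sinh(\gamma t)/\gamma\, (A - \mu I)]}
#' with \eqn{\mu} the mean eigenvalue and \eqn{\gamma} the half eigenvalue
#' gap; the degenerate limit \eqn{\gamma \to 0} is handled by the series
#' \eqn{\sinh(\gamma t)/\gamma \to t (1 + (\gamma t)^2/6)}, not by failure.
#'
#' @param params a [two_pool_params()].
#' @param protocol an [acquisition_protocol()].
#' @param include_relaxation include R1 terms (default `TRUE`)?
#' @return numeric signal vector, one entry per protocol row.
#' @export
#' @examples
#' pr <- default_protocol()
#' pars <- group_preset("control")$params
#' s <- steam_signal(pars, pr)
steam_signal <- function(params, protocol, include_relaxation = TRUE) {
  stopifnot(inherits(params, "two_pool_params"))
  if (!inherits(protocol, "acq_protocol")) {
    stop_validation("'protocol' must be an acq_protocol")
  }
  td <- protocol$td
  q2 <- protocol$b / td
  uts <- unique(td)
  di_u <- sphere_dapp(params$r, params$d_i, uts)
  di_app <- di_u[match(td, uts)]

  kie <- params$k_ie * .PER_S_TO_PER_MS
  kei <- params$k_ei * .PER_S_TO_PER_MS
  if (params$m_i0 >= 1) {
    kie <- 0
    kei <- 0
  }
  r1i <- if (include_relaxation) params$r1_i * .PER_S_TO_PER_MS else 0
  r1e <- if (include_relaxation) params$r1_e * .PER_S_TO_PER_MS else 0

  a11 <- -q2 * di_app - r1i - kie
  a22 <- -q2 * params$d_e_app - r1e - kei
  a12 <- kei
  a21 <- kie

  mu <- (a11 + a22) / 2
  gam <- sqrt(((a11 - a22) / 2)^2 + a12 * a21)  # real: off-diagonals >= 0
  x <- gam * td
  ch <- cosh(x)
  shg <- ifelse(x < 1e-6, td * (1 + x^2 / 6), sinh(x) / gam)

  vi <- params$m_i0
  ve <- 1 - vi
  w1 <- ch * vi + shg * ((a11 - mu) * vi + a12 * ve)
  w2 <- ch * ve + shg * (a21 * vi + (a22 - mu) * ve)
  params$s0 * exp(mu * td) * (w1 + w2)
}
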