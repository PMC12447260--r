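#' Monte-Carlo random walk in an impermeable sphere
#'
#' Independent oracle for [sphere_dapp()]: simulates reflecting Brownian
#' motion of `n_walkers` particles inside a sphere of radius `r` (elastic
#' specular reflection at the surface, time step `dt`) and records the
#' one-axis mean-squared displacement \eqn{\langle z^2(t)\rangle} and its
#' standard error at the requested times. The apparent diffusivity estimate
#' is \eqn{D_{app}^{MC}(t) = \langle z^2\rangle/(2t)}.
#'
#' The step length must resolve the geometry: `sqrt(6 d_i dt) < r/10` is
#' required, otherwise a domain error is raised.
#'
#' @param r sphere radius (\eqn{\mu m}).
#' @param d_i intrinsic diffusivity (\eqn{\mu m^2}/ms).
#' @param n_walkers number of walkers.
#' @param dt time step (ms); `NULL` picks `0.8 (r/10)^2 / (6 d_i)`, safely
#'   inside the precondition.
#' @param t_max maximum time (ms); ignored if `times` is given.
#' @param seed RNG seed.
#' @param times optional vector of record times (ms); default 24
#'   log-spaced times up to `t_max`.
#' @return data frame with columns `t` (achieved record times), `msd`,
#'   `msd_se`, `dapp`, `dapp_se`.
#' @export
#' @examples
#' \donttest{
#' mc <- mc_sphere_walk(4.2, 1.7, n_walkers = 2000, dt = 0.02,
#'                      t_max = 100, seed = 7)
#' }
mc_sphere_walk <- function(r, d_i, n_walkers = 5000, dt = NULL,
                           t_max = 800, seed = NULL, times = NULL) {
  if (r <= 0 || d_i <= 0) stop_domain("r and d_i must be > 0")
  if (is.null(dt)) dt <- 0.8 * (r / 10)^2 / (6 * d_i)
  if (dt <= 0) stop_domain("dt must be > 0")
  if (sqrt(6 * d_i * dt) >= r / 10) {
    stop_domain(sprintf(
      "time step too coarse: sqrt(6 d_i dt) = %.3g must be < r/10 = %.3g",
      sqrt(6 * d_i * dt), r / 10))
  }
  if (is.null(times)) {
    times <- exp(seq(log(max(dt * 10, 1e-3)), log(t_max), length.out = 24))
  }
  steps <- sort(unique(pmax(1L, as.integer(round(times / dt)))))
  res <- with_seed(seed, mc_sphere_walk_cpp(r, d_i, as.integer(n_walkers),
                                            dt, steps))
  n <- res$n
  msd <- res$sum2 / n
  # SE of the mean of (dz)^2 across walkers
  v <- pmax(res$sum4 / n - msd^2, 0)
  se <- sqrt(v / n)
  t_actual <- steps * dt
  data.frame(
    t = t_actual, msd = msd, msd_se = se,
    dapp = msd / (2 * t_actual), dapp_se = se / (2 * t_actual)
  )
}
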