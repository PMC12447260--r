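# Signal-representation analyses: per-separation ADC/kurtosis, the
# time-dependent kurtosis exchange model, and the kurtosis-peak cell-size
# relations.

#' Fit ADC and kurtosis at one gradient separation
#'
#' Cumulant-expansion fit over the nonzero b-values only:
#' \deqn{\ln S = \ln S_0 - b\,D + b^2 D^2 K / 6,}
#' the standard diffusion-kurtosis representation with \eqn{D \equiv} ADC.
#' The fit is linear in \eqn{(\ln S_0,\ D,\ D^2 K/6)} and solved by ordinary
#' least squares on \eqn{\ln S}.
#'
#' @param signals signal values (arbitrary units), > 0 at nonzero b.
#' @param b b-values in canonical ms/\eqn{\mu m^2} (matching `signals`);
#'   zero entries are dropped.
#' @param delta_sep gradient separation label (ms), carried through.
#' @param delta_pulse gradient pulse length (ms), for the diffusion time.
#' @return list of class `kurtosis_point`: `delta_sep`, `t_d`, `adc`
#'   (\eqn{\mu m^2}/ms), `kurtosis`, `s0_fit`.
#' @export
#' @examples
#' b <- seq(0.5, 5, length.out = 6)
#' s <- exp(-b * 1.0 + b^2 * 1.0^2 * 0.8 / 6)
#' fit_adc_kurtosis(s, b)$kurtosis  # 0.8
fit_adc_kurtosis <- function(signals, b, delta_sep = NA_real_,
                             delta_pulse = 4) {
  keep <- b > 0
  b <- b[keep]
  s <- signals[keep]
  if (length(unique(b)) < 3) stop_domain("need >= 3 distinct nonzero b-values")
  if (any(s <= 0)) stop_fit("nonpositive signal at nonzero b; cannot take log")
  X <- cbind(1, -b, b^2)
  beta <- solve(crossprod(X), crossprod(X, log(s)))
  D <- beta[2]
  if (D <= 0) stop_fit("fitted ADC is nonpositive")
  K <- 6 * beta[3] / D^2
  structure(
    list(delta_sep = delta_sep,
         t_d = if (is.na(delta_sep)) NA_real_ else delta_sep - delta_pulse / 3,
         adc = unname(D), kurtosis = unname(K), s0_fit = unname(exp(beta[1]))),
    class = "kurtosis_point"
  )
}

#' Kurtosis series from a signal dataset
#'
#' Applies [fit_adc_kurtosis()] within each gradient separation of a
#' [signal_dataset()].
#'
#' @param dataset a [signal_dataset()].
#' @return data frame with one row per separation: `delta_sep`, `t_d`,
#'   `adc`, `kurtosis`, `s0_fit`.
#' @export
kurtosis_series <- function(dataset) {
  stopifnot(inherits(dataset, "signal_dataset"))
  proto <- dataset$protocol
  out <- lapply(split(seq_len(nrow(proto)), proto$delta_sep), function(ix) {
    kp <- fit_adc_kurtosis(dataset$signal[ix], proto$b[ix],
                           delta_sep = proto$delta_sep[ix][1],
                           delta_pulse = proto$delta_pulse[ix][1])
    data.frame(delta_sep = kp$delta_sep, t_d = kp$t_d, adc = kp$adc,
               kurtosis = kp$kurtosis, s0_fit = kp$s0_fit)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$delta_sep), , drop = FALSE]
}

#' Time-dependent kurtosis under water exchange
#'
#' The exchange model for the diffusion-time dependence of kurtosis:
#' \deqn{K(t) = K_0 \frac{2\tau_{ex}}{t}\left[1 - \frac{\tau_{ex}}{t}
#'   \left(1 - e^{-t/\tau_{ex}}\right)\right] + K_\infty,}
#' where \eqn{K_0} is the kurtosis participating in water exchange,
#' \eqn{\tau_{ex}} the water exchange time and \eqn{K_\infty} the
#' non-exchanging kurtosis. Limits: \eqn{K(t\to 0^+) = K_0 + K_\infty},
#' \eqn{K(t\to\infty) = K_\infty}.
#'
#' @param t diffusion time (ms), > 0; vectorized.
#' @param k0 exchanging kurtosis amplitude.
#' @param tau_ex water exchange time (ms), > 0.
#' @param k_inf non-exchanging kurtosis.
#' @return kurtosis values.
#' @export
#' @examples
#' kurtosis_exchange_model(210, 2.3, 210, 0)  # 2 exp(-1) K0
kurtosis_exchange_model <- function(t, k0, tau_ex, k_inf = 0) {
  if (any(t <= 0)) stop_domain("t must be > 0")
  if (tau_ex <= 0) stop_domain("tau_ex must be > 0")
  x <- t / tau_ex
  # stable small-x evaluation of (2/x)[1 - (1 - exp(-x))/x]
  core <- ifelse(x < 1e-4,
                 1 - x / 3 + x^2 / 12,
                 2 / x * (1 - (1 - exp(-x)) / x))
  k0 * core + k_inf
}

#' Fit the kurtosis exchange-time model
#'
#' Bounded least-squares fit of [kurtosis_exchange_model()] to per-separation
#' kurtosis values. By default only the longest gradient separations are
#' used (the exchange model is valid once diffusion is coarse-grained), via
#' `use = 4`: the four longest separations of the default protocol (200,
#' 250, 500, 800 ms).
#'
#' @param points a data frame as from [kurtosis_series()], or any data frame
#'   with columns `t_d` and `kurtosis`.
#' @param use number of longest separations to fit (default 4), or `"all"`.
#' @param k_inf_nonneg constrain \eqn{K_\infty \ge 0}? Default `FALSE`
#'   (unconstrained, with a wide lower bound).
#' @return list of class `exchange_kurtosis_fit`: `k0`, `tau_ex` (ms),
#'   `k_inf`, `n_points`, and the fitted `points`.
#' @export
fit_kurtosis_exchange <- function(points, use = 4, k_inf_nonneg = FALSE) {
  df <- as.data.frame(points)
  if (!all(c("t_d", "kurtosis") %in% names(df))) {
    stop_validation("points need columns 't_d' and 'kurtosis'")
  }
  df <- df[order(df$t_d), , drop = FALSE]
  if (!identical(use, "all")) {
    n_use <- as.integer(use)
    df <- df[seq.int(nrow(df) - min(n_use, nrow(df)) + 1L, nrow(df)), ,
             drop = FALSE]
  }
  if (nrow(df) < 3) stop_domain("need >= 3 points to fit the exchange model")
  t <- df$t_d
  k <- df$kurtosis
  k_inf_lo <- if (k_inf_nonneg) 0 else -10
  fn <- function(p) kurtosis_exchange_model(t, p[1], p[2], p[3]) - k
  # multi-start over exchange-time decades; amplitude from the data scale
  tau_grid <- c(20, 60, 130, 210, 400, 800)
  best <- NULL
  for (tau0 in tau_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(max(max(k) - min(k), 0.1), tau0, min(k)),
        lower = c(0, 1, k_inf_lo), upper = c(50, 1e5, 10), fn = fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-10,
                                             maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) stop_fit("kurtosis exchange fit failed to converge")
  p <- coef(best)
  structure(
    list(k0 = unname(p[1]), tau_ex = unname(p[2]), k_inf = unname(p[3]),
         n_points = nrow(df), deviance = best$deviance, points = df),
    class = "exchange_kurtosis_fit"
  )
}

#' @export
print.exchange_kurtosis_fit <- function(x, ...) {
  cat(sprintf(
    "Kurtosis exchange fit (%d points): K0 = %.3g, tau_ex = %.4g ms, K_inf = %.3g\n",
    x$n_points, x$k0, x$tau_ex, x$k_inf))
  invisible(x)
}

#' Total water exchange rate from the exchange time
#'
#' \eqn{1/\tau_{ex} = k_{IE} + k_{EI}}, reported in s\eqn{^{-1}}
#' (`1000/tau_ex` for `tau_ex` in ms). No rounding is applied here; rounding
#' to integer rates belongs to the reporting layer.
#'
#' @param tau_ex water exchange time (ms), > 0 (Inf allowed: rate 0).
#' @return total exchange rate in s\eqn{^{-1}}.
#' @export
#' @examples
#' exchange_rate_from_tau(210)  # 4.76 s^-1
exchange_rate_from_tau <- function(tau_ex) {
  if (any(tau_ex <= 0)) stop_domain("tau_ex must be > 0")
  1000 / tau_ex
}

#' Intracellular water fraction from the exchanging kurtosis amplitude
#'
#' The kurtosis-peak relation \eqn{f = K_0 / (3 + K_0)} for a two-site
#' exchange system: the exchanging kurtosis amplitude determines the minor
#' (intracellular) water fraction.
#'
#' @param k0 exchanging kurtosis amplitude, >= 0.
#' @return water fraction in \[0, 1).
#' @export
#' @examples
#' lee_fraction(2.3)  # 0.434
lee_fraction <- function(k0) {
  if (any(k0 < 0)) stop_domain("k0 must be >= 0")
  k0 / (3 + k0)
}

#' Cell radius from the kurtosis peak position
#'
#' Disentangles radius from exchange using the position of the kurtosis peak:
#' \deqn{t_{peak} = \tfrac{6}{5}\sqrt{t_r t_c},\qquad t_c = r^2/D_I,\qquad
#'   \tau_{ex} = (1-f)\,t_r,}
#' inverted as \eqn{t_r = \tau_{ex}/(1-f)},
#' \eqn{t_c = (5 t_{peak}/6)^2 / t_r}, \eqn{r = \sqrt{t_c D_I}}.
#'
#' @param t_peak kurtosis peak time (ms).
#' @param tau_ex water exchange time (ms).
#' @param f intracellular water fraction, in \[0, 1).
#' @param d_i intrinsic intracellular diffusivity (\eqn{\mu m^2}/ms).
#' @return list of class `lee_result`: `f`, `t_r` (residence time, ms),
#'   `t_c` (correlation time, ms), `radius` (\eqn{\mu m}), `t_peak`.
#' @export
#' @examples
#' lee_radius(150, 210, lee_fraction(2.3), 1.7)$radius
lee_radius <- function(t_peak, tau_ex, f, d_i) {
  if (t_peak <= 0 || tau_ex <= 0 || d_i <= 0) stop_domain("inputs must be > 0")
  if (f < 0 || f >= 1) stop_domain("f must be in [0, 1)")
  t_r <- tau_ex / (1 - f)
  t_c <- (5 * t_peak / 6)^2 / t_r
  structure(
    list(f = f, t_r = t_r, t_c = t_c, radius = sqrt(t_c * d_i),
         t_peak = t_peak),
    class = "lee_result"
  )
}

#' Locate the kurtosis peak on the measured grid
#'
#' Returns the gradient separation of the maximal kurtosis. Default is the
#' grid argmax (no interpolation: the reference analysis quotes grid
#' values); `refine = TRUE` adds a quadratic refinement through the peak and
#' its neighbours. A series whose maximum sits on the grid boundary (no
#' interior peak) is flagged and the boundary value returned with a warning.
#'
#' @param points data frame with columns `delta_sep` and `kurtosis`
#'   (e.g. from [kurtosis_series()]).
#' @param refine quadratic peak refinement?
#' @return list: `t_peak` (ms, on the `delta_sep` axis), `index`,
#'   `boundary` flag.
#' @export
find_kurtosis_peak <- function(points, refine = FALSE) {
  df <- as.data.frame(points)
  if (!all(c("delta_sep", "kurtosis") %in% names(df))) {
    stop_validation("points need columns 'delta_sep' and 'kurtosis'")
  }
  df <- df[order(df$delta_sep), , drop = FALSE]
  if (nrow(df) < 3) stop_domain("need >= 3 points to locate a peak")
  i <- which.max(df$kurtosis)
  boundary <- i == 1L || i == nrow(df)
  t_peak <- df$delta_sep[i]
  if (boundary) {
    warning("kurtosis series has no interior maximum; returning boundary")
  } else if (refine) {
    xs <- df$delta_sep[(i - 1):(i + 1)]
    ys <- df$kurtosis[(i - 1):(i + 1)]
    co <- coef(lm(ys ~ xs + I(xs^2)))
    if (is.finite(co[3]) && co[3] < 0) t_peak <- -co[2] / (2 * co[3])
  }
  list(t_peak = unname(t_peak), index = i, boundary = boundary)
}
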