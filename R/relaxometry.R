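# Minimal mono-exponential relaxometry, companions to the diffusion fits.

#' Relaxometry series
#'
#' @param times inversion or echo times (ms), strictly increasing.
#' @param signal magnitudes.
#' @return list of class `relaxometry_series`.
#' @export
relaxometry_series <- function(times, signal) {
  if (length(times) != length(signal)) stop_validation("length mismatch")
  if (any(diff(times) <= 0)) stop_validation("times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal)),
            class = "relaxometry_series")
}

#' Default inversion and echo time grids
#'
#' Five log-spaced inversion times spanning 20 ms to 8 s for the
#' inversion-recovery T1 measurement, and a 7 ms x 180 echo train for the
#' CPMG T2 measurement.
#'
#' @return numeric vector of times (ms).
#' @export
default_ir_times <- function() c(20, 90, 400, 1800, 8000)

#' @rdname default_ir_times
#' @export
default_cpmg_times <- function() 7 * seq_len(180)

#' Fit T1 from magnitude inversion-recovery data
#'
#' Least-squares fit of the magnitude IR model
#' \eqn{S(TI) = S_0 |1 - 2 e^{-TI/T_1}|}. If the signal shows no usable
#' variation over the inversion times (all TI far beyond T1, so
#' \eqn{S \approx S_0}), T1 is unidentifiable: `t1` is `NA` and the result
#' is flagged.
#'
#' @param series a [relaxometry_series()] with >= 3 inversion times.
#' @return list with `t1` (ms), `s0`, `flag` (`"ok"` or `"unidentifiable"`).
#' @export
#' @examples
#' ti <- default_ir_times()
#' s <- 1 * abs(1 - 2 * exp(-ti / 1540))
#' fit_ir_t1(relaxometry_series(ti, s))$t1
fit_ir_t1 <- function(series) {
  stopifnot(inherits(series, "relaxometry_series"))
  ti <- series$times
  s <- series$signal
  if (length(ti) < 3) stop_validation("need >= 3 inversion times")
  s0_init <- max(s)
  if ((max(s) - min(s)) < 1e-6 * max(max(s), .Machine$double.eps)) {
    return(list(t1 = NA_real_, s0 = s0_init, flag = "unidentifiable"))
  }
  fn <- function(p) p[2] * abs(1 - 2 * exp(-ti / p[1])) - s
  # the magnitude model has local minima: multi-start T1 over the TI range,
  # anchored by the null-point scale TI_min-signal / ln 2
  t1_grid <- unique(c(ti[which.min(s)] / log(2),
                      exp(seq(log(min(ti) / 3), log(max(ti) * 3),
                              length.out = 8))))
  best <- NULL
  for (t1_init in t1_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(t1_init, s0_init),
                         lower = c(1e-3, 1e-12), upper = c(1e6, Inf), fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) stop_fit("inversion-recovery fit failed to converge")
  p <- coef(best)
  flag <- if (all(ti > 5 * p[1])) "unidentifiable" else "ok"
  list(t1 = p[1], s0 = p[2], flag = flag)
}

#' Fit T2 from a CPMG echo train
#'
#' Mono-exponential fit \eqn{S(TE) = S_0 e^{-TE/T_2}}, initialized from the
#' log-linear regression and refined by least squares. A flat echo train
#' (no measurable decay) gives `t2 = Inf` with a flag.
#'
#' @param series a [relaxometry_series()] with >= 3 echoes.
#' @return list with `t2` (ms), `s0`, `flag`.
#' @export
#' @examples
#' te <- default_cpmg_times()
#' fit_cpmg_t2(relaxometry_series(te, exp(-te / 68)))$t2
fit_cpmg_t2 <- function(series) {
  stopifnot(inherits(series, "relaxometry_series"))
  te <- series$times
  s <- series$signal
  if (length(te) < 3) stop_validation("need >= 3 echoes")
  if (any(s <= 0)) {
    pos <- s > 0
    if (sum(pos) < 3) stop_fit("too few positive echoes for a T2 fit")
    te <- te[pos]
    s <- s[pos]
  }
  ll <- lm(log(s) ~ te)
  slope <- coef(ll)[2]
  if (slope >= -1e-12) {
    return(list(t2 = Inf, s0 = max(s), flag = "no_decay"))
  }
  p0 <- c(-1 / slope, exp(coef(ll)[1]))
  fn <- function(p) p[2] * exp(-te / p[1]) - s
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = c(1e-3, 1e-12), upper = c(1e7, Inf),
                       fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_fit("CPMG fit failed to converge")
  p <- coef(fit)
  list(t2 = unname(p[1]), s0 = unname(p[2]), flag = "ok")
}
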