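# Joint nonlinear least-squares fitting of the two-pool exchange model.

.TP_PAR_NAMES <- c("r", "k_ie", "m_i0", "d_i", "d_e_app", "s0", "r1_i", "r1_e")

.default_bounds <- function(smax) {
  list(
    lower = c(r = 0.5, k_ie = 0, m_i0 = 0, d_i = 0.1, d_e_app = 0.05,
              s0 = 1e-6 * smax, r1_i = 0, r1_e = 0),
    upper = c(r = 15, k_ie = 100, m_i0 = 1, d_i = 3, d_e_app = 3,
              s0 = 10 * smax, r1_i = 10, r1_e = 10)
  )
}

# Randomized starts: log-uniform for rates (positive-bounded below for the
# draw only), uniform within bounds otherwise.
.draw_starts <- function(n_starts, free, lower, upper, seed) {
  log_pars <- c("k_ie", "r1_i", "r1_e")
  with_seed(seed, {
    t(vapply(seq_len(n_starts), function(i) {
      vapply(free, function(nm) {
        lo <- lower[[nm]]
        hi <- upper[[nm]]
        if (nm %in% log_pars) {
          lo <- max(lo, hi * 1e-4)
          exp(runif(1, log(lo), log(hi)))
        } else {
          runif(1, lo, hi)
        }
      }, numeric(1))
    }, numeric(length(free))))
  })
}

.build_params <- function(theta, fixed) {
  full <- as.list(c(theta, unlist(fixed)))[.TP_PAR_NAMES]
  names(full) <- .TP_PAR_NAMES
  suppressWarnings(two_pool_params(
    r = full$r, k_ie = full$k_ie, m_i0 = full$m_i0, d_i = full$d_i,
    d_e_app = full$d_e_app, s0 = full$s0, r1_i = full$r1_i, r1_e = full$r1_e
  ))
}

#' Reduced chi-squared
#'
#' \eqn{\chi^2_\nu = \sum_i (resid_i/\sigma_i)^2 / (N - n_{free})}. Values
#' near 1 indicate residuals consistent with the per-point noise estimate.
#'
#' @param residuals raw residuals (model - data).
#' @param sigma per-point noise std.
#' @param n_free number of free parameters.
#' @return unitless reduced chi-squared.
#' @export
reduced_chi2 <- function(residuals, sigma, n_free) {
  n <- length(residuals)
  if (n <= n_free) stop_domain("need more points than free parameters")
  sum((residuals / sigma)^2) / (n - n_free)
}

#' Fit the two-pool exchange model jointly over b and diffusion time
#'
#' Weighted bounded trust-region least squares (Levenberg-Marquardt with box
#' constraints) of [steam_signal()] to a [signal_dataset()], jointly over
#' all b-values and gradient separations. The b = 0 rows are excluded (they
#' carry crusher artifacts in the STEAM acquisition this models), leaving
#' the 54 nonzero-b points of the default protocol. The intracellular diffusivity is
#' fixed by default (`d_i = 1.7` \eqn{\mu m^2}/ms) because the protocol's
#' diffusion times are too long to sensitize to it. `n_starts` randomized
#' initializations are drawn reproducibly from the bounds given `seed` and
#' the best converged solution is returned.
#'
#' Parameters whose estimate lies on a bound are flagged `at_bound`;
#' parameters whose Jacobian column at the solution is numerically zero are
#' flagged `unidentifiable`.
#'
#' @param dataset a [signal_dataset()] with at least 2 distinct gradient
#'   separations and at least 3 nonzero b-values per separation.
#' @param fixed named list of parameters held constant
#'   (default `list(d_i = 1.7)`).
#' @param n_starts number of randomized multi-starts.
#' @param seed RNG seed for the start draws.
#' @param include_relaxation model the R1 terms (default `TRUE`)?
#' @param lower,upper named numeric vectors overriding default bounds.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return object of class `two_pool_fit`: estimates as a
#'   [two_pool_params()], `fixed`, `chi2_reduced`, `n_points`, `n_free`,
#'   `start_used`, `objective`, per-parameter `flags`, and a `starts`
#'   summary table.
#' @seealso [contour_interval()], [reduced_chi2()]
#' @export
fit_two_pool <- function(dataset, fixed = list(d_i = 1.7), n_starts = 20,
                         seed = 1, include_relaxation = TRUE,
                         lower = NULL, upper = NULL,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-8, maxiter = 1000)) {
  stopifnot(inherits(dataset, "signal_dataset"))
  keep <- dataset$protocol$b > 0
  proto <- dataset$protocol[keep, , drop = FALSE]
  class(proto) <- c("acq_protocol", "data.frame")
  sig <- dataset$signal[keep]
  sg <- dataset$sigma[keep]
  if (length(unique(proto$delta_sep)) < 2) {
    stop_validation("need >= 2 distinct gradient separations")
  }
  if (min(table(proto$delta_sep)) < 3) {
    stop_validation("need >= 3 nonzero b-values per gradient separation")
  }
  if (!is.list(fixed)) stop_validation("'fixed' must be a named list")
  bad <- setdiff(names(fixed), .TP_PAR_NAMES)
  if (length(bad)) stop_validation(paste0("unknown fixed parameter(s): ",
                                          paste(bad, collapse = ", ")))
  free <- setdiff(.TP_PAR_NAMES, names(fixed))
  n_free <- length(free)
  n_points <- length(sig)
  if (n_points <= n_free) stop_validation("more free parameters than points")

  bounds <- .default_bounds(max(sig))
  lo <- bounds$lower
  up <- bounds$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper

  resid_fn <- function(theta) {
    names(theta) <- free
    p <- .build_params(theta, fixed)
    (steam_signal(p, proto, include_relaxation) - sig) / sg
  }

  starts <- .draw_starts(n_starts, free, as.list(lo), as.list(up), seed)
  colnames(starts) <- free

  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = starts[i, ], lower = lo[free], upper = up[free],
        fn = resid_fn, control = control
      )
      list(ok = TRUE, deviance = fit$deviance, par = coef(fit),
           info = fit$info, message = fit$message)
    }, error = function(e) list(ok = FALSE, deviance = Inf, par = starts[i, ],
                                info = NA, message = conditionMessage(e)))
  }
  dev <- vapply(runs, function(x) x$deviance, numeric(1))
  if (!any(is.finite(dev))) {
    msgs <- vapply(runs, function(x) paste0(x$message), character(1))
    stop_fit(paste0("all multi-starts failed to converge:\n",
                    paste(unique(msgs), collapse = "\n")))
  }
  best_i <- which.min(dev)
  best <- runs[[best_i]]
  est <- best$par
  names(est) <- free

  # flags: estimates at bounds, and numerically flat Jacobian columns
  tol_b <- 1e-8 + 1e-6 * (up[free] - lo[free])
  at_bound <- free[abs(est - lo[free]) < tol_b | abs(est - up[free]) < tol_b]
  J <- .num_jacobian(resid_fn, est, lower = lo[free], upper = up[free])
  cn <- sqrt(colSums(J^2))
  unident <- free[cn < 1e-8 * max(cn, 1e-300)]

  params <- .build_params(est, fixed)
  chi2 <- best$deviance / (n_points - n_free)
  structure(
    list(
      params = params, estimates = est, fixed = fixed,
      chi2_reduced = chi2, objective = best$deviance,
      n_points = n_points, n_free = n_free,
      start_used = best_i,
      flags = list(at_bound = at_bound, unidentifiable = unident),
      starts = data.frame(start = seq_len(n_starts), deviance = dev,
                          converged = vapply(runs, function(x) isTRUE(x$ok),
                                             logical(1))),
      lower = lo, upper = up, free = free,
      include_relaxation = include_relaxation,
      sample_id = dataset$sample_id, group = dataset$group
    ),
    class = "two_pool_fit"
  )
}

.num_jacobian <- function(fn, par, eps = 1e-6, lower = NULL, upper = NULL) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-3)
    if (!is.null(upper) && par[j] + h > upper[j]) h <- -h  # step inward
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' @export
print.two_pool_fit <- function(x, ...) {
  cat(sprintf(
    "Two-pool fit ('%s', %s): %d points, %d free parameters, reduced chi^2 = %.4g\n",
    x$sample_id, x$group, x$n_points, x$n_free, x$chi2_reduced))
  cat(sprintf("  fixed: %s\n",
              paste(sprintf("%s = %g", names(x$fixed), unlist(x$fixed)),
                    collapse = ", ")))
  print(x$params)
  if (length(x$flags$at_bound)) {
    cat("  at bound:", paste(x$flags$at_bound, collapse = ", "), "\n")
  }
  if (length(x$flags$unidentifiable)) {
    cat("  unidentifiable:", paste(x$flags$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- chi^2 contour machinery -------------------------------------------

# Profile reduced chi^2: fix par[fix_idx] at given values, re-optimize the
# rest from `start`, return reduced chi^2 with the unconstrained fit's dof.
.profile_chi2 <- function(resid_fn, full_par, fix_idx, fix_values,
                          lower, upper, dof, control) {
  par <- full_par
  par[fix_idx] <- fix_values
  free_idx <- setdiff(seq_along(full_par), fix_idx)
  if (length(free_idx) == 0) {
    return(list(chi2 = sum(resid_fn(par)^2) / dof, par = par))
  }
  fn_sub <- function(th) {
    p <- par
    p[free_idx] <- th
    resid_fn(p)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = full_par[free_idx], lower = lower[free_idx],
                       upper = upper[free_idx], fn = fn_sub,
                       control = control),
    error = function(e) NULL)
  if (is.null(fit)) return(list(chi2 = Inf, par = par))
  par[free_idx] <- coef(fit)
  list(chi2 = fit$deviance / dof, par = par)
}

# One-sided profile bound for parameter `idx`: march from the optimum in
# direction `dir` until the profile reduced chi^2 crosses `threshold`, then
# bisect. Returns the bound and whether it is open (hit the box first).
.profile_bound <- function(resid_fn, opt_par, idx, dir, threshold, lower,
                           upper, dof, control, rel_step = 0.05,
                           max_steps = 60, tol = 1e-4) {
  p0 <- opt_par[idx]
  limit <- if (dir > 0) upper[idx] else lower[idx]
  scale <- max(abs(p0), (upper[idx] - lower[idx]) / 20)
  step <- rel_step * scale
  cur <- p0
  cur_par <- opt_par
  for (k in seq_len(max_steps)) {
    nxt <- cur + dir * step
    hit_box <- (dir > 0 && nxt >= limit) || (dir < 0 && nxt <= limit)
    if (hit_box) nxt <- limit
    pr <- .profile_chi2(resid_fn, cur_par, idx, nxt, lower, upper, dof, control)
    if (pr$chi2 >= threshold) {
      # bisect between cur (inside) and nxt (outside)
      a <- cur
      bnd <- nxt
      for (j in 1:40) {
        mid <- (a + bnd) / 2
        pm <- .profile_chi2(resid_fn, cur_par, idx, mid, lower, upper, dof,
                            control)
        if (pm$chi2 >= threshold) bnd <- mid else {
          a <- mid
          cur_par <- pm$par
        }
        if (abs(bnd - a) < tol * max(scale, 1e-12)) break
      }
      return(list(bound = (a + bnd) / 2, open = FALSE))
    }
    cur <- nxt
    cur_par <- pr$par
    if (hit_box) return(list(bound = limit, open = TRUE))
    step <- step * 1.6
  }
  list(bound = cur, open = TRUE)
}

#' Chi-squared contour confidence intervals for a parameter pair
#'
#' Implements the F-based contour criterion: starting from the converged
#' fit, the two parameters of `pair` are fixed and moved away from the
#' optimum with all remaining parameters re-optimized at each step, and a
#' point is accepted while
#' \deqn{\chi^2 \ge \chi^2_0 \left(1 + \frac{n_P}{N - n_P} F(n_P, N - n_P)\right)}
#' is not yet violated, where \eqn{\chi^2_0} is the unconstrained reduced
#' chi-squared, \eqn{n_P} the number of free parameters of the unconstrained
#' fit, \eqn{N} the number of fitted points and \eqn{F} the F-distribution
#' quantile at `confidence`. Both reduced chi-squared values use the
#' unconstrained dof \eqn{N - n_P}. The per-parameter interval is the
#' extremal accepted value of each parameter (found by profile-likelihood
#' bisection, which for this criterion coincides with the extremes of the
#' 2-D contour); a 2-D grid trace of the constrained reduced chi-squared is
#' returned for plotting.
#'
#' An interval that reaches a box bound before crossing the threshold is
#' flagged one-sided (`open`).
#'
#' @param fit a converged [fit_two_pool()] result.
#' @param dataset the [signal_dataset()] that was fitted.
#' @param pair character vector of two free parameter names.
#' @param confidence confidence level of the F quantile (default 0.68;
#'   0.95 is the common alternative). Recorded in the output.
#' @param n_grid grid resolution per axis for the 2-D trace (0 skips it).
#' @return list with `interval` (2 x 2 matrix of lower/upper per parameter),
#'   `open` (logical matrix of one-sided flags), `threshold`, `confidence`,
#'   and `trace` (data frame `p1, p2, chi2_reduced, accepted`).
#' @export
contour_interval <- function(fit, dataset, pair, confidence = 0.68,
                             n_grid = 15) {
  stopifnot(inherits(fit, "two_pool_fit"))
  if (length(pair) != 2 || !all(pair %in% fit$free)) {
    stop_validation("'pair' must name two free parameters of the fit")
  }
  keep <- dataset$protocol$b > 0
  proto <- dataset$protocol[keep, , drop = FALSE]
  class(proto) <- c("acq_protocol", "data.frame")
  sig <- dataset$signal[keep]
  sg <- dataset$sigma[keep]
  free <- fit$free
  fixed <- fit$fixed
  inc_rel <- fit$include_relaxation
  resid_fn <- function(theta) {
    names(theta) <- free
    p <- .build_params(theta, fixed)
    (steam_signal(p, proto, inc_rel) - sig) / sg
  }
  nP <- fit$n_free
  N <- fit$n_points
  dof <- N - nP
  threshold <- fit$chi2_reduced * (1 + nP / dof * qf(confidence, nP, dof))
  control <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8,
                                        maxiter = 500)
  opt <- fit$estimates
  lower <- fit$lower[free]
  upper <- fit$upper[free]

  interval <- matrix(NA_real_, 2, 2,
                     dimnames = list(pair, c("lower", "upper")))
  open <- matrix(FALSE, 2, 2, dimnames = list(pair, c("lower", "upper")))
  for (pn in pair) {
    idx <- match(pn, free)
    lo_b <- .profile_bound(resid_fn, opt, idx, -1, threshold, lower, upper,
                           dof, control)
    up_b <- .profile_bound(resid_fn, opt, idx, +1, threshold, lower, upper,
                           dof, control)
    interval[pn, ] <- c(lo_b$bound, up_b$bound)
    open[pn, ] <- c(lo_b$open, up_b$open)
  }

  trace <- NULL
  if (n_grid > 0) {
    i1 <- match(pair[1], free)
    i2 <- match(pair[2], free)
    pad <- 0.15
    g1 <- seq(interval[1, 1] - pad * diff(interval[1, ]),
              interval[1, 2] + pad * diff(interval[1, ]), length.out = n_grid)
    g2 <- seq(interval[2, 1] - pad * diff(interval[2, ]),
              interval[2, 2] + pad * diff(interval[2, ]), length.out = n_grid)
    g1 <- pmin(pmax(g1, lower[i1]), upper[i1])
    g2 <- pmin(pmax(g2, lower[i2]), upper[i2])
    grid <- expand.grid(p1 = g1, p2 = g2)
    chi2 <- vapply(seq_len(nrow(grid)), function(k) {
      .profile_chi2(resid_fn, opt, c(i1, i2),
                    c(grid$p1[k], grid$p2[k]), lower, upper, dof,
                    control)$chi2
    }, numeric(1))
    trace <- data.frame(p1 = grid$p1, p2 = grid$p2, chi2_reduced = chi2,
                        accepted = chi2 < threshold)
    names(trace)[1:2] <- pair
  }

  list(interval = interval, open = open, threshold = threshold,
       confidence = confidence, chi2_reduced_0 = fit$chi2_reduced,
       trace = trace)
}
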