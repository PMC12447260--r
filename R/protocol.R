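#' Build an acquisition protocol
#'
#' An acquisition protocol is the grid of diffusion-weighting settings at
#' which signals are measured: diffusion weighting `b`, gradient separation
#' \eqn{\Delta}, gradient pulse length \eqn{\delta}, mixing time TM and echo
#' time TE. Canonical internal units are ms for times and ms/\eqn{\mu m^2}
#' for `b`; `b` supplied in the conventional s/mm\eqn{^2} is converted exactly
#' once on ingest (1 s/mm\eqn{^2} = 10\eqn{^{-3}} ms/\eqn{\mu m^2}). Derived
#' per-point quantities are the diffusion time \eqn{t_D = \Delta - \delta/3}
#' and the wavevector \eqn{q = \sqrt{b/t_D}}.
#'
#' Rows are sorted stably by (\eqn{\Delta}, b).
#'
#' @param b numeric vector of diffusion weightings.
#' @param delta_sep gradient separation \eqn{\Delta} (ms); recycled.
#' @param delta_pulse gradient pulse length \eqn{\delta} (ms); recycled.
#' @param tm mixing time (ms); if `NULL`, derived as
#'   \eqn{\Delta - TE/2} clipped to the 3--785 ms range of the reference
#'   STEAM protocol.
#' @param te echo time (ms); recycled.
#' @param b_units units of `b`: `"s/mm2"` (default) or `"ms/um2"`.
#' @param name protocol label.
#'
#' @return A data frame of class `acq_protocol` with columns `b_si`
#'   (as-ingested s/mm\eqn{^2}), `b` (canonical ms/\eqn{\mu m^2}),
#'   `delta_sep`, `delta_pulse`, `tm`, `te`, `td`, `q`.
#' @seealso [default_protocol()], [diffusion_time()], [q_from_b()]
#' @export
#' @examples
#' p <- acquisition_protocol(b = c(0, 2500, 5000), delta_sep = 80)
#' p$td  # 80 - 4/3
acquisition_protocol <- function(b, delta_sep, delta_pulse = 4, tm = NULL,
                                 te = 35, b_units = c("s/mm2", "ms/um2"),
                                 name = "protocol") {
  b_units <- match.arg(b_units)
  if (!is.numeric(b) || length(b) < 1L) {
    stop_validation("'b' must be a non-empty numeric vector")
  }
  n <- max(length(b), length(delta_sep))
  b <- rep_len(b, n)
  delta_sep <- rep_len(delta_sep, n)
  delta_pulse <- rep_len(delta_pulse, n)
  te <- rep_len(te, n)
  if (b_units == "s/mm2") {
    b_si <- b
    b_canon <- b / 1000
  } else {
    b_si <- b * 1000
    b_canon <- b
  }
  if (is.null(tm)) tm <- tm_from_delta(delta_sep, te)
  tm <- rep_len(tm, n)

  if (any(b_canon < 0)) stop_validation("b must be >= 0")
  if (any(delta_pulse <= 0)) stop_validation("delta_pulse must be > 0")
  if (any(delta_sep <= delta_pulse)) {
    stop_validation("delta_sep must exceed delta_pulse")
  }
  td <- delta_sep - delta_pulse / 3
  if (any(td <= 0)) stop_validation("diffusion time delta_sep - delta_pulse/3 must be > 0")
  if (all(b_canon == 0)) stop_validation("protocol needs at least one nonzero-b point")

  out <- data.frame(
    b_si = b_si, b = b_canon, delta_sep = delta_sep,
    delta_pulse = delta_pulse, tm = tm, te = te,
    td = td, q = sqrt(b_canon / td)
  )
  ord <- order(out$delta_sep, out$b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- name
  class(out) <- c("acq_protocol", "data.frame")
  out
}

# TM derivation when unrecorded: Delta - TE/2, clipped to the printed range.
tm_from_delta <- function(delta_sep, te) {
  pmin(pmax(delta_sep - te / 2, 3), 785)
}

#' Diffusion time of acquisition points
#'
#' \eqn{t_D = \Delta - \delta/3}, exact for rectangular gradient pulses and
#' reducing to \eqn{\Delta} in the narrow-pulse limit \eqn{\delta \to 0}.
#'
#' @param delta_sep gradient separation \eqn{\Delta} (ms), or an
#'   `acq_protocol` whose `td` column is returned.
#' @param delta_pulse gradient pulse length \eqn{\delta} (ms).
#' @return diffusion time(s) in ms.
#' @export
#' @examples
#' diffusion_time(16, 4)  # 14.667 ms
diffusion_time <- function(delta_sep, delta_pulse = 4) {
  if (inherits(delta_sep, "acq_protocol")) return(delta_sep$td)
  td <- delta_sep - delta_pulse / 3
  if (any(td <= 0)) stop_validation("requires delta_sep > delta_pulse/3")
  td
}

#' Diffusion wavevector from b-value and diffusion time
#'
#' For narrow pulses \eqn{b = q^2 t_D}, so \eqn{q = \sqrt{b/t_D}}
#' (\eqn{\mu m^{-1}}). The gradient amplitude and gyromagnetic ratio are never
#' needed: q is always recovered from (b, \eqn{t_D}).
#'
#' @param b diffusion weighting in canonical ms/\eqn{\mu m^2}, or an
#'   `acq_protocol` whose `q` column is returned.
#' @param td diffusion time (ms).
#' @return wavevector(s) in 1/\eqn{\mu m}.
#' @export
#' @examples
#' q_from_b(5, 500)  # 0.1 um^-1
q_from_b <- function(b, td) {
  if (inherits(b, "acq_protocol")) return(b$q)
  if (any(b < 0)) stop_validation("b must be >= 0")
  if (any(td <= 0)) stop_validation("td must be > 0")
  sqrt(b / td)
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf(
    "Acquisition protocol '%s': %d points, %d gradient separations (%g-%g ms), b %g-%g s/mm^2\n",
    attr(x, "name") %||% "protocol", nrow(x), length(unique(x$delta_sep)),
    min(x$delta_sep), max(x$delta_sep), min(x$b_si), max(x$b_si)
  ))
  print.data.frame(x, ...)
  invisible(x)
}
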