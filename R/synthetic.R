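#' Group parameter presets
#'
#' Reference two-pool parameter sets representative of untreated (control)
#' and cisplatin-treated (apoptotic) AML cell pellets: apoptosis shrinks the
#' cells, lowers the intracellular fraction and speeds up transmembrane
#' exchange.
#'
#' @param name `"control"` or `"apoptotic"`.
#' @return list with elements `name`, `params` (a [two_pool_params()]) and
#'   `sds` (between-sample standard deviations used by [make_study()]).
#' @export
#' @examples
#' group_preset("control")$params
group_preset <- function(name = c("control", "apoptotic")) {
  name <- match.arg(name)
  if (name == "control") {
    params <- two_pool_params(r = 4.2, k_ie = 4.0, m_i0 = 0.55, d_i = 1.7,
                              d_e_app = 0.95, s0 = 1, r1_i = 0, r1_e = 2.9)
    sds <- c(r = 0.1, k_ie = 0.2, m_i0 = 0.02, d_e_app = 0.07, r1_e = 0.2)
  } else {
    params <- two_pool_params(r = 3.6, k_ie = 6, m_i0 = 0.32, d_i = 1.7,
                              d_e_app = 0.85, s0 = 1, r1_i = 0, r1_e = 1.7)
    sds <- c(r = 0.2, k_ie = 1, m_i0 = 0.03, d_e_app = 0.05, r1_e = 0.2)
  }
  list(name = name, params = params, sds = sds)
}

#' The default STEAM acquisition protocol
#'
#' The 7 x 9 = 63-point grid of the emulated protocol: 7 b-values spanning
#' 0-5000 s/mm\eqn{^2} (linearly spaced by default; the exact placement
#' within the printed range is configurable) at each of 9 gradient
#' separations (16, 30, 50, 80, 150, 200, 250, 500, 800 ms), with gradient
#' pulse length \eqn{\delta} = 4 ms and TE = 35 ms. Mixing times are derived
#' as \eqn{\Delta - TE/2} clipped to the protocol's 3-785 ms range.
#'
#' @param b_values b-values in s/mm\eqn{^2}; default `seq(0, 5000, length.out = 7)`.
#' @param deltas gradient separations (ms).
#' @param delta_pulse gradient pulse length (ms).
#' @param te echo time (ms).
#' @return an [acquisition_protocol()] with 63 points by default
#'   (54 nonzero-b points used in fits).
#' @export
default_protocol <- function(b_values = seq(0, 5000, length.out = 7),
                             deltas = c(16, 30, 50, 80, 150, 200, 250, 500, 800),
                             delta_pulse = 4, te = 35) {
  grid <- expand.grid(b = b_values, delta_sep = deltas)
  acquisition_protocol(
    b = grid$b, delta_sep = grid$delta_sep, delta_pulse = delta_pulse,
    te = te, b_units = "s/mm2", name = "steam-7x9"
  )
}

#' Noise specification
#'
#' @param model `"rician"` (magnitude MRI, default) or `"gaussian"`.
#' @param snr signal-to-noise ratio relative to `s0`; the noise std is
#'   `s0/snr`. `Inf` gives noiseless data.
#' @param seed integer RNG seed, or `NULL`.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(model = c("rician", "gaussian"), snr = Inf, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(snr) || snr <= 0) stop_validation("snr must be > 0")
  structure(list(model = model, snr = snr, seed = seed), class = "noise_spec")
}

#' Generate a synthetic signal dataset
#'
#' Evaluates the noiseless two-pool signal [steam_signal()] for the preset
#' parameters over the protocol and adds noise: Rician noise takes the
#' magnitude of `(signal + N(0, sigma), N(0, sigma))` with
#' `sigma = s0/snr`; Gaussian noise adds `N(0, sigma)` (clipped at 0 to
#' respect the non-negativity of magnitude data). Generation is
#' deterministic given `noise$seed`. The dataset's `sigma` column carries
#' the generator sigma; for noiseless data (`snr = Inf`) a nominal uniform
#' `0.01 s0` is recorded so that weighted fits remain defined (uniform
#' weights leave the estimates unchanged).
#'
#' @param preset a [group_preset()] (or any list with `name` and `params`).
#' @param protocol an [acquisition_protocol()].
#' @param noise a [noise_spec()].
#' @param sample_id sample label.
#' @return a [signal_dataset()].
#' @export
#' @examples
#' d <- generate_dataset(group_preset("control"),
#'                       noise = noise_spec("rician", snr = 50, seed = 1))
generate_dataset <- function(preset, protocol = default_protocol(),
                             noise = noise_spec(), sample_id = NULL) {
  params <- preset$params
  stopifnot(inherits(params, "two_pool_params"))
  clean <- steam_signal(params, protocol)
  sigma <- params$s0 / noise$snr
  if (!is.finite(sigma) || sigma == 0) {
    sig <- clean
    sigma_col <- 0.01 * params$s0
  } else {
    sig <- with_seed(noise$seed, {
      if (noise$model == "rician") {
        n1 <- rnorm(length(clean), 0, sigma)
        n2 <- rnorm(length(clean), 0, sigma)
        sqrt((clean + n1)^2 + n2^2)
      } else {
        pmax(clean + rnorm(length(clean), 0, sigma), 0)
      }
    })
    sigma_col <- sigma
  }
  signal_dataset(
    protocol = protocol, signal = sig, sigma = sigma_col,
    group = if (preset$name %in% c("control", "apoptotic", "media")) preset$name else "control",
    sample_id = sample_id %||% paste0(preset$name, "-1")
  )
}

#' Generate a synthetic two-group study
#'
#' Emulates a study of `n_per_group` sample preparations, each contributing
#' one control and one apoptotic pellet. Per-sample parameters are drawn
#' around the group presets with Gaussian between-sample spread equal to
#' `jitter` times each preset's between-sample standard deviations (the
#' `sds` element of [group_preset()]), truncated to physical ranges, and
#' each dataset receives independent noise. Fully reproducible given `seed`.
#'
#' @param n_per_group samples per group (>= 2).
#' @param noise a [noise_spec()]; its `seed` is ignored in favour of `seed`.
#' @param jitter scalar multiplier on the between-sample SDs (0 = identical
#'   samples within a group before noise).
#' @param seed integer seed for both parameter draws and noise.
#' @param protocol acquisition protocol.
#' @return list with elements `datasets` (list of [signal_dataset()]),
#'   `truth` (data frame of per-sample generating parameters) and
#'   `manifest` (seeds and settings).
#' @export
make_study <- function(n_per_group = 10, noise = noise_spec("rician", snr = 50),
                       jitter = 1, seed = 1, protocol = default_protocol()) {
  if (n_per_group < 2) stop_validation("n_per_group must be >= 2")
  if (jitter < 0) stop_validation("jitter must be >= 0")
  datasets <- list()
  truth <- list()
  with_seed(seed, {
    for (grp in c("control", "apoptotic")) {
      preset <- group_preset(grp)
      for (i in seq_len(n_per_group)) {
        p <- preset$params
        draw <- unclass(p)
        for (nm in names(preset$sds)) {
          draw[[nm]] <- draw[[nm]] + jitter * preset$sds[[nm]] * rnorm(1)
        }
        draw$r <- max(draw$r, 0.6)
        draw$k_ie <- max(draw$k_ie, 0)
        draw$m_i0 <- min(max(draw$m_i0, 0.01), 0.99)
        draw$d_e_app <- max(draw$d_e_app, 0.06)
        draw$r1_e <- max(draw$r1_e, 0)
        pars <- two_pool_params(
          r = draw$r, k_ie = draw$k_ie, m_i0 = draw$m_i0, d_i = draw$d_i,
          d_e_app = draw$d_e_app, s0 = draw$s0, r1_i = draw$r1_i,
          r1_e = draw$r1_e
        )
        id <- sprintf("%s-%02d", grp, i)
        ds_noise <- noise_spec(noise$model, noise$snr,
                               seed = sample.int(.Machine$integer.max, 1))
        ds <- generate_dataset(list(name = grp, params = pars),
                               protocol = protocol, noise = ds_noise,
                               sample_id = id)
        datasets[[id]] <- ds
        truth[[id]] <- data.frame(
          sample_id = id, group = grp, r = pars$r, k_ie = pars$k_ie,
          m_i0 = pars$m_i0, d_i = pars$d_i, d_e_app = pars$d_e_app,
          s0 = pars$s0, r1_i = pars$r1_i, r1_e = pars$r1_e
        )
      }
    }
  })
  list(
    datasets = datasets,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    manifest = list(
      n_per_group = n_per_group, noise_model = noise$model, snr = noise$snr,
      jitter = jitter, seed = seed,
      b_values_s_per_mm2 = sort(unique(protocol$b_si)),
      deltas_ms = sort(unique(protocol$delta_sep))
    )
  )
}
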