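# Figures (ggplot2 is optional: Suggests).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_steamdiff("ggplot2 is required for figures", "steamdiff_dependency_error")
  }
}

#' Plot signal decay per gradient separation with fit and residuals
#'
#' Semilog signal-vs-b curves for each gradient separation with the
#' two-pool model overlaid, plus percent-difference residuals.
#'
#' @param dataset a [signal_dataset()].
#' @param fit optional [fit_two_pool()] result for the model overlay.
#' @return a ggplot object.
#' @export
plot_signal_fit <- function(dataset, fit = NULL) {
  .need_ggplot()
  df <- data.frame(
    b = dataset$protocol$b_si, delta_sep = factor(dataset$protocol$delta_sep),
    signal = dataset$signal, sigma = dataset$sigma
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(b, signal, colour = delta_sep)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(signal - sigma, 1e-12),
                                        ymax = signal + sigma), width = 0) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b (s/mm^2)", y = "signal",
                  colour = expression(Delta ~ "(ms)"),
                  title = sprintf("%s (%s)", dataset$sample_id, dataset$group))
  if (!is.null(fit)) {
    model <- steam_signal(fit$params, dataset$protocol,
                          fit$include_relaxation)
    mdf <- df
    mdf$signal <- model
    p <- p + ggplot2::geom_line(data = mdf)
  }
  p
}

#' Plot ADC and kurtosis versus gradient separation
#'
#' @param x a `study_report`, or a data frame from [kurtosis_series()].
#' @return a ggplot object (ADC and kurtosis facets).
#' @export
plot_kurtosis_series <- function(x) {
  .need_ggplot()
  if (inherits(x, "study_report")) {
    df <- do.call(rbind, lapply(names(x$kurtosis), function(id) {
      cbind(sample_id = id, group = x$fits[[id]]$group,
            x$kurtosis[[id]]$series)
    }))
  } else {
    df <- cbind(sample_id = "sample", group = "sample", as.data.frame(x))
  }
  long <- rbind(
    data.frame(df[c("sample_id", "group", "delta_sep")],
               quantity = "ADC (um^2/ms)", value = df$adc),
    data.frame(df[c("sample_id", "group", "delta_sep")],
               quantity = "kurtosis", value = df$kurtosis)
  )
  ggplot2::ggplot(long, ggplot2::aes(delta_sep, value, colour = group,
                                     group = sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(Delta ~ "(ms)"), y = NULL)
}

#' Boxplots of fitted parameters by group
#'
#' @param report a `study_report`.
#' @param params parameters to show.
#' @return a ggplot object.
#' @export
plot_param_boxplots <- function(report,
                                params = c("m_i0", "r", "k_ie", "d_e_app")) {
  .need_ggplot()
  tab <- report$parameters
  long <- do.call(rbind, lapply(params, function(pn) {
    data.frame(group = tab$group, parameter = pn, value = tab[[pn]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(group, value, fill = group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
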