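# Study-level orchestration: group statistics, pipeline, report writers.

#' Two-group comparison with percent change
#'
#' Two-sided two-sample t-test, pooled variance by default (the common
#' default of MATLAB-style `ttest2`; set `var_equal = FALSE` for Welch).
#' Percent change of group B relative to group A is reported two ways,
#' because they genuinely differ: from the group means,
#' \eqn{100 (\bar b - \bar a)/\bar a}, and - when the groups are paired and
#' of equal size - as the mean of per-pair changes
#' \eqn{100\,\mathrm{mean}((b_i - a_i)/a_i)}. Neither is preferred.
#'
#' @param values_a numeric vector, reference group (>= 2 values).
#' @param values_b numeric vector, comparison group (>= 2 values).
#' @param var_equal pooled variance (default) or Welch.
#' @return list: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `pct_change_means`, `pct_change_paired` (NA if unpaired/unequal n),
#'   `degenerate` flag (both groups constant).
#' @export
#' @examples
#' compare_groups(c(4.1, 4.2, 4.3), c(3.5, 3.6, 3.7))$pct_change_means
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_validation("need >= 2 values per group")
  }
  degenerate <- var(values_a) == 0 && var(values_b) == 0
  if (degenerate) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    tt <- list(statistic = if (same) 0 else Inf,
               parameter = length(values_a) + length(values_b) - 2,
               p.value = if (same) 1 else 0)
  } else {
    tt <- t.test(values_b, values_a, var.equal = var_equal)
  }
  ma <- mean(values_a)
  mb <- mean(values_b)
  paired <- if (length(values_a) == length(values_b) && all(values_a != 0)) {
    100 * mean((values_b - values_a) / values_a)
  } else {
    NA_real_
  }
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = unname(tt$p.value),
    mean_a = ma, mean_b = mb, sd_a = sd(values_a), sd_b = sd(values_b),
    pct_change_means = if (ma != 0) 100 * (mb - ma) / ma else NA_real_,
    pct_change_paired = paired,
    degenerate = degenerate
  )
}

.report_params <- c("m_i0", "r", "k_ie", "d_e_app", "r1_i", "r1_e", "s0")

#' Run the full analysis pipeline
#'
#' Orchestrates the study analysis: load datasets (or generate a seeded
#' synthetic study), fit the two-pool exchange model per sample, run the
#' kurtosis chain per sample (per-separation ADC/K, exchange-time fit, peak
#' location), compare groups per parameter, and optionally compute contour
#' confidence intervals and write tables, figures and a JSON report.
#'
#' The configuration is a YAML or JSON file (or an equivalent R list) with
#' blocks:
#' \preformatted{
#' study:    n_per_group, snr, noise (rician|gaussian), jitter, seed
#' datasets: [paths]          # alternative to 'study'
#' fit:      n_starts, seed, fixed (name: value), confidence
#' kurtosis: use               # separations in the exchange fit
#' contours: [[par1, par2], ...]
#' output:   dir, figures (true|false)
#' }
#' Identical config and seed give an identical report (no timestamps are
#' embedded). No multiple-testing correction is applied across parameters;
#' the report header says so.
#'
#' @param config path to a YAML/JSON config file, or a list.
#' @param out_dir output directory override; `NULL` writes nothing unless
#'   the config's `output$dir` is set.
#' @return a `study_report` list: `fits`, `kurtosis` (per sample),
#'   `kurtosis_group` (exchange-model fits to the group-mean kurtosis
#'   curves), `group_stats`, `comparisons`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_format(paste0("config not found: ", config))
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop_validation("'config' must be a file path or a list")
  }

  # ---- inputs ----
  datasets <- list()
  truth <- NULL
  if (!is.null(cfg$study)) {
    st <- cfg$study
    study <- make_study(
      n_per_group = st$n_per_group %||% 10,
      noise = noise_spec(st$noise %||% "rician", st$snr %||% 50),
      jitter = st$jitter %||% 1,
      seed = st$seed %||% 1
    )
    datasets <- study$datasets
    truth <- study$truth
  } else if (!is.null(cfg$datasets)) {
    paths <- unlist(cfg$datasets)
    if (length(paths) == 0) stop_validation("empty sample list in config")
    datasets <- lapply(paths, load_dataset)
    names(datasets) <- vapply(datasets, function(d) d$sample_id, character(1))
  } else {
    stop_validation("config must provide either a 'study' block or 'datasets'")
  }
  if (length(datasets) == 0) stop_validation("empty sample list")

  fit_cfg <- cfg$fit %||% list()
  fixed <- as.list(fit_cfg$fixed %||% list(d_i = 1.7))
  n_starts <- fit_cfg$n_starts %||% 20
  fit_seed <- fit_cfg$seed %||% 1
  confidence <- fit_cfg$confidence %||% 0.68
  kurt_use <- cfg$kurtosis$use %||% 4

  # ---- per-sample analyses ----
  fits <- list()
  kurt <- list()
  errors <- list()
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    res <- tryCatch({
      fit <- fit_two_pool(ds, fixed = fixed, n_starts = n_starts,
                          seed = fit_seed)
      ks <- kurtosis_series(ds)
      kx <- tryCatch(fit_kurtosis_exchange(ks, use = kurt_use),
                     error = function(e) NULL)
      pk <- tryCatch(suppressWarnings(find_kurtosis_peak(ks)),
                     error = function(e) NULL)
      list(fit = fit, kurtosis = list(series = ks, exchange = kx, peak = pk))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      fits[[id]] <- res$fit
      kurt[[id]] <- res$kurtosis
    }
  }
  if (length(fits) == 0) stop_fit("every sample failed; no report to write")

  # ---- tables ----
  par_tab <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    row <- as.data.frame(f$params[.report_params])
    cbind(data.frame(sample_id = id, group = f$group,
                     chi2_reduced = f$chi2_reduced), row)
  }))
  kurt_tab <- do.call(rbind, lapply(names(kurt), function(id) {
    kx <- kurt[[id]]$exchange
    pk <- kurt[[id]]$peak
    data.frame(
      sample_id = id, group = fits[[id]]$group,
      k0 = if (is.null(kx)) NA else kx$k0,
      tau_ex = if (is.null(kx)) NA else kx$tau_ex,
      k_inf = if (is.null(kx)) NA else kx$k_inf,
      k_total = if (is.null(kx)) NA else exchange_rate_from_tau(kx$tau_ex),
      t_peak = if (is.null(pk)) NA else pk$t_peak,
      peak_boundary = if (is.null(pk)) NA else pk$boundary
    )
  }))

  # ---- group-level kurtosis exchange fits (on the mean K(Delta) curve,
  # which is how multi-sample kurtosis summaries are usually analysed) ----
  kurt_group <- list()
  all_series <- do.call(rbind, lapply(names(kurt), function(id) {
    cbind(group = fits[[id]]$group, kurt[[id]]$series)
  }))
  for (grp in unique(all_series$group)) {
    gs <- all_series[all_series$group == grp, ]
    agg <- stats::aggregate(cbind(adc, kurtosis) ~ delta_sep + t_d, gs, mean)
    agg <- agg[order(agg$delta_sep), ]
    kurt_group[[grp]] <- list(
      series = agg,
      exchange = tryCatch(fit_kurtosis_exchange(agg, use = kurt_use),
                          error = function(e) NULL),
      peak = tryCatch(suppressWarnings(find_kurtosis_peak(agg)),
                      error = function(e) NULL)
    )
  }

  # ---- group statistics ----
  comparisons <- list()
  groups <- unique(par_tab$group)
  if (all(c("control", "apoptotic") %in% groups)) {
    for (pn in c(.report_params, "chi2_reduced")) {
      a <- par_tab[par_tab$group == "control", pn]
      b <- par_tab[par_tab$group == "apoptotic", pn]
      if (length(a) >= 2 && length(b) >= 2) {
        comparisons[[pn]] <- compare_groups(a, b)
      }
    }
    for (pn in c("k0", "tau_ex", "k_inf", "k_total")) {
      a <- na.omit(kurt_tab[kurt_tab$group == "control", pn])
      b <- na.omit(kurt_tab[kurt_tab$group == "apoptotic", pn])
      if (length(a) >= 2 && length(b) >= 2) {
        comparisons[[paste0("kurtosis_", pn)]] <- compare_groups(a, b)
      }
    }
  }
  group_stats <- do.call(rbind, lapply(split(par_tab, par_tab$group),
    function(gdf) {
      means <- vapply(c(.report_params, "chi2_reduced"),
                      function(p) mean(gdf[[p]]), numeric(1))
      sds <- vapply(c(.report_params, "chi2_reduced"),
                    function(p) sd(gdf[[p]]), numeric(1))
      data.frame(group = gdf$group[1], parameter = names(means),
                 mean = unname(means), sd = unname(sds),
                 row.names = NULL)
    }))
  rownames(group_stats) <- NULL

  # ---- contour intervals ----
  contours <- list()
  if (!is.null(cfg$contours)) {
    prs <- cfg$contours
    if (!is.list(prs[[1]])) prs <- list(prs)
    first_id <- names(fits)[1]
    for (pr in prs) {
      pr <- unlist(pr)
      key <- paste(pr, collapse = "-")
      contours[[key]] <- tryCatch(
        contour_interval(fits[[first_id]], datasets[[first_id]], pr,
                         confidence = confidence),
        error = function(e) conditionMessage(e))
    }
  }

  report <- structure(list(
    fits = fits, kurtosis = kurt, kurtosis_group = kurt_group,
    parameters = par_tab,
    kurtosis_parameters = kurt_tab, group_stats = group_stats,
    comparisons = comparisons, contours = contours, truth = truth,
    errors = errors,
    provenance = list(
      package_version = as.character(utils::packageVersion("steamdiff")),
      config = cfg, n_starts = n_starts, fit_seed = fit_seed,
      fixed = fixed, confidence = confidence,
      multiple_testing = "none",
      note = "two-sided pooled-variance t-tests; no multiplicity correction"
    )
  ), class = "study_report")

  out_dir <- out_dir %||% cfg$output$dir
  if (!is.null(out_dir)) {
    write_report(report, out_dir,
                 figures = isTRUE(cfg$output$figures))
  }
  report
}

#' Write a study report to disk
#'
#' Writes `parameters.csv`, `kurtosis_parameters.csv`, `group_stats.csv`,
#' contour traces (`contour_<pair>.csv`), a machine-readable `report.json`
#' (no timestamps, so identical inputs give byte-identical output), and
#' optionally figures (requires ggplot2).
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param figures write figures?
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, figures = FALSE) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$parameters, file.path(dir, "parameters.csv"),
            row.names = FALSE)
  write.csv(report$kurtosis_parameters,
            file.path(dir, "kurtosis_parameters.csv"), row.names = FALSE)
  write.csv(report$group_stats, file.path(dir, "group_stats.csv"),
            row.names = FALSE)
  for (key in names(report$contours)) {
    ci <- report$contours[[key]]
    if (is.list(ci) && !is.null(ci$trace)) {
      write.csv(ci$trace, file.path(dir, paste0("contour_", key, ".csv")),
                row.names = FALSE)
    }
  }
  json <- list(
    parameters = report$parameters,
    kurtosis_parameters = report$kurtosis_parameters,
    group_stats = report$group_stats,
    comparisons = report$comparisons,
    errors = report$errors,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    ids <- names(report$fits)
    grDevices::pdf(file.path(dir, "figures.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off())
    print(plot_param_boxplots(report))
    print(plot_kurtosis_series(report))
  }
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d fits (%d failed samples)\n",
              length(x$fits), length(x$errors)))
  if (length(x$kurtosis_group)) {
    cat("Group-mean kurtosis exchange fits:\n")
    for (grp in names(x$kurtosis_group)) {
      kx <- x$kurtosis_group[[grp]]$exchange
      pk <- x$kurtosis_group[[grp]]$peak
      if (!is.null(kx)) {
        cat(sprintf(
          "  %-10s K0 = %.3g, tau_ex = %.3g ms (rate %.3g s^-1), K_inf = %.3g, peak at %s ms\n",
          grp, kx$k0, kx$tau_ex, exchange_rate_from_tau(kx$tau_ex), kx$k_inf,
          if (is.null(pk)) "?" else format(pk$t_peak)))
      }
    }
  }
  if (length(x$comparisons)) {
    cat("Group comparisons (control vs apoptotic):\n")
    for (pn in names(x$comparisons)) {
      cm <- x$comparisons[[pn]]
      cat(sprintf("  %-18s p = %-9.3g mean %.3g -> %.3g (%+.1f%%)\n",
                  pn, cm$p_value, cm$mean_a, cm$mean_b, cm$pct_change_means))
    }
  }
  invisible(x)
}
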