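#' Construct a signal dataset
#'
#' A signal dataset couples an acquisition protocol with the mean ROI signal
#' per point and a per-point noise standard deviation (the ROI pixel std in
#' measured data), plus sample metadata.
#'
#' If `sigma` is `NULL` or contains missing values, absent entries are filled
#' with the mean sigma of the b = 0 rows (the unweighted images are the usual
#' source of a pixel-noise estimate); if no sigma information exists at all,
#' construction fails.
#'
#' @param protocol an [acquisition_protocol()].
#' @param signal numeric vector of mean ROI signals, one per protocol row
#'   (in the protocol's sorted order).
#' @param sigma per-point noise std, or `NULL`/partially `NA` (see Details).
#' @param group sample group: `"control"`, `"apoptotic"` or `"media"`.
#' @param sample_id sample label.
#' @return An object of class `signal_dataset`: a list with elements
#'   `protocol`, `signal`, `sigma`, `group`, `sample_id`.
#' @export
signal_dataset <- function(protocol, signal, sigma = NULL,
                           group = c("control", "apoptotic", "media"),
                           sample_id = "sample") {
  group <- match.arg(group)
  if (!inherits(protocol, "acq_protocol")) {
    stop_validation("'protocol' must be an acq_protocol")
  }
  if (length(signal) != nrow(protocol)) {
    stop_validation("one signal value is required per protocol point")
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    stop_validation("signal must be finite and >= 0")
  }
  if (is.null(sigma)) sigma <- rep(NA_real_, length(signal))
  sigma <- rep_len(as.numeric(sigma), length(signal))
  if (anyNA(sigma)) {
    b0 <- protocol$b == 0 & !is.na(sigma)
    if (!any(b0)) stop_validation("sigma missing and no b=0 sigma available to impute from")
    sigma[is.na(sigma)] <- mean(sigma[b0])
  }
  if (any(sigma <= 0)) stop_validation("sigma must be > 0")
  structure(
    list(protocol = protocol, signal = as.numeric(signal), sigma = sigma,
         group = group, sample_id = as.character(sample_id)),
    class = "signal_dataset"
  )
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf(
    "Signal dataset '%s' (%s): %d points, %d gradient separations, signal range [%.4g, %.4g]\n",
    x$sample_id, x$group, nrow(x$protocol),
    length(unique(x$protocol$delta_sep)), min(x$signal), max(x$signal)
  ))
  invisible(x)
}

#' @export
as.data.frame.signal_dataset <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id,
    group = x$group,
    b_s_per_mm2 = x$protocol$b_si,
    delta_sep_ms = x$protocol$delta_sep,
    delta_pulse_ms = x$protocol$delta_pulse,
    tm_ms = x$protocol$tm,
    te_ms = x$protocol$te,
    signal = x$signal,
    sigma = x$sigma
  )
}

.dataset_columns <- c(
  "sample_id", "group", "b_s_per_mm2", "delta_sep_ms", "delta_pulse_ms",
  "tm_ms", "te_ms", "signal", "sigma"
)

dataset_from_table <- function(df) {
  required <- setdiff(.dataset_columns, c("sigma", "tm_ms"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_format(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  protocol <- acquisition_protocol(
    b = df$b_s_per_mm2,
    delta_sep = df$delta_sep_ms,
    delta_pulse = df$delta_pulse_ms,
    tm = if ("tm_ms" %in% names(df)) df$tm_ms else NULL,
    te = df$te_ms,
    b_units = "s/mm2",
    name = as.character(df$sample_id[1])
  )
  ord <- order(df$delta_sep_ms, df$b_s_per_mm2 / 1000)
  sig <- if ("sigma" %in% names(df)) df$sigma[ord] else NULL
  signal_dataset(
    protocol = protocol,
    signal = df$signal[ord],
    sigma = sig,
    group = as.character(df$group[1]),
    sample_id = as.character(df$sample_id[1])
  )
}

#' Read a signal dataset from CSV or JSON
#'
#' The CSV schema has a header row with columns `sample_id, group,
#' b_s_per_mm2, delta_sep_ms, delta_pulse_ms, tm_ms, te_ms, signal, sigma`
#' (comma-separated, UTF-8, '.' decimal); `tm_ms` and `sigma` are optional.
#' The JSON schema mirrors the same field names one-to-one, scalars for
#' `sample_id`/`group` and arrays for the per-point columns. b-values are in
#' s/mm\eqn{^2} on disk and converted to canonical units exactly once on
#' load; rows are sorted by (\eqn{\Delta}, b).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return a [signal_dataset()].
#' @seealso [write_dataset()]
#' @export
load_dataset <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(obj)) stop_format("JSON dataset must be an object")
    df <- tryCatch(as.data.frame(obj, stringsAsFactors = FALSE),
                   error = function(e) stop_format(paste0("malformed JSON dataset: ", conditionMessage(e))))
  }
  dataset_from_table(df)
}

#' Write a signal dataset to CSV or JSON
#'
#' Values round-trip bit-exactly through [load_dataset()]: numerics are
#' serialized at full double precision and the as-ingested s/mm\eqn{^2}
#' b-values are written verbatim.
#'
#' @param x a [signal_dataset()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, format = c("auto", "csv", "json")) {
  if (!inherits(x, "signal_dataset")) stop_validation("'x' must be a signal_dataset")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- as.data.frame(x)
  if (format == "csv") {
    fmt <- df
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
    write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- c(
      list(sample_id = x$sample_id, group = x$group),
      as.list(df[setdiff(names(df), c("sample_id", "group"))])
    )
    # I(17) significant digits round-trips IEEE doubles exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}
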