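# internal helpers: classed conditions and seed hygiene

stop_steamdiff <- function(message, class) {
  stop(structure(
    class = c(class, "steamdiff_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_validation <- function(message) stop_steamdiff(message, "steamdiff_validation_error")
stop_format <- function(message) stop_steamdiff(message, "steamdiff_format_error")
stop_domain <- function(message) stop_steamdiff(message, "steamdiff_domain_error")
stop_numerical <- function(message) stop_steamdiff(message, "steamdiff_numerical_error")
stop_fit <- function(message) stop_steamdiff(message, "steamdiff_fit_error")

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
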