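# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a validation error
#'
#' Input-contract violations raise conditions of class
#' `prsblend_validation_error` so the command-line driver can map them to a
#' distinct exit code.
#'
#' @param ... passed to [sprintf()] to build the message.
#' @keywords internal
#' @noRd
stop_validation <- function(...) {
  msg <- sprintf(...)
  stop(structure(
    class = c("prsblend_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# key=value structured log line on stderr
log_kv <- function(event, ...) {
  kv <- list(...)
  parts <- c(
    sprintf("event=%s", event),
    if (length(kv)) paste0(names(kv), "=", vapply(kv, format, "", digits = 6))
  )
  message(paste(parts, collapse = " "))
  invisible(NULL)
}

# check a numeric vector: no NAs, finite
check_numeric <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x)) stop_validation("'%s' must be numeric", name)
  if (anyNA(x) || any(!is.finite(x))) {
    stop_validation("'%s' contains missing or non-finite values", name)
  }
  if (positive && any(x <= 0)) stop_validation("'%s' must be strictly positive", name)
  if (any(x < min) || any(x > max)) {
    stop_validation("'%s' must lie in [%s, %s]", name, format(min), format(max))
  }
  invisible(x)
}

check_same_length <- function(...) {
  xs <- list(...)
  n <- lengths(xs)
  if (length(unique(n)) != 1L) {
    stop_validation(
      "length mismatch between %s (%s)",
      paste(names(xs), collapse = ", "), paste(n, collapse = ", ")
    )
  }
  invisible(n[[1]])
}
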