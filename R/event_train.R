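#' Event trains: (time, amplitude) sequences with optional responses
#'
#' An event train represents a stimulation or response sequence as a series of
#' variable-amplitude, random-interval delta functions
#' \eqn{x(t) = \sum_i A_i\, \delta(t - t_i)}: strictly increasing event times
#' (seconds) with one non-negative amplitude per event, and optionally one
#' contemporaneous output (response) amplitude per event.  Typical units are
#' microamperes for stimulation amplitudes and millivolts for evoked-response
#' amplitudes (population-spike or fEPSP peaks extracted upstream).
#'
#' @param times Numeric vector of event times in seconds, strictly increasing.
#' @param amplitudes Numeric vector of input amplitudes, same length,
#'   finite and non-negative.
#' @param outputs Optional numeric vector of contemporaneous response
#'   amplitudes, same length (or `NULL`).
#' @param train_id Character label for the train.
#' @param units Named character vector tagging units, e.g.
#'   `c(amplitude = "uA", output = "mV")`.
#' @return An object of class `"event_train"`.
#' @export
#' @examples
#' event_train(c(0, 0.05, 1), c(150, 150, 200), train_id = "demo")
event_train <- function(times, amplitudes, outputs = NULL,
                        train_id = "train1",
                        units = c(amplitude = "uA", output = "mV")) {
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes)) {
    stop("`times` and `amplitudes` must have equal length", call. = FALSE)
  }
  if (length(times) && (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))) {
    stop(sprintf("event times must be finite and strictly increasing (train '%s')",
                 train_id), call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(outputs)) {
    outputs <- as.numeric(outputs)
    if (length(outputs) != length(times)) {
      stop("`outputs` must have one value per event", call. = FALSE)
    }
    if (any(!is.finite(outputs))) {
      stop("outputs must be finite", call. = FALSE)
    }
  }
  structure(
    list(times = times, amplitudes = amplitudes, outputs = outputs,
         train_id = as.character(train_id), units = units),
    class = "event_train"
  )
}

as_event_train <- function(x) {
  if (inherits(x, "event_train")) return(x)
  if (is.list(x) && !is.null(x$times) && !is.null(x$amplitudes)) {
    return(event_train(x$times, x$amplitudes, x$outputs,
                       train_id = x$train_id %||% "train1"))
  }
  stop("cannot interpret input as an event train", call. = FALSE)
}

# accept a single train or a list of trains; always return a named list
as_train_list <- function(x) {
  if (inherits(x, "event_train")) x <- list(x)
  x <- lapply(x, as_event_train)
  names(x) <- vapply(x, `[[`, character(1), "train_id")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.event_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Event train '%s': %d events over %.3f s\n",
              x$train_id, n, if (n) diff(range(x$times)) else 0))
  cat(sprintf("  amplitude [%s]: mean %.3g, range [%.3g, %.3g]\n",
              x$units[["amplitude"]] %||% "?", mean(x$amplitudes),
              min(x$amplitudes), max(x$amplitudes)))
  if (!is.null(x$outputs)) {
    cat(sprintf("  output [%s]: mean %.3g, range [%.3g, %.3g]\n",
                x$units[["output"]] %||% "?", mean(x$outputs),
                min(x$outputs), max(x$outputs)))
  } else {
    cat("  no outputs recorded\n")
  }
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$times)

#' @export
as.data.frame.event_train <- function(x, ...) {
  data.frame(train_id = rep(x$train_id, length(x$times)),
             time_s = x$times,
             amplitude = x$amplitudes,
             output = if (is.null(x$outputs)) NA_real_ else x$outputs,
             stringsAsFactors = FALSE)
}
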