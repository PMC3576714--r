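#' Variance accounted for
#'
#' `VAF = 1 - var(Y - X) / var(Y)`, where `Y` are observed and `X` predicted
#' amplitudes.  Sample variance (denominator `n - 1`) is used; the value is
#' identical under the population convention since the factor cancels.  Note
#' that because only the *variance* of the residual enters, a constant offset
#' between prediction and observation does not reduce VAF.
#'
#' @param Y Observed amplitudes (length >= 2, non-constant).
#' @param X Predicted amplitudes, same length.
#' @return VAF as a fraction (1 = perfect); multiply by 100 for percent.
#' @export
#' @examples
#' vaf(c(1, 2, 3), c(1, 2, 5))  # -1/3
vaf <- function(Y, X) {
  check_metric_args(Y, X, min_n = 2L)
  vy <- stats::var(Y)
  if (vy == 0) stop("VAF undefined: var(Y) is zero", call. = FALSE)
  1 - stats::var(Y - X) / vy
}

#' Normalized mean-square error
#'
#' `NMSE = sum((Y - X)^2) / sum(Y^2)`.  The denominator is the *uncentered*
#' sum of squared observed values (not the variance), so a zero predictor
#' scores exactly 1.
#'
#' @inheritParams vaf
#' @return NMSE as a fraction (0 = perfect); multiply by 100 for percent.
#' @export
#' @examples
#' nmse(c(3, 4), c(3, 0))  # 16/25
nmse <- function(Y, X) {
  check_metric_args(Y, X, min_n = 1L)
  ss <- sum(Y^2)
  if (ss == 0) stop("NMSE undefined: sum(Y^2) is zero", call. = FALSE)
  sum((Y - X)^2) / ss
}

#' Quantile-quantile comparison of two amplitude series
#'
#' Sorts each series ascending and pairs them by rank, for distributional
#' comparison of observed vs predicted amplitudes; reports the maximum
#' absolute deviation from the identity line.
#'
#' @inheritParams vaf
#' @return List of class `"lv_qq"`: `qy`, `qx` (sorted series), and
#'   `max_abs_dev`.
#' @export
qq_points <- function(Y, X) {
  check_metric_args(Y, X, min_n = 1L)
  qy <- sort(Y); qx <- sort(X)
  structure(list(qy = qy, qx = qx, max_abs_dev = max(abs(qy - qx))),
            class = "lv_qq")
}

#' @export
print.lv_qq <- function(x, ...) {
  cat(sprintf("Q-Q comparison of %d paired quantiles; max |deviation| = %.4g\n",
              length(x$qy), x$max_abs_dev))
  invisible(x)
}

#' @export
plot.lv_qq <- function(x, ...) {
  graphics::plot(x$qx, x$qy, xlab = "predicted quantiles",
                 ylab = "observed quantiles", main = "Q-Q plot", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Full metrics report for an observed/predicted pair
#'
#' @inheritParams vaf
#' @return List with `vaf`, `vaf_pct`, `nmse`, `nmse_pct`, `n`, and `qq`.
#' @export
metrics_report <- function(Y, X) {
  list(vaf = vaf(Y, X), vaf_pct = 100 * vaf(Y, X),
       nmse = nmse(Y, X), nmse_pct = 100 * nmse(Y, X),
       n = length(Y), qq = qq_points(Y, X))
}

check_metric_args <- function(Y, X, min_n) {
  if (length(Y) != length(X)) {
    stop("`Y` and `X` must have equal length", call. = FALSE)
  }
  if (length(Y) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  if (any(!is.finite(Y)) || any(!is.finite(X))) {
    stop("`Y` and `X` must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
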