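#' Regression design matrix for Laguerre-Volterra estimation
#'
#' Builds the least-squares design matrix whose row for event `i` is
#' `[1, A_i, A_i^2, v_1..v_L, {v_l1 v_l2 : l1 <= l2}, 2 A_i v_1 .. 2 A_i v_L]`.
#' Off-diagonal second-order products (`l1 < l2`) are folded into a single
#' column carrying `2 v_l1 v_l2`, so the fitted coefficient is the shared
#' symmetric entry `c2(l1, l2)` of the double sum; cross-term columns carry
#' `2 A_i v_l` so the fitted coefficient is `c2(l)` directly.  Trains are
#' treated as independent: the Laguerre history resets at each train start.
#'
#' @param basis A [laguerre_basis()].
#' @param trains An [event_train()] or list of them; every train must carry
#'   outputs.
#' @return A list with `X` (design matrix, one row per event, named columns),
#'   `y` (stacked outputs), and `train` (train id per row).
#' @export
lv_design_matrix <- function(basis, trains) {
  trains <- as_train_list(trains)
  missing_out <- vapply(trains, function(tr) is.null(tr$outputs), logical(1))
  if (any(missing_out)) {
    stop(sprintf("train(s) without outputs: %s",
                 paste(names(trains)[missing_out], collapse = ", ")),
         call. = FALSE)
  }
  Xs <- lapply(trains, function(tr) design_rows(basis, tr))
  list(X = do.call(rbind, Xs),
       y = unlist(lapply(trains, `[[`, "outputs"), use.names = FALSE),
       train = rep(names(trains), vapply(trains, length, integer(1))))
}

design_rows <- function(basis, train) {
  train <- as_event_train(train)
  V <- convolve_events(basis, train)               # n x L
  L <- basis$n_basis
  A <- train$amplitudes
  ut <- which(upper.tri(diag(L), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  quad <- V[, ut[, 1L], drop = FALSE] * V[, ut[, 2L], drop = FALSE]
  off <- ut[, 1L] != ut[, 2L]
  quad[, off] <- 2 * quad[, off, drop = FALSE]     # folded symmetric column
  X <- cbind(1, A, A^2, V, quad, 2 * A * V)
  colnames(X) <- lv_param_names(L)
  X
}

#' Fit a Laguerre-Volterra model by least squares
#'
#' Estimates the expansion coefficients from one or more event trains with
#' recorded outputs, minimising the residual sum of squares by SVD-based
#' least squares (optionally ridge-penalised, intercept excluded from the
#' penalty).  The returned model carries a fit report with the design
#' condition number, residuals, and per-train in-sample VAF/NMSE.
#'
#' @param trains An [event_train()] or list of them, all with outputs.
#' @param alpha Laguerre decay parameter (default 0.7).
#' @param n_basis Number of basis functions (default 3).
#' @param memory Kernel memory window in seconds (default 3).
#' @param dt Lag-bin width in seconds (default 0.001).
#' @param ridge Optional non-negative ridge penalty (default 0 = ordinary
#'   least squares).
#' @param basis Alternatively, supply a prebuilt [laguerre_basis()] (overrides
#'   `alpha`, `n_basis`, `memory`, `dt`).
#' @return An object of class `"lv_model"` with components `coefficients`
#'   ([lv_coefficients()]), `basis`, and `fit` (list: `n_events`, `n_params`,
#'   `condition_number`, `residuals`, `fitted`, `per_train_vaf`,
#'   `per_train_nmse`).
#' @seealso [predict.lv_model()], [lv_cross_validate()], [volterra_kernels()]
#' @export
#' @examples
#' b <- laguerre_basis(0.9, 2, 100, 0.01)
#' truth <- lv_model(lv_coefficients(0.1, 0.01, -2e-5, c(5e-3, 1e-3),
#'                                   diag(c(-1e-5, 0)), c(1e-6, 0)), b)
#' tr <- generate_rarit(n_trains = 2, n_pulses = 80)
#' tr <- lapply(tr, function(t) simulate(truth, train = t, noise_sd = 0))
#' fit <- lv_fit(tr, basis = b)
#' max(abs(coef(fit) - coef(truth)))
lv_fit <- function(trains, alpha = 0.7, n_basis = 3, memory = 3, dt = 0.001,
                   ridge = 0, basis = NULL) {
  basis <- basis %||% laguerre_basis(alpha, n_basis, round(memory / dt), dt)
  dm <- lv_design_matrix(basis, trains)
  fit <- fit_least_squares(dm$X, dm$y, ridge = ridge)
  trains <- as_train_list(trains)
  per_vaf <- per_nmse <- numeric(length(trains))
  for (k in seq_along(trains)) {
    rows <- dm$train == names(trains)[k]
    per_vaf[k] <- tryCatch(vaf(dm$y[rows], fit$fitted[rows]),
                           error = function(e) NA_real_)
    per_nmse[k] <- tryCatch(nmse(dm$y[rows], fit$fitted[rows]),
                            error = function(e) NA_real_)
  }
  m <- lv_model(fit$coefficients, basis,
                units = trains[[1L]]$units)
  m$fit <- c(fit[c("n_events", "n_params", "condition_number",
                   "residuals", "fitted")],
             list(per_train_vaf = per_vaf, per_train_nmse = per_nmse,
                  train_ids = names(trains), ridge = ridge))
  m$call <- match.call()
  m
}

#' Solve the Laguerre-Volterra normal equations
#'
#' Lower-level workhorse behind [lv_fit()]: solves `min ||y - X b||^2`
#' (`+ ridge * ||b[-1]||^2` when `ridge > 0`) for a design built by
#' [lv_design_matrix()], via singular value decomposition.  Rank deficiency
#' without ridge is an error naming the dependent columns.
#'
#' @param X Design matrix with the canonical column order/names.
#' @param y Response vector.
#' @param ridge Non-negative penalty (intercept unpenalised).
#' @return List with `coefficients` ([lv_coefficients()]), `beta`,
#'   `fitted`, `residuals`, `n_events`, `n_params`, `condition_number`.
#' @export
fit_least_squares <- function(X, y, ridge = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  if (n < p && ridge == 0) {
    stop(sprintf("fewer events (%d) than parameters (%d); supply more data or ridge > 0",
                 n, p), call. = FALSE)
  }
  sv <- svd(X)
  cond <- sv$d[1L] / sv$d[p]
  if (ridge == 0) {
    tol <- max(n, p) * .Machine$double.eps * sv$d[1L]
    if (any(sv$d < tol)) {
      qx <- qr(X, LAPACK = FALSE)
      bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
      stop(sprintf("design matrix is rank deficient; dependent column(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    beta <- sv$v %*% (crossprod(sv$u, y) / sv$d)
  } else {
    # ridge on all but the intercept, via augmented normal equations
    D <- diag(c(0, rep(1, p - 1L)))
    beta <- solve(crossprod(X) + ridge * D, crossprod(X, y))
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  L <- lv_order_from_params(p)
  list(coefficients = coef_from_vector(beta, L), beta = beta,
       fitted = fitted, residuals = y - fitted,
       n_events = n, n_params = p, condition_number = cond)
}

lv_order_from_params <- function(p) {
  for (L in 1:64) if (n_lv_params(L) == p) return(L)
  stop("column count does not match any Laguerre-Volterra model order",
       call. = FALSE)
}

#' @export
summary.lv_model <- function(object, ...) {
  structure(list(model = object), class = "summary.lv_model")
}

#' @export
print.summary.lv_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$fit)) {
    tab <- data.frame(train = m$fit$train_ids,
                      VAF_pct = round(100 * m$fit$per_train_vaf, 2),
                      NMSE_pct = round(100 * m$fit$per_train_nmse, 2))
    cat("\nPer-train in-sample fit:\n")
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Leave-one-train-out cross-validation over basis configurations
#'
#' For each candidate configuration `(alpha, n_basis, memory)` and each fold
#' (one held-out train), fits the model on the remaining trains, predicts the
#' held-out train, and scores held-out VAF and NMSE.  Independent data are
#' thus used for estimation and prediction; the configuration maximising mean
#' held-out VAF is reported as best.
#'
#' @param trains List of at least two [event_train()]s with outputs.
#' @param grid Data frame with columns `alpha`, `n_basis`, `memory` (one row
#'   per candidate configuration).  Defaults to the single default
#'   configuration.
#' @param dt Lag-bin width in seconds.
#' @param ridge Ridge penalty passed to [lv_fit()].
#' @return Object of class `"lv_cv"`: list with `results` (per-configuration
#'   data frame: mean/sd of held-out VAF and NMSE), `folds` (per-fold
#'   records), `best` (row index of the best configuration), and
#'   `best_model` (final fit of the best configuration on all trains).
#' @export
lv_cross_validate <- function(trains,
                              grid = data.frame(alpha = 0.7, n_basis = 3,
                                                memory = 3),
                              dt = 0.001, ridge = 0) {
  trains <- as_train_list(trains)
  if (length(trains) < 2L) {
    stop("cross-validation requires at least 2 trains", call. = FALSE)
  }
  req <- c("alpha", "n_basis", "memory")
  if (!all(req %in% names(grid))) {
    stop("`grid` needs columns alpha, n_basis, memory", call. = FALSE)
  }
  folds <- list()
  res <- grid
  res$mean_vaf <- res$sd_vaf <- res$mean_nmse <- res$sd_nmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    basis <- laguerre_basis(grid$alpha[g], grid$n_basis[g],
                            round(grid$memory[g] / dt), dt)
    fv <- fn <- numeric(length(trains))
    for (k in seq_along(trains)) {
      fit <- lv_fit(trains[-k], basis = basis, ridge = ridge)
      pred <- predict(fit, trains[[k]])
      fv[k] <- vaf(trains[[k]]$outputs, pred)
      fn[k] <- nmse(trains[[k]]$outputs, pred)
      folds[[length(folds) + 1L]] <-
        data.frame(config = g, held_out = names(trains)[k],
                   vaf = fv[k], nmse = fn[k])
    }
    res$mean_vaf[g] <- mean(fv); res$sd_vaf[g] <- stats::sd(fv)
    res$mean_nmse[g] <- mean(fn); res$sd_nmse[g] <- stats::sd(fn)
  }
  best <- which.max(res$mean_vaf)
  best_basis <- laguerre_basis(grid$alpha[best], grid$n_basis[best],
                               round(grid$memory[best] / dt), dt)
  structure(list(results = res, folds = do.call(rbind, folds), best = best,
                 best_model = lv_fit(trains, basis = best_basis,
                                     ridge = ridge)),
            class = "lv_cv")
}

#' @export
print.lv_cv <- function(x, ...) {
  cat(sprintf("Leave-one-train-out cross-validation (%d configuration%s, %d folds each)\n",
              nrow(x$results), if (nrow(x$results) > 1) "s" else "",
              length(unique(x$folds$held_out))))
  res <- x$results
  res$mean_vaf <- sprintf("%.2f%%", 100 * res$mean_vaf)
  res$mean_nmse <- sprintf("%.2f%%", 100 * res$mean_nmse)
  print(res[, c("alpha", "n_basis", "memory", "mean_vaf", "mean_nmse")],
        row.names = FALSE)
  cat(sprintf("Best configuration: row %d (alpha = %g, L = %d, memory = %g s)\n",
              x$best, res$alpha[x$best], as.integer(res$n_basis[x$best]),
              res$memory[x$best]))
  invisible(x)
}
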