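#' Read event trains from CSV
#'
#' Reads a CSV with header `train_id,time_s,amplitude[,output]` (an empty or
#' all-missing `output` column is treated as absent) into a list of
#' [event_train()]s grouped by `train_id`.  An optional leading comment line
#' of the form `# units: amplitude=uA output=mV` sets the unit tags;
#' otherwise uA/mV are assumed.  Times must be strictly increasing within
#' each train.
#'
#' @param path CSV file path.
#' @return Named list of [event_train()]s, in order of first appearance.
#' @export
read_event_trains <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  units <- c(amplitude = "uA", output = "mV")
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*units:", first)) {
    for (kv in strsplit(sub("^#\\s*units:\\s*", "", first), "\\s+")[[1L]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(p) == 2L) units[p[1L]] <- p[2L]
    }
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  need <- c("train_id", "time_s", "amplitude")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  for (col in intersect(c("time_s", "amplitude", "output"), names(df))) {
    if (!is.numeric(df[[col]])) {
      df[[col]] <- suppressWarnings(as.numeric(as.character(df[[col]])))
    }
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$amplitude))
  if (length(bad)) {
    stop(sprintf("%s: malformed row(s) at data line %s",
                 path, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  has_out <- "output" %in% names(df) && any(!is.na(df$output))
  ids <- unique(df$train_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$train_id == id, ]
    event_train(rows$time_s, rows$amplitude,
                outputs = if (has_out) rows$output else NULL,
                train_id = id, units = units)
  })
  names(out) <- ids
  out
}

#' Write event trains to CSV
#'
#' Inverse of [read_event_trains()]: writes all trains into one CSV with a
#' `# units:` comment header, at full (17 significant digit) precision.
#'
#' @param trains An [event_train()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_trains <- function(trains, path) {
  trains <- as_train_list(trains)
  u <- trains[[1L]]$units
  df <- do.call(rbind, lapply(trains, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: amplitude=%s output=%s",
                     u[["amplitude"]] %||% "uA", u[["output"]] %||% "mV"), con)
  # full precision so a write/read round trip is exact
  for (col in c("time_s", "amplitude", "output")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df$output[df$output == "NA"] <- ""
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a Laguerre-Volterra model as JSON
#'
#' Serialises the basis *parameters* and the coefficients (plus optional fit
#' metadata); the tabulated basis is regenerated deterministically on load,
#' never stored.
#'
#' @param model An `lv_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lv_model <- function(model, path) {
  stopifnot(inherits(model, "lv_model"))
  b <- model$basis
  co <- model$coefficients
  obj <- list(
    basis = list(alpha = b$alpha, n_basis = b$n_basis, n_lags = b$n_lags,
                 dt = b$dt),
    coefficients = list(c0 = co$c0, c1_present = co$c1_present,
                        c2_present = co$c2_present, c1 = co$c1,
                        c2 = co$c2, c2_cross = co$c2_cross),
    metadata = list(units = as.list(model$units),
                    preset = model$preset,
                    fit = if (!is.null(model$fit)) {
                      list(n_events = model$fit$n_events,
                           vaf_pct = 100 * mean(model$fit$per_train_vaf),
                           nmse_pct = 100 * mean(model$fit$per_train_nmse),
                           train_ids = model$fit$train_ids)
                    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a Laguerre-Volterra model from JSON
#'
#' @param path JSON path written by [write_lv_model()].
#' @return An `lv_model` (without fit residuals; summary fit metadata, if
#'   present, is kept in `$metadata`).
#' @export
read_lv_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$basis) || is.null(obj$coefficients)) {
    stop(sprintf("%s is not a Laguerre-Volterra model file", path),
         call. = FALSE)
  }
  b <- obj$basis
  basis <- laguerre_basis(b$alpha, b$n_basis, b$n_lags, b$dt)
  co <- obj$coefficients
  coeffs <- lv_coefficients(co$c0, co$c1_present, co$c2_present, co$c1,
                            matrix(unlist(co$c2), b$n_basis, b$n_basis),
                            co$c2_cross)
  units <- c(amplitude = "uA", output = "mV")
  mu <- obj$metadata$units
  if (!is.null(mu)) units[names(mu)] <- unlist(mu)
  m <- lv_model(coeffs, basis, units = units)
  m$metadata <- obj$metadata
  m
}
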