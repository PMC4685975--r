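# Readers and writers: packaged model coefficients (JSON), treatment-mean
# CSV files, and fit reports.

#' Load transfer-model coefficients
#'
#' Reads a JSON coefficients file into a named list of [new_iodine_model()]
#' objects.  With `path = NULL` the coefficients packaged with lactiodine
#' (the two published models) are loaded; the packaged file must contain
#' exactly 9 terms for model 1 and 6 for model 2, and any file is validated
#' for unique, well-formed term descriptors and finite estimates.
#'
#' @param path Path to a coefficients JSON file, or `NULL` for the packaged
#'   defaults.
#' @param validity A [validity_ranges()] object attached to every model.
#' @return Named list of `iodine_model` objects.
#' @examples
#' models <- load_coefficients()
#' names(models)
#' @export
load_coefficients <- function(path = NULL, validity = validity_ranges()) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "transfer_models.json",
                        package = "lactiodine", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("coefficients file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) {
                    stop("malformed coefficients JSON (", path, "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("coefficients file must map model ids to model objects", call. = FALSE)
  }
  models <- list()
  for (id in names(raw)) {
    models[[id]] <- .coefficients_entry_to_model(raw[[id]], id, path, validity)
  }
  if (packaged) {
    n_terms <- vapply(models, function(m) length(m$terms), 0L)
    expected <- c(model1 = 9L, model2 = 6L)
    if (!identical(n_terms[names(expected)], expected)) {
      stop("packaged coefficients corrupted: expected 9 terms (model1) and 6 (model2)",
           call. = FALSE)
    }
  }
  models
}

.coefficients_entry_to_model <- function(entry, id, path, validity) {
  terms <- entry$terms
  if (is.null(terms)) {
    stop("field '", id, ".terms' missing in ", path, call. = FALSE)
  }
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  for (col in c("term", "estimate")) {
    if (!col %in% names(terms)) {
      stop("field '", id, ".terms.", col, "' missing in ", path, call. = FALSE)
    }
  }
  if (!is.numeric(terms$estimate) || anyNA(terms$estimate)) {
    stop("field '", id, ".terms.estimate' must be numeric and complete",
         call. = FALSE)
  }
  cf <- data.frame(term = as.character(terms$term),
                   estimate = terms$estimate,
                   se = if ("se" %in% names(terms)) terms$se else NA_real_,
                   ci_low = if ("ci_low" %in% names(terms)) terms$ci_low else NA_real_,
                   ci_high = if ("ci_high" %in% names(terms)) terms$ci_high else NA_real_,
                   p = if ("p" %in% names(terms)) terms$p else NA_real_,
                   stringsAsFactors = FALSE)
  if ("p_censored" %in% names(terms)) cf$p_censored <- terms$p_censored
  new_iodine_model(
    coefficients = cf,
    covariate = if (is.null(entry$covariate)) NA_character_ else entry$covariate,
    model_id = id,
    n_obs = if (is.null(entry$n_obs)) NA_integer_ else as.integer(entry$n_obs),
    error_df = if (is.null(entry$error_df)) NA_integer_ else as.integer(entry$error_df),
    rmse = if (is.null(entry$rmse)) NA_real_ else entry$rmse,
    adj_r2 = if (is.null(entry$adj_r2)) NA_real_ else entry$adj_r2,
    rmsecv = if (is.null(entry$rmsecv)) NA_real_ else entry$rmsecv,
    validity = validity)
}

#' Write transfer-model coefficients to JSON
#'
#' Inverse of [load_coefficients()]: a written file reads back to identical
#' coefficients.
#'
#' @param models Named list of `iodine_model` objects (or a single model).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_coefficients <- function(models, path) {
  if (inherits(models, "iodine_model")) {
    models <- stats::setNames(list(models),
                              models$model_id %||% "model")
  }
  out <- lapply(models, function(m) {
    list(covariate = m$covariate, n_obs = m$n_obs, error_df = m$error_df,
         rmse = m$rmse, adj_r2 = m$adj_r2, rmsecv = m$rmsecv,
         terms = m$coefficients)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a treatment-means CSV file
#'
#' Reads the fitting-dataset dialect: UTF-8 CSV with header
#' `study_id,iodine_in,gsl,rapeseed,milk_iodine`; an empty cell means the
#' covariate was not reported for that treatment.  Rows where both `gsl` and
#' `rapeseed` are blank cannot enter either model and are excluded with a
#' warning; non-positive milk iodine is rejected (the response is a strictly
#' positive concentration that is log-transformed for fitting).
#'
#' @param path CSV file path.
#' @return Data frame of treatment means (one row per dietary treatment
#'   group-mean).
#' @export
read_treatment_means <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty input file: ", path, call. = FALSE)
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            stringsAsFactors = FALSE)
  required <- c("study_id", "iodine_in", "gsl", "rapeseed", "milk_iodine")
  if (!all(required %in% as.character(header[1, ]))) {
    stop("missing header column(s): ",
         paste(setdiff(required, as.character(header[1, ])), collapse = ", "),
         call. = FALSE)
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(study_id = "character"))
  if (nrow(dat) == 0L) stop("empty input file (no data rows): ", path, call. = FALSE)
  for (col in c("iodine_in", "gsl", "rapeseed", "milk_iodine")) {
    x <- dat[[col]]
    if (is.character(x)) {
      x[x == ""] <- NA
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "', row ", bad[1],
             ": '", x[bad[1]], "'", call. = FALSE)
      }
      dat[[col]] <- conv
    } else {
      dat[[col]] <- as.numeric(x)
    }
  }
  bad_resp <- which(is.na(dat$milk_iodine) | dat$milk_iodine <= 0)
  if (length(bad_resp)) {
    stop("milk_iodine must be a positive concentration; offending row(s): ",
         paste(bad_resp, collapse = ", "), call. = FALSE)
  }
  no_cov <- which(is.na(dat$gsl) & is.na(dat$rapeseed))
  if (length(no_cov)) {
    warning("excluding ", length(no_cov),
            " row(s) with neither gsl nor rapeseed reported: row(s) ",
            paste(no_cov, collapse = ", "), call. = FALSE)
    dat <- dat[-no_cov, , drop = FALSE]
    rownames(dat) <- NULL
  }
  dat
}

#' Write a treatment-means CSV file
#'
#' @param data Treatment-means data frame (see [read_treatment_means()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_treatment_means <- function(data, path) {
  cols <- c("study_id", "iodine_in", "gsl", "rapeseed", "milk_iodine")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write a fit report
#'
#' Writes the coefficient table and fit statistics of an `iodine_model` as
#' CSV (full-precision plus display-rounded estimate columns) or JSON.
#'
#' @param fit An `iodine_model`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @return Invisibly, `path`.
#' @export
write_report <- function(fit, path, format = NULL) {
  stopifnot(inherits(fit, "iodine_model"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  cf <- fit$coefficients
  cf$estimate_display <- signif(cf$estimate, 3)
  stats <- list(n_obs = fit$n_obs, error_df = fit$error_df, rmse = fit$rmse,
                adj_r2 = fit$adj_r2, rmsecv = fit$rmsecv)
  if (format == "json") {
    jsonlite::write_json(list(model_id = fit$model_id,
                              covariate = fit$covariate,
                              statistics = stats, coefficients = cf),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", paste(sprintf("%s=%s", names(stats),
                                          vapply(stats, base::format, "")),
                                  collapse = " ")), con)
    utils::write.csv(cf, con, row.names = FALSE)
  }
  invisible(path)
}
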