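# Validity ranges of the transfer models.
#
# The published models interpolate the source feeding trials; outside the
# covariate ranges those trials span, the cubic terms extrapolate wildly
# (rapeseed turns upward past ~180 g/kg DM, iodine past ~4 mg/kg DM).  The
# packaged defaults are the declared validity limits; predictions outside
# them are computed but flagged, or refused under `strict`.

#' Validity ranges for the transfer models
#'
#' @param iodine_in Closed interval for feed iodine, mg I/kg dry matter.
#' @param gsl Closed interval for glucosinolate intake, mmol/day.
#' @param rapeseed Closed interval for rapeseed cake/meal inclusion,
#'   g/kg dry matter.
#' @return A named list of length-2 numeric ranges, class `validity_ranges`.
#' @export
validity_ranges <- function(iodine_in = c(0, 4), gsl = c(0, 14),
                            rapeseed = c(0, 180)) {
  ranges <- list(iodine_in = as.numeric(iodine_in),
                 gsl = as.numeric(gsl),
                 rapeseed = as.numeric(rapeseed))
  for (v in names(ranges)) {
    r <- ranges[[v]]
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop("validity range for '", v, "' must be an ordered length-2 interval",
           call. = FALSE)
    }
  }
  structure(ranges, class = "validity_ranges")
}

#' Check rations against validity ranges
#'
#' @param data Data frame of rations (columns `iodine_in` and/or `gsl`,
#'   `rapeseed`).
#' @param ranges A [validity_ranges()] object.
#' @param variables Which variables to check; defaults to those present in
#'   both `data` and `ranges`.
#' @return Data frame with one row per violation: `row`, `variable`, `value`,
#'   `lower`, `upper`.  Zero rows when everything is in range.
#' @export
check_validity <- function(data, ranges = validity_ranges(),
                           variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) variables <- intersect(names(ranges), names(data))
  out <- list()
  for (v in variables) {
    if (!v %in% names(data)) next
    x <- as.numeric(data[[v]])
    r <- ranges[[v]]
    bad <- which(x < r[1] | x > r[2])
    if (length(bad)) {
      out[[v]] <- data.frame(row = bad, variable = v, value = x[bad],
                             lower = r[1], upper = r[2],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), variable = character(0),
                      value = numeric(0), lower = numeric(0),
                      upper = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row), , drop = FALSE]
}

.violation_message <- function(violations) {
  paste(sprintf("row %d: %s = %g outside [%g, %g]",
                violations$row, violations$variable, violations$value,
                violations$lower, violations$upper),
        collapse = "; ")
}

# warn (default) or stop (strict) on range violations
.handle_violations <- function(violations, strict) {
  if (nrow(violations) == 0L) return(invisible(violations))
  msg <- .violation_message(violations)
  if (strict) {
    stop("input outside the model's validity range: ", msg, call. = FALSE)
  }
  warning("prediction outside the model's validity range: ", msg,
          call. = FALSE)
  invisible(violations)
}
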