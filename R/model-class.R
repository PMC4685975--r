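# The iodine_model class.
#
# An iodine_model holds a log-scale polynomial transfer model for milk iodine:
# log(milk iodine, ug/kg) = sum over terms of coefficient * term value, with
# terms in feed iodine (mg I/kg DM) and one goitrogen covariate (glucosinolate
# intake, mmol/day, or rapeseed cake/meal inclusion, g/kg DM).  The two
# published models and fits produced by milk_iodine_fit() share this class.

#' Construct an iodine transfer model object
#'
#' Low-level constructor; users normally obtain models from
#' [milk_iodine_model()] (the packaged published models) or
#' [milk_iodine_fit()] (fits to treatment-mean data).
#'
#' @param coefficients Data frame with columns `term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p` (inference columns may be `NA`).
#' @param covariate `"gsl"` or `"rapeseed"` -- the goitrogen covariate the
#'   model uses (may be `NA` for iodine-only models).
#' @param model_id Optional identifier, e.g. `"model1"`.
#' @param n_obs,error_df Number of observations and residual degrees of
#'   freedom behind the fit.
#' @param rmse Residual root mean squared error on the log scale.
#' @param adj_r2 Adjusted R-squared.
#' @param rmsecv Leave-one-out root mean square error of cross-validation on
#'   the log scale (optional).
#' @param validity A [validity_ranges()] object.
#' @param data Optional treatment-mean data frame the model was fitted to.
#' @param selection Optional stepwise-selection history.
#' @param call Matched call of the fitting function.
#' @return An object of class `iodine_model`.
#' @export
new_iodine_model <- function(coefficients, covariate = NA_character_,
                             model_id = NULL, n_obs = NA_integer_,
                             error_df = NA_integer_, rmse = NA_real_,
                             adj_r2 = NA_real_, rmsecv = NA_real_,
                             validity = validity_ranges(), data = NULL,
                             selection = NULL, call = NULL) {
  stopifnot(is.data.frame(coefficients))
  required <- c("term", "estimate")
  missing_cols <- setdiff(required, names(coefficients))
  if (length(missing_cols)) {
    stop("coefficients table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("se", "ci_low", "ci_high", "p")) {
    if (!col %in% names(coefficients)) coefficients[[col]] <- NA_real_
  }
  if (anyDuplicated(coefficients$term)) {
    stop("duplicated term descriptor(s): ",
         paste(unique(coefficients$term[duplicated(coefficients$term)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(coefficients$estimate))) {
    stop("non-finite coefficient estimate(s)", call. = FALSE)
  }
  # canonicalize descriptors (validates them as a side effect)
  coefficients$term <- vapply(coefficients$term,
                              function(t) format_term(parse_term(t)), "")
  if (!is.na(covariate) && !covariate %in% c("gsl", "rapeseed")) {
    stop("covariate must be 'gsl' or 'rapeseed'", call. = FALSE)
  }
  structure(
    list(model_id = model_id,
         covariate = covariate,
         terms = coefficients$term,
         coefficients = coefficients,
         n_obs = n_obs, error_df = error_df,
         rmse = rmse, adj_r2 = adj_r2, rmsecv = rmsecv,
         validity = validity,
         data = data,
         selection = selection,
         call = call),
    class = "iodine_model")
}

#' Packaged published transfer models
#'
#' Loads one of the two published feed-to-milk iodine transfer models from
#' the coefficients shipped with the package: `"model1"` uses glucosinolate
#' intake (9 terms), `"model2"` rapeseed cake/meal inclusion (6 terms).
#'
#' @param id `"model1"` or `"model2"` (also accepts `1`/`2`).
#' @return An `iodine_model` object.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' coef(m2)
#' @export
milk_iodine_model <- function(id = c("model2", "model1")) {
  if (is.numeric(id)) id <- paste0("model", id)
  id <- match.arg(id)
  load_coefficients()[[id]]
}

#' @export
coef.iodine_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$terms)
}

#' @export
confint.iodine_model <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  ci <- cbind(cf$ci_low, cf$ci_high)
  rownames(ci) <- cf$term
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.iodine_model <- function(x, digits = 4, ...) {
  cat("Feed-to-milk iodine transfer model",
      if (!is.null(x$model_id)) paste0("(", x$model_id, ")"), "\n")
  cov_lab <- switch(as.character(x$covariate),
                    gsl = "glucosinolate intake (mmol/day)",
                    rapeseed = "rapeseed cake/meal (g/kg DM)",
                    "none")
  cat("  response : log(milk iodine, ug/kg)\n")
  cat("  covariate:", cov_lab, "\n")
  cat("  terms    :", paste(x$terms, collapse = " + "), "\n")
  if (!is.na(x$n_obs)) {
    cat(sprintf("  n = %d, error df = %d\n", x$n_obs, x$error_df))
  }
  stats <- c(RMSE = x$rmse, `adj R2` = x$adj_r2, RMSECV = x$rmsecv)
  stats <- stats[!is.na(stats)]
  if (length(stats)) {
    cat("  ", paste(sprintf("%s = %.3g", names(stats), stats),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.iodine_model <- function(object, ...) {
  structure(list(model = object), class = "summary.iodine_model")
}

#' @export
print.summary.iodine_model <- function(x, digits = 4, ...) {
  m <- x$model
  print(m)
  cat("\nCoefficients:\n")
  cf <- m$coefficients
  tab <- data.frame(Estimate = cf$estimate, SE = cf$se,
                    `CI low` = cf$ci_low, `CI high` = cf$ci_high,
                    `p value` = cf$p, check.names = FALSE,
                    row.names = cf$term)
  print(format(tab, digits = digits))
  vr <- m$validity
  cat(sprintf("\nValidity: iodine_in [%g, %g] mg/kg DM; gsl [%g, %g] mmol/day; rapeseed [%g, %g] g/kg DM\n",
              vr$iodine_in[1], vr$iodine_in[2], vr$gsl[1], vr$gsl[2],
              vr$rapeseed[1], vr$rapeseed[2]))
  invisible(x)
}

#' Predict milk iodine concentration from an iodine_model
#'
#' @param object An `iodine_model`.
#' @param newdata Data frame of rations with column `iodine_in` and the
#'   model's covariate column; defaults to the training data when present.
#' @param type `"response"` for ug I/kg milk, `"log"` for the natural-log
#'   scale the model is linear on.
#' @param strict If `TRUE`, rations outside the validity ranges raise an
#'   error; otherwise they are predicted with a warning.
#' @param check Set `FALSE` to skip the validity screen entirely (used
#'   internally for derivative scans).
#' @param ... Unused.
#' @return Numeric vector of predictions; attribute `"violations"` carries
#'   the validity-violation table.
#' @export
predict.iodine_model <- function(object, newdata = NULL,
                                 type = c("response", "log"),
                                 strict = FALSE, check = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$data)) {
      stop("'newdata' is required: the model carries no training data",
           call. = FALSE)
    }
    newdata <- object$data
  }
  newdata <- .as_ration_frame(newdata)
  X <- term_matrix(object$terms, newdata)
  lp <- drop(X %*% object$coefficients$estimate)
  violations <- if (check) {
    vars <- intersect(c("iodine_in", object$covariate), names(object$validity))
    v <- check_validity(newdata, object$validity, variables = vars)
    .handle_violations(v, strict)
    v
  } else {
    NULL
  }
  out <- if (type == "log") lp else exp(lp)
  attr(out, "violations") <- violations
  out
}

#' @export
fitted.iodine_model <- function(object, ...) {
  if (is.null(object$fitted_log)) {
    stop("model carries no training data", call. = FALSE)
  }
  object$fitted_log
}

#' @export
residuals.iodine_model <- function(object, ...) {
  if (is.null(object$residuals_log)) {
    stop("model carries no training data", call. = FALSE)
  }
  object$residuals_log
}

#' Simulate milk iodine responses from a transfer model
#'
#' Draws responses `exp(log-prediction + N(0, sd))` at the rows of `newdata`,
#' using the model's residual RMSE as the log-scale noise SD by default.
#'
#' @param object An `iodine_model` with a known `rmse` (or pass `sd`).
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param newdata Rations to simulate at (default: training data).
#' @param sd Log-scale residual SD override.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated ug/kg responses.
#' @export
simulate.iodine_model <- function(object, nsim = 1, seed = NULL,
                                  newdata = NULL, sd = object$rmse, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(sd)) stop("no residual SD available; supply 'sd'", call. = FALSE)
  lp <- predict(object, newdata = newdata, type = "log", check = FALSE)
  out <- as.data.frame(replicate(nsim, exp(lp + stats::rnorm(length(lp), 0, sd)),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Plot prediction curves of a transfer model
#'
#' Draws predicted milk iodine (ug/kg) against feed iodine, one curve per
#' covariate level, over the model's validity range.
#'
#' @param x An `iodine_model`.
#' @param covariate_values Goitrogen levels to draw curves at; defaults to
#'   six levels spanning the covariate's validity range.
#' @param iodine_limits Feed iodine range for the x axis.
#' @param n Number of grid points per curve.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted predictions.
#' @export
plot.iodine_model <- function(x, covariate_values = NULL,
                              iodine_limits = x$validity$iodine_in,
                              n = 101, ...) {
  cov <- x$covariate
  if (is.null(covariate_values)) {
    r <- x$validity[[cov]]
    covariate_values <- seq(r[1], r[2], length.out = 6)
  }
  iod <- seq(iodine_limits[1], iodine_limits[2], length.out = n)
  grid <- prediction_grid(x, iod, covariate_values)
  cov_lab <- if (identical(cov, "gsl")) "GSL (mmol/day)" else "rapeseed (g/kg DM)"
  graphics::matplot(iod, grid, type = "l", lty = 1,
                    xlab = "feed iodine (mg I/kg DM)",
                    ylab = expression(paste("predicted milk iodine (", mu, "g/kg)")),
                    ...)
  graphics::legend("topleft", legend = paste(cov_lab, "=", signif(covariate_values, 3)),
                   col = seq_along(covariate_values), lty = 1, bty = "n", cex = 0.8)
  invisible(grid)
}
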