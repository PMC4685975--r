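# Prediction, inversion and grid evaluation of the transfer models.

#' Predict the milk iodine concentration for a feed ration
#'
#' Evaluates a transfer model at one or more rations and returns both the
#' natural-log prediction and the back-transformed concentration in ug I/kg
#' milk, together with any validity-range violations.
#'
#' @param model An `iodine_model` (see [milk_iodine_model()]).
#' @param iodine_in Feed iodine concentration(s), mg I/kg dry matter.
#' @param gsl Glucosinolate intake(s), mmol/day (model 1).
#' @param rapeseed Rapeseed cake/meal inclusion(s), g/kg dry matter (model 2).
#' @param strict If `TRUE`, out-of-range rations raise an error instead of a
#'   warning.
#' @return An object of class `milk_iodine_prediction`: a list with
#'   `log_value`, `value` (= `exp(log_value)`, ug/kg) and `violations`.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' predict_milk_iodine(m2, iodine_in = 1, rapeseed = 0)
#' @export
predict_milk_iodine <- function(model, iodine_in, gsl = NULL, rapeseed = NULL,
                                strict = FALSE) {
  stopifnot(inherits(model, "iodine_model"))
  ration <- .build_rations(model, iodine_in, gsl, rapeseed)
  if (any(ration$iodine_in < 0) ||
      any(ration[[model$covariate]] < 0)) {
    stop("ration values must be non-negative", call. = FALSE)
  }
  lp <- predict(model, newdata = ration, type = "log", strict = strict)
  structure(list(log_value = as.numeric(lp),
                 value = exp(as.numeric(lp)),
                 violations = attr(lp, "violations"),
                 ration = ration,
                 model_id = model$model_id),
            class = "milk_iodine_prediction")
}

#' @export
print.milk_iodine_prediction <- function(x, ...) {
  cat("Predicted milk iodine concentration",
      if (!is.null(x$model_id)) paste0("(", x$model_id, ")"), "\n")
  tab <- cbind(x$ration,
               log_value = round(x$log_value, 4),
               ug_per_kg = round_half_up(x$value))
  print(tab, row.names = FALSE)
  if (nrow(x$violations)) {
    cat("Note:", nrow(x$violations), "ration value(s) outside the validity range\n")
  }
  invisible(x)
}

.build_rations <- function(model, iodine_in, gsl, rapeseed) {
  cov <- model$covariate
  cov_val <- switch(cov, gsl = gsl, rapeseed = rapeseed)
  if (is.null(cov_val)) {
    stop("model requires covariate '", cov, "'; supply it", call. = FALSE)
  }
  n <- max(length(iodine_in), length(cov_val))
  ration <- data.frame(iodine_in = rep_len(as.numeric(iodine_in), n))
  ration[[cov]] <- rep_len(as.numeric(cov_val), n)
  ration
}

#' Feed iodine required to reach a target milk concentration
#'
#' Inverts a transfer model in the feed-iodine direction: finds the feed
#' iodine concentration (mg I/kg DM, within the validity range) whose
#' predicted milk iodine equals `target` at a fixed goitrogen level.  The
#' log-prediction is verified to be strictly increasing in feed iodine over
#' the search interval (derivative sign scan at step 0.01), then solved by
#' bisection to `tol` on the log scale.
#'
#' @param model An `iodine_model`.
#' @param target Target milk iodine concentration, ug/kg (> 0).
#' @param gsl,rapeseed Fixed goitrogen level (supply the one the model uses).
#' @param interval Feed-iodine search interval; defaults to the model's
#'   validity range for `iodine_in`.
#' @param tol Absolute tolerance on the log scale (default 1e-6).
#' @return Feed iodine in mg I/kg DM.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' invert_required_iodine(m2, target = 260, rapeseed = 0)
#' @export
invert_required_iodine <- function(model, target, gsl = NULL, rapeseed = NULL,
                                   interval = model$validity$iodine_in,
                                   tol = 1e-6) {
  stopifnot(inherits(model, "iodine_model"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    stop("'target' must be a single positive concentration (ug/kg)",
         call. = FALSE)
  }
  cov <- model$covariate
  cov_val <- switch(cov, gsl = gsl, rapeseed = rapeseed)
  if (is.null(cov_val)) {
    stop("model requires covariate '", cov, "'; supply it", call. = FALSE)
  }
  cov_range <- model$validity[[cov]]
  if (cov_val < cov_range[1] || cov_val > cov_range[2]) {
    stop("fixed ", cov, " = ", cov_val, " outside validity range [",
         cov_range[1], ", ", cov_range[2], "]", call. = FALSE)
  }

  logpred <- function(x) {
    nd <- data.frame(iodine_in = x)
    nd[[cov]] <- cov_val
    as.numeric(predict(model, nd, type = "log", check = FALSE))
  }

  # monotonicity screen: the log-prediction must strictly increase in feed
  # iodine over the search interval, otherwise the root is not unique
  grid <- seq(interval[1], interval[2], by = 0.01)
  if (grid[length(grid)] < interval[2]) grid <- c(grid, interval[2])
  lp_grid <- logpred(grid)
  if (any(diff(lp_grid) <= 0)) {
    stop("log-prediction is not strictly increasing in feed iodine on [",
         interval[1], ", ", interval[2], "]; inversion is not well defined",
         call. = FALSE)
  }

  log_target <- log(target)
  lo <- interval[1]; hi <- interval[2]
  f_lo <- logpred(lo) - log_target
  f_hi <- logpred(hi) - log_target
  if (abs(f_lo) <= tol) return(lo)
  if (abs(f_hi) <= tol) return(hi)
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf(paste0("target %g ug/kg is unattainable at %s = %g: ",
                        "achievable range is [%g, %g] ug/kg"),
                 target, cov, cov_val,
                 exp(logpred(lo)), exp(logpred(hi))), call. = FALSE)
  }
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f_mid <- logpred(mid) - log_target
    if (abs(f_mid) <= tol) return(mid)
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  stop("bisection did not converge", call. = FALSE) # nocov
}

#' Grid of predicted milk iodine concentrations
#'
#' Evaluates a transfer model over the Cartesian product of feed-iodine and
#' goitrogen values, as used for the published prediction-surface figures.
#'
#' @param model An `iodine_model`.
#' @param iodine_values Feed iodine values, mg I/kg DM (rows).
#' @param covariate_values Goitrogen values -- gsl (mmol/day) or rapeseed
#'   (g/kg DM) depending on the model (columns).
#' @param strict Escalate validity violations to an error.
#' @return Numeric matrix of concentrations (ug/kg), rows indexed by iodine,
#'   columns by the covariate; attribute `"violations"` lists out-of-range
#'   cells.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' prediction_grid(m2, c(1.5, 2), c(50, 70))
#' @export
prediction_grid <- function(model, iodine_values, covariate_values,
                            strict = FALSE) {
  stopifnot(inherits(model, "iodine_model"))
  if (!length(iodine_values) || !length(covariate_values)) {
    stop("value lists must be non-empty", call. = FALSE)
  }
  cov <- model$covariate
  cells <- expand.grid(iodine_in = as.numeric(iodine_values),
                       cov = as.numeric(covariate_values))
  names(cells)[2] <- cov
  val <- predict(model, cells, type = "response", strict = strict)
  out <- matrix(as.numeric(val),
                nrow = length(iodine_values), ncol = length(covariate_values),
                dimnames = list(iodine_in = as.character(iodine_values),
                                as.character(covariate_values)))
  names(dimnames(out))[2] <- cov
  attr(out, "violations") <- attr(val, "violations")
  out
}

#' Round half away from zero
#'
#' Presentation rounding used for reported concentrations, intakes and
#' percentages: halves round up (0.5 -> 1), unlike [round()]'s
#' round-half-to-even.  Internal computation is always kept at full
#' precision; this is applied only when printing or reporting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
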