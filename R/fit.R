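# Model construction: OLS on the log response, p-value stepwise selection
# over the polynomial candidate pool, leave-one-out cross-validation and the
# study-effect screen.
#
# The response throughout is log(milk_iodine) with milk iodine in ug/kg; all
# fit statistics (RMSE, RMSECV) are on that natural-log scale.

# prepare the response and drop rows unusable for the requested covariate
.fit_data <- function(data, terms) {
  stopifnot(is.data.frame(data))
  if (!"milk_iodine" %in% names(data)) {
    stop("data must contain a 'milk_iodine' column (ug/kg)", call. = FALSE)
  }
  if (any(is.na(data$milk_iodine) | data$milk_iodine <= 0)) {
    stop("milk_iodine must be strictly positive (it is log-transformed)",
         call. = FALSE)
  }
  vars <- term_variables(terms)
  cols <- unname(.term_vars[vars])
  cols <- cols[!is.na(cols)]
  keep <- rep(TRUE, nrow(data))
  for (col in intersect(cols, names(data))) keep <- keep & !is.na(data[[col]])
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " row(s) with missing covariate values",
            call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  data
}

#' Ordinary least squares fit of a fixed term set
#'
#' Fits `log(milk_iodine) ~ terms` by least squares and returns the full
#' inference table: estimates, standard errors from the unbiased residual
#' variance, two-sided t-based p-values, and t-quantile confidence intervals
#' at `level`.  `rmse = sqrt(SSE / error_df)` and the adjusted R-squared use
#' the standard definitions.
#'
#' @param data Treatment-means data frame with columns `milk_iodine` and the
#'   variables the terms reference (`iodine_in`, `gsl`, `rapeseed`).
#' @param terms Character vector of term descriptors (see
#'   [build_candidate_terms()]); include `"1"` for the intercept.
#' @param level Confidence level for the intervals (default 0.95).
#' @param model_id Optional identifier stored on the result.
#' @return An [new_iodine_model()] object carrying the data, fitted values
#'   and log-scale residuals (no `rmsecv`; see [loo_rmsecv()]).
#' @examples
#' d <- data.frame(iodine_in = seq(0, 4, length.out = 20))
#' d$milk_iodine <- exp(4.22 + 1.84 * d$iodine_in)
#' fit_ols(d, c("1", "iodineIn"))
#' @export
fit_ols <- function(data, terms, level = 0.95, model_id = NULL) {
  data <- .fit_data(data, terms)
  y <- log(data$milk_iodine)
  X <- term_matrix(terms, data)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop("too few observations (", n, ") for ", p,
         " parameters: need at least n_terms + 2", call. = FALSE)
  }
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):p]]
    stop("singular design: term(s) collinear with the rest: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_X, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- n - p
  sse <- sum(resid^2)
  sigma2 <- sse / df
  XtX_inv <- chol2inv(qr.R(qr_X))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  sst <- sum((y - mean(y))^2)
  adj_r2 <- 1 - (sse / df) / (sst / (n - 1))

  covariate <- intersect(term_variables(terms), c("gsl", "rapeseed"))
  m <- new_iodine_model(
    coefficients = data.frame(term = terms, estimate = unname(beta),
                              se = unname(se), ci_low = unname(beta - tq * se),
                              ci_high = unname(beta + tq * se),
                              p = unname(pval), stringsAsFactors = FALSE),
    covariate = if (length(covariate) == 1L) covariate else NA_character_,
    model_id = model_id,
    n_obs = n, error_df = df,
    rmse = sqrt(sigma2), adj_r2 = adj_r2,
    data = data, call = match.call())
  m$fitted_log <- fitted
  m$residuals_log <- resid
  m
}

#' Stepwise term selection by p-value
#'
#' Bidirectional stepwise search over a polynomial candidate pool, mirroring
#' the construction of the published models: at each move, the candidate with
#' the smallest partial t-test p-value enters if below `p_enter`, then the
#' included term with the largest p-value leaves if above `p_remove`; the
#' intercept is always retained.  Ties break deterministically by lower total
#' degree, then lexicographic descriptor.  With `hierarchy = TRUE` a pure
#' power can only enter while its next lower power is in the model, an
#' interaction only while its main effects are, and a term protected by a
#' retained higher-order term cannot leave.
#'
#' @param data Treatment-means data frame.
#' @param pool Candidate descriptors from [build_candidate_terms()].
#' @param p_enter,p_remove Entry/removal significance thresholds (defaults
#'   0.05 / 0.05); requires `0 < p_enter <= p_remove < 1`.
#' @param hierarchy Enforce model hierarchy (default `TRUE`).
#' @param level Confidence level for the final inference table.
#' @param model_id Optional identifier stored on the result.
#' @return The selected fit as an `iodine_model`; `$selection` records the
#'   move history.
#' @export
stepwise_select <- function(data, pool, p_enter = 0.05, p_remove = 0.05,
                            hierarchy = TRUE, level = 0.95, model_id = NULL) {
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1)) {
    stop("need 0 < p_enter <= p_remove < 1", call. = FALSE)
  }
  pool <- unique(pool)
  if (!"1" %in% pool) pool <- c("1", pool)
  data <- .fit_data(data, pool)

  degree <- vapply(pool, term_degree, 0)
  ord <- order(degree, pool)
  pool <- pool[ord]; degree <- degree[ord]

  included <- "1"
  history <- list()
  max_moves <- 100L * length(pool)
  moves <- 0L

  term_p <- function(terms, term) {
    fit <- fit_ols(data, terms, level = level)
    fit$coefficients$p[match(term, fit$terms)]
  }

  y <- log(data$milk_iodine)
  sst <- sum((y - mean(y))^2)

  repeat {
    moved <- FALSE
    cur <- fit_ols(data, included, level = level)
    sse_cur <- cur$rmse^2 * cur$error_df
    # once the fit is numerically exact, t-based p-values on the ~zero
    # residuals are noise: stop adding terms
    saturated <- sse_cur <= 1e-12 * max(sst, .Machine$double.eps)

    # entry step: candidate with the smallest partial p-value below p_enter
    candidates <- if (saturated) character(0) else setdiff(pool, included)
    if (hierarchy && length(candidates)) {
      ok <- vapply(candidates, function(t) all(term_parents(t) %in% included),
                   TRUE)
      candidates <- candidates[ok]
    }
    if (length(candidates)) {
      p_in <- vapply(candidates, function(t) {
        tryCatch(term_p(c(included, t), t), error = function(e) NA_real_)
      }, 0)
      if (any(!is.na(p_in) & p_in < p_enter)) {
        best <- which(p_in == min(p_in, na.rm = TRUE))[1] # pool pre-sorted: ties fall to lower degree, then lexicographic
        included <- c(included, candidates[best])
        history[[length(history) + 1L]] <-
          list(move = "add", term = candidates[best], p = p_in[best])
        moved <- TRUE
        moves <- moves + 1L
      }
    }

    # removal step: included term with the largest p-value above p_remove
    removable <- setdiff(included, "1")
    if (hierarchy && length(removable)) {
      protected <- unique(unlist(lapply(setdiff(included, "1"), term_parents)))
      removable <- setdiff(removable, protected)
    }
    if (length(removable)) {
      fit <- if (moved) fit_ols(data, included, level = level) else cur
      p_cur <- fit$coefficients$p[match(removable, fit$terms)]
      if (any(!is.na(p_cur) & p_cur > p_remove)) {
        worst_p <- max(p_cur, na.rm = TRUE)
        cand <- removable[!is.na(p_cur) & p_cur == worst_p]
        dgr <- vapply(cand, term_degree, 0)
        drop_term <- cand[order(-dgr, cand)][1] # drop highest degree first
        included <- setdiff(included, drop_term)
        history[[length(history) + 1L]] <-
          list(move = "drop", term = drop_term, p = worst_p)
        moved <- TRUE
        moves <- moves + 1L
      }
    }

    if (!moved) break
    if (moves > max_moves) {
      stop("stepwise selection is cycling (", moves, " moves without convergence)",
           call. = FALSE)
    }
  }

  included <- pool[pool %in% included] # canonical (degree, lexicographic) order
  fit <- fit_ols(data, included, level = level, model_id = model_id)
  fit$selection <- list(pool = pool, history = history,
                        p_enter = p_enter, p_remove = p_remove,
                        hierarchy = hierarchy)
  fit$call <- match.call()
  fit
}

#' Leave-one-out root mean square error of cross-validation
#'
#' For each observation, the model is fitted to the remaining rows and the
#' held-out log response predicted; RMSECV is the root mean of the squared
#' held-out prediction errors.  The default uses the exact hat-matrix
#' identity `e_(-i) = e_i / (1 - h_ii)`; `method = "refit"` runs the literal
#' n-refit loop (the two agree to machine precision and the loop serves as
#' the oracle in the test suite).
#'
#' @param data Treatment-means data frame.
#' @param terms Term descriptors of the model to cross-validate.
#' @param method `"hat"` (default) or `"refit"`.
#' @return RMSECV on the natural-log scale.
#' @export
loo_rmsecv <- function(data, terms, method = c("hat", "refit")) {
  method <- match.arg(method)
  data <- .fit_data(data, terms)
  y <- log(data$milk_iodine)
  X <- term_matrix(terms, data)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop("leave-one-out requires at least n_terms + 2 observations",
         call. = FALSE)
  }
  if (method == "hat") {
    qr_X <- qr(X)
    if (qr_X$rank < p) stop("singular design", call. = FALSE)
    h <- rowSums(qr.Q(qr_X)^2)
    bad <- which(1 - h < 1e-10)
    if (length(bad)) {
      stop("leave-one-out design rank-deficient when row ", bad[1],
           " is removed (leverage 1)", call. = FALSE)
    }
    resid <- y - drop(X %*% qr.coef(qr_X, y))
    e_loo <- resid / (1 - h)
  } else {
    e_loo <- numeric(n)
    for (i in seq_len(n)) {
      qr_i <- qr(X[-i, , drop = FALSE])
      if (qr_i$rank < p) {
        stop("leave-one-out design rank-deficient when row ", i,
             " is removed", call. = FALSE)
      }
      beta_i <- qr.coef(qr_i, y[-i])
      e_loo[i] <- y[i] - sum(X[i, ] * beta_i)
    }
  }
  sqrt(mean(e_loo^2))
}

#' Fit a feed-to-milk iodine transfer model
#'
#' The package's main fitting interface: builds the polynomial candidate pool
#' in feed iodine and one goitrogen covariate, runs p-value stepwise
#' selection (or fits a fixed `terms` set), and attaches leave-one-out
#' cross-validation.  The response is `log(milk_iodine)`.
#'
#' @param data Treatment-means data frame with columns `study_id`,
#'   `iodine_in`, `milk_iodine` and the chosen covariate (`gsl` or
#'   `rapeseed`); see [read_treatment_means()] / [generate_dataset()].
#' @param covariate `"gsl"` or `"rapeseed"`.
#' @param terms Optional fixed term set; skips selection when given.
#' @param max_order Maximal total polynomial degree of the candidate pool
#'   (default 3).
#' @param p_enter,p_remove,hierarchy Passed to [stepwise_select()].
#' @param cv Compute RMSECV by [loo_rmsecv()] (default `TRUE`).
#' @param level Confidence level for the inference table.
#' @return An `iodine_model` with full inference, `rmse`, `adj_r2` and
#'   `rmsecv`.
#' @examples
#' d <- generate_dataset(simulation_config(seed = 42))
#' fit <- milk_iodine_fit(d, covariate = "rapeseed")
#' summary(fit)
#' @export
milk_iodine_fit <- function(data, covariate = c("rapeseed", "gsl"),
                            terms = NULL, max_order = 3,
                            p_enter = 0.05, p_remove = 0.05,
                            hierarchy = TRUE, cv = TRUE, level = 0.95) {
  covariate <- match.arg(covariate)
  cov_term <- covariate # descriptor name equals the column name for gsl/rapeseed
  if (is.null(terms)) {
    pool <- build_candidate_terms(c("iodineIn", cov_term), max_order)
    fit <- stepwise_select(data, pool, p_enter = p_enter,
                           p_remove = p_remove, hierarchy = hierarchy,
                           level = level)
  } else {
    fit <- fit_ols(data, terms, level = level)
  }
  if (cv) fit$rmsecv <- loo_rmsecv(fit$data, fit$terms)
  fit$covariate <- covariate
  fit$call <- match.call()
  fit
}

#' Screen for a study effect on the log response
#'
#' Before any covariate modelling, the treatment-mean compilation is screened
#' for systematic between-study differences by regressing `log(milk_iodine)`
#' on the study label alone (fixed-effect one-way layout, dummy coding with
#' the first sorted label as reference).  Reported are the overall F-test
#' against the intercept-only model, the adjusted R-squared (negative when
#' the factor is useless), and the per-level t-test p-values.
#'
#' @param data Treatment-means data frame with `study_id` and `milk_iodine`.
#' @return List of class `study_screen`: `f_statistic`, `f_p_value`,
#'   `adj_r2`, `per_level_p`, `n_studies`, `df`.
#' @export
study_effect_screen <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("study_id", "milk_iodine") %in% names(data))) {
    stop("data must contain 'study_id' and 'milk_iodine'", call. = FALSE)
  }
  if (any(data$milk_iodine <= 0)) {
    stop("milk_iodine must be strictly positive", call. = FALSE)
  }
  study <- factor(data$study_id, levels = sort(unique(as.character(data$study_id))))
  if (nlevels(study) < 2L) {
    stop("degenerate design: need at least 2 study levels", call. = FALSE)
  }
  y <- log(data$milk_iodine)
  fit <- stats::lm(y ~ study)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  per_level <- stats::coef(sm)[-1, 4]
  names(per_level) <- levels(study)[-1]
  structure(
    list(f_statistic = unname(fstat[1]),
         f_p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                      lower.tail = FALSE)),
         adj_r2 = sm$adj.r.squared,
         per_level_p = per_level,
         reference_level = levels(study)[1],
         n_studies = nlevels(study),
         df = unname(fstat[2:3])),
    class = "study_screen")
}

#' @export
print.study_screen <- function(x, ...) {
  cat("Study-effect screen on log(milk iodine)\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g, adjusted R2 = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$f_p_value, x$adj_r2))
  cat("  per-level p-values (vs reference '", x$reference_level, "'): ",
      paste(sprintf("%s=%.2g", names(x$per_level_p), x$per_level_p),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
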