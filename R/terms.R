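# Polynomial term descriptors.
#
# A term is a multiset of (variable, power) pairs written in Wilkinson-style
# notation: "1" is the intercept, "iodineIn^2" a pure power, and
# "iodineIn:gsl^2" the product iodineIn * gsl^2.  Internally a term is a named
# integer vector of powers; the empty vector is the intercept.

# canonical variable order and the data column each maps to
.term_vars <- c(iodineIn = "iodine_in", gsl = "gsl", rapeseed = "rapeseed")

#' Parse a term descriptor
#'
#' Converts a descriptor such as `"iodineIn:gsl^2"` into a named integer
#' vector of powers per variable. `"1"` (the intercept) parses to an empty
#' vector.
#'
#' @param descriptor Character scalar, e.g. `"1"`, `"rapeseed^2"`,
#'   `"iodineIn:gsl"`.
#' @return Named integer vector of powers (empty for the intercept).
#' @keywords internal
parse_term <- function(descriptor) {
  stopifnot(is.character(descriptor), length(descriptor) == 1L)
  descriptor <- gsub("\\s+", "", descriptor)
  if (descriptor == "" || descriptor == "1") {
    return(stats::setNames(integer(0), character(0)))
  }
  factors <- strsplit(descriptor, ":", fixed = TRUE)[[1]]
  powers <- integer(0)
  for (f in factors) {
    m <- regmatches(f, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\^([0-9]+))?$", f))[[1]]
    if (length(m) == 0L) {
      stop("malformed term descriptor: '", descriptor, "' (factor '", f, "')",
           call. = FALSE)
    }
    var <- m[2]
    k <- if (m[4] == "") 1L else as.integer(m[4])
    if (k < 1L) stop("zero power in term descriptor: '", descriptor, "'", call. = FALSE)
    powers[var] <- (if (var %in% names(powers)) powers[[var]] else 0L) + k
  }
  .order_powers(powers)
}

# order variables canonically: known variables first in .term_vars order,
# anything else alphabetically after
.order_powers <- function(powers) {
  known <- intersect(names(.term_vars), names(powers))
  other <- sort(setdiff(names(powers), names(.term_vars)))
  powers[c(known, other)]
}

#' Format a power vector back to its canonical descriptor string
#' @param powers Named integer vector of powers.
#' @return Character scalar descriptor.
#' @keywords internal
format_term <- function(powers) {
  powers <- .order_powers(powers)
  if (length(powers) == 0L) return("1")
  paste(ifelse(powers == 1L, names(powers),
               paste0(names(powers), "^", powers)),
        collapse = ":")
}

# total polynomial degree of a descriptor
term_degree <- function(descriptor) {
  sum(parse_term(descriptor))
}

#' Candidate polynomial term pool
#'
#' Enumerates all monomials in the given variables up to a maximal total
#' degree: the intercept, every pure power `x^k` with `k <= max_order`, and
#' every cross-product `x^a:y^b` with `a + b <= max_order`.  The pool is
#' ordered by total degree and, within a degree, by descending power of the
#' first variable -- for two variables of order 3 this yields
#' `1, x, y, x^2, x:y, y^2, x^3, x^2:y, x:y^2, y^3`.
#'
#' @param variables Character vector of 1 or 2 variable names (e.g.
#'   `c("iodineIn", "gsl")`).
#' @param max_order Maximal total degree (default 3).
#' @return Character vector of term descriptors, intercept first.
#' @examples
#' build_candidate_terms("iodineIn", 3)
#' build_candidate_terms(c("iodineIn", "rapeseed"), 2)
#' @export
build_candidate_terms <- function(variables, max_order = 3L) {
  variables <- as.character(variables)
  if (length(variables) < 1L) stop("at least one variable is required", call. = FALSE)
  if (length(variables) > 2L) {
    stop("term pools are defined for one or two continuous variables", call. = FALSE)
  }
  if (anyDuplicated(variables)) stop("duplicated variable names", call. = FALSE)
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 1L)

  terms <- "1"
  for (d in seq_len(max_order)) {
    if (length(variables) == 1L) {
      pw <- stats::setNames(d, variables)
      terms <- c(terms, format_term(pw))
    } else {
      for (a in d:0) {
        pw <- c(a, d - a)
        names(pw) <- variables
        terms <- c(terms, format_term(pw[pw > 0L]))
      }
    }
  }
  terms
}

#' Evaluate term values on a data frame
#'
#' Builds the design matrix whose columns are the term descriptors evaluated
#' on the rows of `data`.  The intercept column is identically 1; an
#' interaction `a:b` is the plain product; `a^k` the k-th power.
#'
#' @param terms Character vector of term descriptors.
#' @param data Data frame holding the model variables either under their
#'   descriptor names (`iodineIn`, ...) or their dataset column names
#'   (`iodine_in`, ...).
#' @return Numeric matrix, `nrow(data)` rows, one column per term
#'   (column names = descriptors).
#' @export
term_matrix <- function(terms, data) {
  stopifnot(is.character(terms), is.data.frame(data))
  if (anyDuplicated(terms)) {
    stop("duplicated term descriptors: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  X <- matrix(NA_real_, nrow = n, ncol = length(terms),
              dimnames = list(NULL, terms))
  for (j in seq_along(terms)) {
    powers <- parse_term(terms[j])
    col <- rep(1, n)
    for (v in names(powers)) {
      col <- col * .get_model_var(data, v)^powers[[v]]
    }
    X[, j] <- col
  }
  X
}

# fetch a model variable from a data frame, accepting either the descriptor
# name (iodineIn) or the dataset column name (iodine_in)
.get_model_var <- function(data, var) {
  candidates <- unique(c(var, unname(.term_vars[var])))
  candidates <- candidates[!is.na(candidates)]
  for (cand in candidates) {
    if (cand %in% names(data)) {
      x <- data[[cand]]
      if (anyNA(x)) {
        stop("variable '", cand, "' contains missing values", call. = FALSE)
      }
      return(as.numeric(x))
    }
  }
  stop("model requires variable '", var, "' which is absent from the data",
       call. = FALSE)
}

# variables appearing in a set of term descriptors
term_variables <- function(terms) {
  unique(unlist(lapply(terms, function(t) names(parse_term(t)))))
}

# lower-order terms a candidate requires under hierarchy:
# pure powers require the next lower power; interactions require their
# main effects (power-1 terms of each constituent variable)
term_parents <- function(descriptor) {
  powers <- parse_term(descriptor)
  if (length(powers) == 0L) return(character(0))
  if (length(powers) == 1L) {
    if (powers[[1]] == 1L) return(character(0))
    pw <- powers
    pw[1] <- pw[1] - 1L
    return(format_term(pw))
  }
  vapply(names(powers), function(v) format_term(stats::setNames(1L, v)), "")
}

#' Evaluate one ration against a model's term set
#'
#' @param model An [iodine_model] object (see [milk_iodine_model()]).
#' @param ration A one-row data frame or named list/vector with `iodine_in`
#'   and the model's goitrogen covariate (`gsl` or `rapeseed`).
#' @return Named numeric vector of term values aligned with `coef(model)`.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' expand_terms(m2, list(iodine_in = 2, rapeseed = 150))
#' @export
expand_terms <- function(model, ration) {
  stopifnot(inherits(model, "iodine_model"))
  ration <- .as_ration_frame(ration)
  drop(term_matrix(model$terms, ration)[1, ])
}

.as_ration_frame <- function(ration) {
  if (is.data.frame(ration)) return(ration)
  as.data.frame(as.list(ration))
}
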