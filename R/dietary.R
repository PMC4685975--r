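# Dietary iodine intake from dairy products.
#
# Converts a milk iodine concentration into per-group daily iodine intake
# and percent of the recommended intake, using Norwegian dairy-consumption
# profiles (men, women, 2-year-old children, pregnant women) and product
# iodine concentrations anchored at the current milk level of 200 ug/kg.
# All arithmetic is at full precision; reported numbers are rounded half-up
# only at presentation.

# milk iodine concentration (ug/kg) the packaged product table corresponds to
.reference_milk_conc <- 200

# products whose iodine tracks the fluid-milk concentration under the
# "milk-only" scaling rule; cheeses stay at their tabulated values
.fluid_products <- c("milk", "flavored_milk", "yoghurt", "cream_products")

#' Packaged dairy intake and product iodine table
#'
#' Daily dairy-product consumption (g/day) of four Norwegian population
#' groups from national dietary surveys, together with representative
#' product iodine concentrations (ug/100 g) at the current milk iodine level
#' of 200 ug/kg.
#'
#' @param path Optional CSV override in the packaged dialect
#'   (`product,conc_ug_per_100g,men,women,toddlers,pregnant`).
#' @return Data frame, one row per product.
#' @examples
#' dairy_intake_table()
#' @export
dairy_intake_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dairy_intake_norway.csv",
                        package = "lactiodine", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("product", "conc_ug_per_100g")
  if (!all(required %in% names(tab))) {
    stop("intake table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$conc_ug_per_100g <= 0)) {
    stop("product iodine concentrations must be positive", call. = FALSE)
  }
  if (anyDuplicated(tab$product)) {
    stop("duplicated product rows: ",
         paste(unique(tab$product[duplicated(tab$product)]), collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Recommended daily iodine intakes (ug/day)
#'
#' Nordic reference values: 150 ug/day for adults, 90 for 2-year-old
#' children, 175 for pregnant women.
#'
#' @return Named numeric vector over the four packaged groups.
#' @export
recommended_intakes <- function() {
  c(men = 150, women = 150, toddlers = 90, pregnant = 175)
}

#' Population dairy-consumption profiles
#'
#' Builds one profile per population group from an intake table: the
#' product-wise daily consumption (g/day) and the group's recommended
#' iodine intake.
#'
#' @param table Intake table from [dairy_intake_table()].
#' @param groups Group columns to extract (default: all four packaged
#'   groups).
#' @param recommended Named vector of recommended intakes, ug/day.
#' @return Named list of profiles; each a list with `group`, `intake`
#'   (named numeric, g/day) and `recommended` (ug/day).
#' @examples
#' population_profiles()[["toddlers"]]
#' @export
population_profiles <- function(table = dairy_intake_table(),
                                groups = names(recommended_intakes()),
                                recommended = recommended_intakes()) {
  missing_groups <- setdiff(groups, names(table))
  if (length(missing_groups)) {
    stop("intake table lacks group column(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  out <- lapply(groups, function(g) {
    rec <- recommended[[g]]
    if (is.null(rec) || is.na(rec) || rec <= 0) {
      stop("no positive recommended intake for group '", g, "'", call. = FALSE)
    }
    intake <- stats::setNames(as.numeric(table[[g]]), table$product)
    if (any(intake < 0)) stop("negative intake for group '", g, "'", call. = FALSE)
    list(group = g, intake = intake, recommended = rec)
  })
  stats::setNames(out, groups)
}

.check_profile <- function(profile) {
  if (!is.list(profile) || !all(c("intake", "recommended") %in% names(profile))) {
    stop("a profile is a list with 'intake' (named g/day) and 'recommended' (ug/day)",
         call. = FALSE)
  }
  profile
}

#' Per-product iodine contribution for one population group
#'
#' `contribution = intake (g/day) * concentration (ug/100 g) / 100`, at full
#' precision.
#'
#' @param profile One profile from [population_profiles()].
#' @param table Intake/concentration table.
#' @return Named numeric vector, ug/day per product.
#' @examples
#' contribution_by_product(population_profiles()[["men"]])
#' @export
contribution_by_product <- function(profile, table = dairy_intake_table()) {
  profile <- .check_profile(profile)
  products <- names(profile$intake)
  unknown <- setdiff(products, table$product)
  if (length(unknown)) {
    stop("unknown product(s) in profile: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  conc <- table$conc_ug_per_100g[match(products, table$product)]
  stats::setNames(profile$intake * conc / 100, products)
}

#' Total daily iodine intake from dairy products
#'
#' @inheritParams contribution_by_product
#' @return Total intake, ug/day (unrounded).
#' @examples
#' total_dairy_iodine(population_profiles()[["men"]])
#' @export
total_dairy_iodine <- function(profile, table = dairy_intake_table()) {
  sum(contribution_by_product(profile, table))
}

#' Percent of the recommended iodine intake
#'
#' @param total Daily iodine intake, ug/day.
#' @param profile Profile carrying the group's recommended intake.
#' @return Percent (unrounded; round half-up for presentation).
#' @export
percent_of_recommendation <- function(total, profile) {
  profile <- .check_profile(profile)
  100 * total / profile$recommended
}

# rescale product concentrations for a milk iodine concentration of `conc`
.scale_table <- function(table, conc, rule, reference = .reference_milk_conc) {
  rule <- match.arg(rule, c("proportional", "milk-only"))
  factor <- conc / reference
  out <- table
  if (rule == "proportional") {
    out$conc_ug_per_100g <- table$conc_ug_per_100g * factor
  } else {
    fluid <- table$product %in% .fluid_products
    out$conc_ug_per_100g[fluid] <- table$conc_ug_per_100g[fluid] * factor
  }
  out
}

#' Iodine intake as a function of the milk iodine concentration
#'
#' Scenario curves: for each milk iodine concentration, product
#' concentrations are rescaled from their values at the current 200 ug/kg
#' level and the per-group totals and percent-of-recommendation recomputed.
#' Under the default `"proportional"` rule every product scales with the
#' milk concentration; under `"milk-only"` the cheeses keep their tabulated
#' concentrations and only fluid products (milk, flavored milk, yoghurt,
#' cream products) scale.
#'
#' @param profiles List of profiles from [population_profiles()] (or one
#'   profile).
#' @param table Intake/concentration table at the 200 ug/kg reference.
#' @param conc_values Milk iodine concentrations to evaluate, ug/kg (> 0).
#' @param rule `"proportional"` (default) or `"milk-only"`.
#' @return Data frame of class `scenario_curve`: `milk_conc`, `group`,
#'   `total_ug_day`, `percent_of_recommended`.
#' @examples
#' curve <- intake_vs_milk_concentration(conc_values = c(100, 200, 400))
#' subset(curve, group == "toddlers")
#' @export
intake_vs_milk_concentration <- function(profiles = population_profiles(),
                                         table = dairy_intake_table(),
                                         conc_values = seq(50, 400, by = 50),
                                         rule = c("proportional", "milk-only")) {
  rule <- match.arg(rule)
  if (!is.null(names(profiles)) && "intake" %in% names(profiles)) {
    profiles <- list(profiles)
  }
  if (any(conc_values <= 0)) {
    stop("milk concentrations must be positive", call. = FALSE)
  }
  rows <- list()
  for (conc in conc_values) {
    scaled <- .scale_table(table, conc, rule)
    for (pr in profiles) {
      total <- total_dairy_iodine(pr, scaled)
      rows[[length(rows) + 1L]] <- data.frame(
        milk_conc = conc, group = pr$group, total_ug_day = total,
        percent_of_recommended = percent_of_recommendation(total, pr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rule") <- rule
  class(out) <- c("scenario_curve", class(out))
  out
}

#' Chain a feed scenario through a transfer model to population intake
#'
#' Predicts the milk iodine concentration for a cow ration with a transfer
#' model, then evaluates the dietary scenario at that concentration: the
#' full feed-to-population pipeline.
#'
#' @param model An `iodine_model`.
#' @param iodine_in Feed iodine, mg I/kg DM.
#' @param gsl,rapeseed Goitrogen level for the model.
#' @param profiles,table,rule As in [intake_vs_milk_concentration()].
#' @param strict Escalate validity violations of the ration to an error.
#' @return The `scenario_curve` row set at the predicted concentration, with
#'   attribute `"milk_conc"`.
#' @examples
#' m2 <- milk_iodine_model("model2")
#' feed_scenario_to_population_intake(m2, iodine_in = 1, rapeseed = 0)
#' @export
feed_scenario_to_population_intake <- function(model, iodine_in, gsl = NULL,
                                               rapeseed = NULL,
                                               profiles = population_profiles(),
                                               table = dairy_intake_table(),
                                               rule = c("proportional", "milk-only"),
                                               strict = FALSE) {
  rule <- match.arg(rule)
  pred <- predict_milk_iodine(model, iodine_in, gsl = gsl,
                              rapeseed = rapeseed, strict = strict)
  if (length(pred$value) != 1L) {
    stop("supply a single feed scenario", call. = FALSE)
  }
  out <- intake_vs_milk_concentration(profiles, table,
                                      conc_values = pred$value, rule = rule)
  attr(out, "milk_conc") <- pred$value
  out
}
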