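# Dietary iodine intake from dairy products.

profiles <- population_profiles()
tab <- dairy_intake_table()

test_that("per-product contributions reproduce the intake table", {
  men <- contribution_by_product(profiles$men)
  expect_equal(unname(men["milk"]), 68)            # 340 g/day * 20 ug/100 g
  expect_equal(unname(men["cheese"]), 14)
  toddlers <- contribution_by_product(profiles$toddlers)
  expect_equal(unname(toddlers["whey_cheese"]), 14) # 10 g/day * 140 ug/100 g
  expect_equal(unname(round_half_up(toddlers["milk"])), 63)
  zero <- profiles$men
  zero$intake[] <- 0
  expect_true(all(contribution_by_product(zero) == 0))
  bad <- profiles$men
  names(bad$intake)[1] <- "butter"
  expect_error(contribution_by_product(bad), "unknown product.*butter")
})

test_that("group totals and percent of recommendation match the survey table", {
  totals <- vapply(profiles, total_dairy_iodine, 0)
  expect_equal(unname(totals), c(102.31, 73.95, 97.05, 98.44),
               tolerance = 1e-12)
  expect_equal(unname(round_half_up(totals[c("men", "women", "toddlers")])),
               c(102, 74, 97))
  pct <- mapply(percent_of_recommendation, totals, profiles)
  expect_equal(unname(round_half_up(pct)), c(68, 49, 108, 56))
  expect_equal(percent_of_recommendation(0, profiles$men), 0)
})

test_that("totals are invariant to product order and row splitting", {
  perm <- sample(seq_len(nrow(tab)))
  tab_perm <- tab[perm, ]
  pr <- profiles$women
  pr$intake <- pr$intake[sample(names(pr$intake))]
  expect_equal(total_dairy_iodine(pr, tab_perm),
               total_dairy_iodine(profiles$women, tab))
  # split the milk row into two halves summing to the same intake
  tab_split <- rbind(tab, tab[tab$product == "milk", ])
  tab_split$product[nrow(tab_split)] <- "milk_b"
  pr2 <- profiles$women
  milk <- pr2$intake[["milk"]]
  pr2$intake[["milk"]] <- milk / 2
  pr2$intake <- c(pr2$intake, milk_b = milk / 2)
  expect_equal(total_dairy_iodine(pr2, tab_split),
               total_dairy_iodine(profiles$women, tab))
})

test_that("scenario curves scale linearly and anchor at 200 ug/kg", {
  cur <- intake_vs_milk_concentration(conc_values = c(100, 200, 400))
  at200 <- cur[cur$milk_conc == 200, ]
  expect_equal(at200$total_ug_day[match(c("men", "women", "toddlers", "pregnant"),
                                        at200$group)],
               c(102.31, 73.95, 97.05, 98.44))
  # proportional rule: exactly linear in the milk concentration
  at400 <- cur[cur$milk_conc == 400, ]
  expect_equal(at400$total_ug_day, 2 * at200$total_ug_day)
  expect_equal(at400$total_ug_day[at400$group == "toddlers"], 2 * 97.05)
  at100 <- cur[cur$milk_conc == 100, ]
  expect_equal(at100$total_ug_day, at200$total_ug_day / 2)
  # vanishing concentration drives the percent to zero
  tiny <- intake_vs_milk_concentration(conc_values = 1e-9)
  expect_true(all(tiny$percent_of_recommended < 1e-9))
  expect_error(intake_vs_milk_concentration(conc_values = 0), "positive")
  expect_error(intake_vs_milk_concentration(conc_values = 200,
                                            rule = "cheddar"))
})

test_that("milk-only rule keeps cheese contributions fixed", {
  cur <- intake_vs_milk_concentration(conc_values = c(200, 400),
                                      rule = "milk-only")
  at200 <- cur[cur$milk_conc == 200, ]
  expect_equal(at200$total_ug_day[at200$group == "men"], 102.31)
  men400 <- cur$total_ug_day[cur$milk_conc == 400 & cur$group == "men"]
  # fluid products double (68 + 3.36 + 4.37 + 4.18), cheeses (14 + 8.4) fixed
  expect_equal(men400, 2 * (68 + 3.36 + 4.37 + 4.18) + 14 + 8.4)
  expect_lt(men400, 2 * 102.31)
})

test_that("percent crosses 100 at conc = 200 * recommendation / total(200)", {
  for (g in names(profiles)) {
    tot200 <- total_dairy_iodine(profiles[[g]])
    conc_star <- 200 * profiles[[g]]$recommended / tot200
    cur <- intake_vs_milk_concentration(profiles[g], conc_values = conc_star)
    expect_equal(cur$percent_of_recommended, 100, tolerance = 1e-10)
  }
  # 2-year-olds meet their recommendation below the current milk level
  tod <- profiles$toddlers
  conc_star <- 200 * tod$recommended / total_dairy_iodine(tod)
  expect_lt(conc_star, 200)
})

test_that("feed scenarios chain the transfer model into group intakes", {
  m2 <- milk_iodine_model("model2")
  res <- feed_scenario_to_population_intake(m2, iodine_in = 1, rapeseed = 0)
  conc <- attr(res, "milk_conc")
  expect_equal(round_half_up(conc), 260)
  men <- res[res$group == "men", ]
  expect_equal(men$total_ug_day, 102.31 * conc / 200, tolerance = 1e-12)
  expect_equal(round_half_up(men$total_ug_day), 133)
  # a ration predicting exactly 200 ug/kg returns the reference totals
  iod200 <- invert_required_iodine(m2, 200, rapeseed = 0)
  res200 <- feed_scenario_to_population_intake(m2, iod200, rapeseed = 0)
  expect_equal(res200$total_ug_day,
               unname(vapply(profiles, total_dairy_iodine, 0)),
               tolerance = 1e-4)
  expect_error(feed_scenario_to_population_intake(m2, iodine_in = 6,
                                                  rapeseed = 0,
                                                  strict = TRUE),
               "validity")
})
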