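# Prediction, inversion and grid evaluation of the published models.

m1 <- milk_iodine_model("model1")
m2 <- milk_iodine_model("model2")

test_that("published worked predictions are reproduced", {
  p <- predict_milk_iodine(m2, iodine_in = 1, rapeseed = 0)
  expect_equal(round_half_up(p$value), 260)
  expect_equal(p$value, exp(p$log_value))
  expect_equal(round_half_up(predict_milk_iodine(m2, 2, rapeseed = 150)$value),
               206)
  # intercept-only point
  expect_equal(predict_milk_iodine(m2, 0, rapeseed = 0)$value, exp(4.22))
})

test_that("predictions equal literal polynomial evaluation", {
  set.seed(41)
  for (k in 1:25) {
    iod <- runif(1, 0, 4)
    gsl <- runif(1, 0, 14)
    rap <- runif(1, 0, 180)
    expect_equal(predict_milk_iodine(m1, iod, gsl = gsl)$log_value,
                 oracle_model1_log(iod, gsl), tolerance = 1e-12)
    expect_equal(predict_milk_iodine(m2, iod, rapeseed = rap)$log_value,
                 oracle_model2_log(iod, rap), tolerance = 1e-12)
  }
  # the frozen hand-summed point
  expect_equal(predict_milk_iodine(m1, 2, gsl = 10)$log_value, 5.3629,
               tolerance = 1e-10)
})

test_that("out-of-range rations warn by default and error under strict", {
  expect_warning(predict_milk_iodine(m2, 5, rapeseed = 0), "validity")
  expect_error(predict_milk_iodine(m2, 5, rapeseed = 0, strict = TRUE),
               "iodine_in = 5")
  expect_error(predict_milk_iodine(m2, 2, rapeseed = 200, strict = TRUE),
               "rapeseed = 200")
  expect_error(predict_milk_iodine(m2, -1, rapeseed = 0), "non-negative")
  v <- suppressWarnings(predict_milk_iodine(m1, c(1, 5), gsl = c(20, 2)))
  expect_equal(sort(v$violations$variable), c("gsl", "iodine_in"))
})

test_that("log-prediction is strictly increasing in feed iodine", {
  iod <- seq(0, 4, by = 0.01)
  for (g in c(0, 5, 10, 14)) {
    lp <- predict(m1, data.frame(iodine_in = iod, gsl = g),
                  type = "log", check = FALSE)
    expect_true(all(diff(lp) > 0), label = paste("model1 at gsl", g))
  }
  for (r in c(0, 60, 120, 180)) {
    lp <- predict(m2, data.frame(iodine_in = iod, rapeseed = r),
                  type = "log", check = FALSE)
    expect_true(all(diff(lp) > 0), label = paste("model2 at rapeseed", r))
  }
})

test_that("rapeseed model is non-increasing in rapeseed up to 170 g/kg DM", {
  rap <- seq(0, 170, by = 0.5)
  for (iod in c(0.5, 1, 2, 3, 4)) {
    lp <- predict(m2, data.frame(iodine_in = iod, rapeseed = rap),
                  type = "log", check = FALSE)
    expect_true(all(diff(lp) <= 0), label = paste("iodine", iod))
  }
})

test_that("inversion solves predict to 1e-3 and round-trips", {
  expect_equal(invert_required_iodine(m2, 260, rapeseed = 0), 1.0,
               tolerance = 1e-3)
  expect_equal(invert_required_iodine(m2, exp(4.22), rapeseed = 0), 0,
               tolerance = 1e-6)
  target <- predict_milk_iodine(m1, 3, gsl = 5)$value
  expect_equal(invert_required_iodine(m1, target, gsl = 5), 3,
               tolerance = 1e-3)
  # round-trip identity over random valid rations, both models
  set.seed(42)
  for (k in 1:20) {
    iod <- runif(1, 0.05, 3.95)
    g <- runif(1, 0, 14)
    r <- runif(1, 0, 180)
    t1 <- predict_milk_iodine(m1, iod, gsl = g)$value
    expect_equal(invert_required_iodine(m1, t1, gsl = g), iod,
                 tolerance = 1e-3)
    t2 <- predict_milk_iodine(m2, iod, rapeseed = r)$value
    expect_equal(invert_required_iodine(m2, t2, rapeseed = r), iod,
                 tolerance = 1e-3)
  }
})

test_that("unattainable targets report the achievable range", {
  expect_error(invert_required_iodine(m2, 10, rapeseed = 0), "unattainable")
  expect_error(invert_required_iodine(m2, 5000, rapeseed = 0), "achievable")
  expect_error(invert_required_iodine(m2, 260, rapeseed = 300),
               "outside validity")
  expect_error(invert_required_iodine(m2, -5, rapeseed = 0), "positive")
})

test_that("prediction grid matches cellwise predictions and the envelope", {
  g <- prediction_grid(m2, seq(1.5, 2, by = 0.05), seq(50, 70, by = 1))
  expect_equal(round_half_up(min(g)), 216)
  expect_equal(round_half_up(max(g)), 315)
  single <- prediction_grid(m2, 2, 150)
  expect_equal(dim(single), c(1L, 1L))
  expect_equal(round_half_up(single[1, 1]), 206)
  expect_equal(unname(prediction_grid(m1, 0, 0)[1, 1]), exp(4.16))
  expect_equal(unname(prediction_grid(m2, 0, 0)[1, 1]), exp(4.22))
  # cellwise agreement with predict_milk_iodine
  gg <- prediction_grid(m1, c(1, 2), c(0, 10))
  expect_equal(gg[2, 2], predict_milk_iodine(m1, 2, gsl = 10)$value,
               ignore_attr = TRUE)
  # violations are surfaced, never dropped
  expect_warning(gw <- prediction_grid(m2, c(2, 5), c(0, 190)), "validity")
  expect_equal(nrow(attr(gw, "violations")), 4)
  expect_error(prediction_grid(m2, numeric(0), 0), "non-empty")
})

test_that("the two models agree closely where the data were dense", {
  # comparable slice: goitrogen-free diets, feed iodine up to 3 mg/kg DM
  iod <- seq(0, 3, by = 0.05)
  p1 <- predict(m1, data.frame(iodine_in = iod, gsl = 0), check = FALSE)
  p2 <- predict(m2, data.frame(iodine_in = iod, rapeseed = 0), check = FALSE)
  expect_true(all(abs(p1 / p2 - 1) < 0.25))
})

test_that("model accessors and methods behave", {
  expect_length(coef(m1), 9)
  expect_length(coef(m2), 6)
  expect_equal(unname(coef(m2)["1"]), 4.22)
  ci <- confint(m2)
  expect_equal(unname(ci["1", ]), c(3.85, 4.59))
  expect_output(print(m2), "rapeseed")
  expect_output(print(summary(m1)), "Coefficients")
  expect_error(predict(m2), "newdata")
})
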