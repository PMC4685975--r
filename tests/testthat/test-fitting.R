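# OLS fitting, stepwise selection and the study-effect screen.

test_that("noiseless linear data are recovered exactly", {
  d <- data.frame(iodine_in = seq(0.1, 4, length.out = 30), rapeseed = 0)
  d$milk_iodine <- exp(4.22 + 1.84 * d$iodine_in)
  f <- fit_ols(d, c("1", "iodineIn"))
  expect_equal(unname(coef(f)), c(4.22, 1.84), tolerance = 1e-10)
  expect_lt(f$rmse, 1e-10)
})

test_that("intercept-only fit is the mean with rmse = sample SD", {
  d <- random_dataset(25, seed = 5)
  f <- fit_ols(d, "1")
  y <- log(d$milk_iodine)
  expect_equal(unname(coef(f)), mean(y))
  expect_equal(f$rmse, sd(y))
  expect_equal(f$error_df, 24)
})

test_that("estimates, SEs and CIs match the normal-equations oracle", {
  for (seed in c(3, 17, 88)) {
    d <- random_dataset(20, seed = seed)
    terms <- c("1", "iodineIn", "rapeseed", "iodineIn^2")
    f <- fit_ols(d, terms)
    X <- term_matrix(terms, d)
    y <- log(d$milk_iodine)
    beta <- oracle_ols(X, y)
    expect_equal(unname(coef(f)), unname(beta), tolerance = 1e-8)
    # inference oracle: unbiased sigma^2 and t quantiles
    res <- y - X %*% beta
    s2 <- sum(res^2) / (20 - 4)
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(f$coefficients$se, unname(se), tolerance = 1e-8)
    tq <- qt(0.975, 16)
    expect_equal(f$coefficients$ci_high - f$coefficients$ci_low,
                 unname(2 * tq * se), tolerance = 1e-8)
    expect_equal(f$coefficients$p,
                 unname(2 * pt(abs(beta / se), 16, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear term", {
  d <- random_dataset(15, seed = 2)
  d$rapeseed <- 2 * d$iodine_in
  expect_error(fit_ols(d, c("1", "iodineIn", "rapeseed")),
               "singular.*rapeseed")
})

test_that("adding a term weakly decreases rmse (adj R2 need not follow)", {
  d <- random_dataset(40, seed = 9)
  base_terms <- c("1", "iodineIn")
  f0 <- fit_ols(d, base_terms)
  sse0 <- f0$rmse^2 * f0$error_df
  for (extra in c("rapeseed", "iodineIn^2", "gsl")) {
    f1 <- fit_ols(d, c(base_terms, extra))
    expect_lte(f1$rmse^2 * f1$error_df, sse0 + 1e-10)
  }
})

test_that("stepwise on noiseless linear data selects exactly the line", {
  set.seed(6)
  d <- data.frame(study_id = "a", iodine_in = seq(0.2, 4, length.out = 69),
                  rapeseed = runif(69, 0, 100))
  d$milk_iodine <- exp(2 * d$iodine_in)
  pool <- build_candidate_terms(c("iodineIn", "rapeseed"), 3)
  f <- stepwise_select(d, pool)
  expect_identical(f$terms, c("1", "iodineIn"))
})

test_that("stepwise respects p thresholds, hierarchy and determinism", {
  expect_error(stepwise_select(random_dataset(30, 1),
                               c("1", "iodineIn"), p_enter = 0.5,
                               p_remove = 0.1),
               "p_enter <= p_remove")
  d <- generate_dataset(simulation_config(seed = 314))
  pool <- build_candidate_terms(c("iodineIn", "rapeseed"), 3)
  f1 <- stepwise_select(d, pool)
  f2 <- stepwise_select(d, pool)
  expect_identical(f1$terms, f2$terms)
  expect_identical(coef(f1), coef(f2))
  # hierarchy: every selected term has its parents selected
  for (t in setdiff(f1$terms, "1")) {
    expect_true(all(lactiodine:::term_parents(t) %in% f1$terms), label = t)
  }
})

test_that("pure-noise responses select the intercept alone in >=90% of runs", {
  pool <- build_candidate_terms(c("iodineIn", "rapeseed"), 3)
  set.seed(11)
  hits <- replicate(100, {
    d <- generate_dataset(simulation_config(seed = sample.int(1e6, 1)))
    d$milk_iodine <- exp(rnorm(69, 5, 0.4))
    identical(stepwise_select(d, pool)$terms, "1")
  })
  expect_gte(mean(hits), 0.90)
})

test_that("stepwise recovers the generating structure from synthetic data", {
  # truth = packaged rapeseed model, its published residual SD, n = 69
  pool <- build_candidate_terms(c("iodineIn", "rapeseed"), 3)
  truth_terms <- milk_iodine_model("model2")$terms
  set.seed(2024)
  seeds <- sample.int(1e6, 30)
  sel <- lapply(seeds, function(s) {
    stepwise_select(generate_dataset(simulation_config(seed = s)), pool)$terms
  })
  # the intercept and both main effects are found every time
  for (s in sel) expect_true(all(c("1", "iodineIn", "rapeseed") %in% s))
  # the full published term set is recovered a non-trivial fraction of runs
  exact <- vapply(sel, function(s) setequal(s, truth_terms), TRUE)
  expect_gte(sum(exact), 2)
  # false discoveries are rare: on average under one spurious term per fit
  spurious <- vapply(sel, function(s) length(setdiff(s, truth_terms)), 0L)
  expect_lt(mean(spurious), 1)
})

test_that("milk_iodine_fit wires selection, inference and cross-validation", {
  d <- generate_dataset(simulation_config(seed = 42))
  f <- milk_iodine_fit(d, covariate = "rapeseed")
  expect_s3_class(f, "iodine_model")
  expect_false(is.na(f$rmsecv))
  expect_equal(f$rmsecv, loo_rmsecv(d, f$terms))
  expect_equal(f$error_df, 69 - length(f$terms))
  expect_equal(length(residuals(f)), 69)
  expect_equal(fitted(f) + residuals(f), log(d$milk_iodine))
  # fixed-term fit skips selection
  ffix <- milk_iodine_fit(d, covariate = "rapeseed",
                          terms = milk_iodine_model("model2")$terms)
  expect_identical(ffix$terms, milk_iodine_model("model2")$terms)
})

test_that("study screen: identical studies give F ~ 0, offsets are detected", {
  d <- data.frame(study_id = rep(c("a", "b"), each = 10),
                  milk_iodine = rep(exp(c(5, 5.3, 5.1, 4.9, 5.2)), 4))
  d$milk_iodine <- rep(d$milk_iodine[1:10], 2) # identical response per study
  scr <- study_effect_screen(d)
  expect_lt(scr$f_statistic, 1e-20)
  expect_gt(scr$f_p_value, 0.999)

  set.seed(8)
  d2 <- random_dataset(60, seed = 8)
  d2$study_id <- rep(c("s1", "s2", "s3"), each = 20)
  d2$milk_iodine <- d2$milk_iodine * exp(rep(c(-1, 0, 1), each = 20))
  expect_lt(study_effect_screen(d2)$f_p_value, 0.001)

  expect_error(study_effect_screen(data.frame(study_id = "a",
                                              milk_iodine = c(1, 2))),
               "degenerate")
})

test_that("study-screen F p-values are uniform under the null", {
  set.seed(77)
  pvals <- replicate(1000, {
    d <- data.frame(study_id = rep(sprintf("s%02d", 1:10), each = 7),
                    milk_iodine = exp(rnorm(70, 5, 0.4)))
    study_effect_screen(d)$f_p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_true(all(pvals >= 0 & pvals <= 1))
})
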