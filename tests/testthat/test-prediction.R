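test_that("a scenario at reference levels returns the intercept", {
  fit <- make_known_fit(intercept = 40)
  sc <- prediction_scenario("dog baseline", species = "dog",
                            follow_up_hours = 0)
  pr <- predict_outcome(fit, sc)
  expect_equal(pr$point, 40)
})

test_that("prediction is the hand-computed linear combination", {
  fit <- make_known_fit(intercept = 40, b_pig = 21.6, b_fu = -0.03)
  sc <- prediction_scenario("pig 1wk", species = "pig",
                            follow_up_hours = 168)
  pr <- predict_outcome(fit, sc)
  expect_equal(pr$point, 40 + 21.6 - 0.03 * 168)   # 56.56
  expect_equal(pr$ci_low, pr$point - 1.959964 * pr$se)
  # new-study interval is wider by the residual heterogeneity
  pr2 <- predict_outcome(fit, sc, interval = "new_study")
  expect_gt(pr2$se, pr$se)
  expect_equal(pr2$se^2 - pr$se^2, fit$tau2_resid, tolerance = 1e-10)
})

test_that("unresolvable scenarios raise configuration errors", {
  fit <- make_known_fit()
  expect_error(predict_outcome(fit, prediction_scenario("x", species = "pig")),
               "configuration error")   # follow-up missing
  expect_error(
    predict_outcome(fit, prediction_scenario("x", species = "goat",
                                             follow_up_hours = 24)),
    "configuration error")
})

test_that("early EF predictions are flagged for myocardial stunning", {
  fit <- make_known_fit(outcome = "EF", intercept = 45, b_pig = 2, b_fu = 0)
  sc <- prediction_scenario("pig early", species = "pig",
                            follow_up_hours = 24)
  pr <- predict_outcome(fit, sc)
  expect_true("stunning_window" %in% pr$flags)
  late <- predict_outcome(fit, sc, follow_up_hours = 168)
  expect_false("stunning_window" %in% late$flags)

  rep <- scenario_report(list(EF = fit), list(sc), follow_up_hours = c(24))
  expect_identical(rep$rendered, "—†")
  expect_true(is.na(rep$point))
})

test_that("follow-up beyond the fitted range is marked as extrapolated", {
  fit <- make_known_fit(fu_range = c(24, 400))
  sc <- prediction_scenario("pig", species = "pig", follow_up_hours = 672)
  pr <- predict_outcome(fit, sc)
  expect_true("extrapolated_follow_up" %in% pr$flags)
  rep <- scenario_report(list(IS_AAR = fit), list(sc),
                         follow_up_hours = c(168, 672))
  expect_match(rep$rendered[2], "^\\(.*\\)\\*$")
  expect_false(grepl("\\(", rep$rendered[1]))
})

test_that("the report grid enumerates scenarios x outcomes x times", {
  fits <- list(IS_AAR = make_known_fit("IS_AAR"),
               IS_LV = make_known_fit("IS_LV", intercept = 18, b_pig = 4,
                                      b_fu = -0.001),
               EF = make_known_fit("EF", intercept = 42, b_pig = 3, b_fu = 0))
  sc <- list(
    prediction_scenario("Pig A", species = "pig"),
    prediction_scenario("Dog B", species = "dog"),
    prediction_scenario("Pig C", species = "pig"))
  rep <- scenario_report(fits, sc, follow_up_hours = c(24, 168, 672))
  expect_identical(nrow(rep), 27L)

  # every unflagged cell equals the hand-computed linear predictor
  for (i in which(rep$flags == "")) {
    f <- fits[[rep$outcome[i]]]
    is_pig <- grepl("Pig", rep$scenario[i])
    hand <- f$coefficients["intercept"] +
      is_pig * f$coefficients["species:pig"] +
      rep$follow_up_hours[i] * f$coefficients["follow_up_hours"]
    expect_equal(rep$point[i], unname(hand), tolerance = 1e-12)
  }

  # cells are invariant to scenario ordering
  rep2 <- scenario_report(fits, rev(sc), follow_up_hours = c(24, 168, 672))
  key <- function(d) d[order(d$scenario, d$outcome, d$follow_up_hours),
                       c("scenario", "outcome", "follow_up_hours", "point")]
  expect_equal(key(rep), key(rep2), ignore_attr = TRUE)
})

test_that("default scenarios cover the three common designs", {
  sc <- default_scenarios()
  expect_length(sc, 3)
  expect_identical(vapply(sc, `[[`, "", "name"),
                   c("Pig I/R (60 min) LAD model",
                     "Dog I/R (60 min) LAD model",
                     "Pig permanent LAD model"))
})

test_that("interval width grows away from the continuous centroid", {
  # with a genuine fitted covariance, se(x) is convex in follow-up
  cfg <- synthetic_config(k_studies = 120, seed = 40,
                          true_betas = list(follow_up_hours = -0.03))
  ds <- suppressMessages(generate_arms(cfg))
  d <- build_design_matrix(effects_from_arms(ds, "IS_AAR"),
                           design_spec(c("species", "follow_up_hours")))
  fit <- fit_meta_regression(X = d, outcome = "IS_AAR")
  sc <- prediction_scenario("dog", species = "dog")
  centroid <- weighted.mean(d$data$follow_up_hours, 1 / d$v)
  widths <- vapply(centroid + c(0, 100, 200, 400, 600), function(fu) {
    pr <- predict_outcome(fit, sc, follow_up_hours = fu)
    pr$ci_high - pr$ci_low
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("ols association recovers exact and null relations", {
  x <- 1:20
  res <- suppressWarnings(ols_association(x, 2 * x))  # perfect-fit warning
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_lt(res$p, 1e-12)

  resr <- suppressWarnings(ols_association(rev(x), rev(2 * x)))
  expect_equal(resr$slope, res$slope, tolerance = 1e-12)

  expect_error(ols_association(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(ols_association(1:2, 1:2), "insufficient data")

  set.seed(41)
  pvals <- replicate(500, ols_association(rnorm(30), rnorm(30))$p)
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})
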