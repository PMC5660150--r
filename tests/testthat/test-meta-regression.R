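eff_fixture <- function(k = 12, seed = 42, betas = list(), tau2 = 9,
                        intercept = 50) {
  cfg <- synthetic_config(k_studies = k, seed = seed, true_betas = betas,
                          tau2_true = tau2, true_intercept = intercept)
  effects_from_arms(suppressMessages(generate_arms(cfg)), "IS_AAR")
}

test_that("dummy coding produces one column per non-reference level", {
  eff <- eff_fixture(k = 30, seed = 2)
  d <- build_design_matrix(eff, design_spec("sex"))
  lev <- d$xlevels$sex
  expect_identical(ncol(d$X), length(lev))       # intercept + (L-1) dummies
  expect_identical(d$term_info$term[1], "intercept")
  expect_true(all(d$X[, 1] == 1))
})

test_that("species labels are phrased against the reference level", {
  eff <- eff_fixture(k = 120, seed = 8)
  d <- build_design_matrix(eff, design_spec("species"))
  expect_setequal(setdiff(d$term_info$label, "intercept"),
                  c("pig (vs dog)", "sheep (vs dog)"))
})

test_that("degenerate and misconfigured designs are caught", {
  eff <- eff_fixture(k = 10, seed = 3)
  eff$species <- "dog"
  expect_warning(d <- build_design_matrix(eff, design_spec("species")),
                 "single level")
  expect_identical(ncol(d$X), 1L)

  eff2 <- eff_fixture(k = 10, seed = 3)
  expect_error(
    build_design_matrix(eff2, design_spec("species",
                                          reference_levels = c(species = "sheep"))),
    "configuration error|absent")
})

test_that("rows with missing moderator values are dropped with a count", {
  eff <- eff_fixture(k = 20, seed = 4)
  eff$weight_kg[c(2, 5)] <- NA
  expect_message(d <- build_design_matrix(eff, design_spec("weight_kg")),
                 "2 row")
  expect_identical(nrow(d$X), 18L)
  expect_identical(d$n_dropped, 2L)
})

test_that("intercept-only regression reduces to random-effects pooling", {
  eff <- eff_fixture(k = 25, seed = 6)
  X <- matrix(1, nrow(eff), 1, dimnames = list(NULL, "intercept"))
  fit <- fit_meta_regression(eff$yi, eff$vi, X)
  pool <- pool_random_effects(eff$yi, eff$vi)
  expect_equal(unname(fit$coefficients[1]), pool$mu, tolerance = 1e-8)
  expect_equal(unname(fit$se[1]), pool$se, tolerance = 1e-8)
})

test_that("beta and covariance match the brute-force WLS oracle", {
  y <- c(40.1, 55.2, 47.9, 61.0, 44.4, 52.3)
  v <- c(2.0, 4.1, 1.5, 6.2, 2.8, 3.3)
  X <- cbind(intercept = 1, x1 = c(0, 1, 0, 1, 0, 1),
             x2 = c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4))
  t2 <- grid_reml_tau2_X(y, v, X, upper = 80, step = 1e-3)
  oracle <- wls_oracle(y, v, X, t2)
  fit <- fit_meta_regression(y, v, X)
  expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-3)
  expect_equal(unname(fit$cov), unname(oracle$cov), tolerance = 1e-2)
  expect_equal(fit$tau2_resid, t2, tolerance = 1e-3)
})

test_that("meta-regression agrees with metafor including the omnibus test", {
  eff <- eff_fixture(k = 80, seed = 10,
                     betas = list("species=pig" = 12, follow_up_hours = -0.02))
  d <- build_design_matrix(eff, design_spec(c("species", "follow_up_hours")))
  fit <- fit_meta_regression(X = d)
  ref <- metafor::rma(yi = d$y, vi = d$v, mods = d$X[, -1], method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(unname(fit$coefficients), unname(c(ref$beta)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(ref$se), tolerance = 1e-5)
  expect_equal(fit$tau2_resid, ref$tau2, tolerance = 1e-5)
  expect_equal(fit$omnibus_p, ref$QMp, tolerance = 1e-6)
})

test_that("perfectly collinear terms raise a collinearity error by name", {
  y <- rnorm(8, 50); v <- rep(1, 8)
  x <- rep(c(0, 1), 4)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(fit_meta_regression(y, v, X), "collinearity.*b")
})

test_that("a two-level omnibus test equals its own pairwise contrast", {
  eff <- eff_fixture(k = 40, seed = 12)
  eff$comedication <- rep(c(TRUE, FALSE), 20)   # guarantee both levels
  d <- build_design_matrix(eff, design_spec("comedication"))
  fit <- fit_meta_regression(X = d)
  ct <- pairwise_category_tests(fit, "comedication")
  expect_identical(nrow(ct), 1L)
  expect_equal(ct$p, fit$omnibus_p, tolerance = 1e-10)
  expect_equal(ct$p, unname(fit$pval[2]), tolerance = 1e-10)
})

test_that("three levels yield all C(3,2) contrasts", {
  eff <- eff_fixture(k = 150, seed = 13)
  d <- build_design_matrix(eff, design_spec("species"))
  fit <- fit_meta_regression(X = d)
  ct <- pairwise_category_tests(fit, "species")
  expect_identical(nrow(ct), 3L)
  expect_error(pairwise_category_tests(fit, "vessel"), "configuration error")
})

test_that("contrasts are invariant to the categorical reference level", {
  eff <- eff_fixture(k = 150, seed = 14, betas = list("species=pig" = 10))
  eff$species <- rep(c("dog", "pig", "sheep"), c(90, 50, 10))
  fit_dog <- fit_meta_regression(
    X = build_design_matrix(eff, design_spec("species")))
  fit_sheep <- fit_meta_regression(
    X = build_design_matrix(eff, design_spec("species",
                                             reference_levels = c(species = "sheep"))))
  # pig-vs-sheep contrast from the dog-referenced fit equals the pig
  # coefficient of the sheep-referenced fit
  ct <- pairwise_category_tests(fit_dog, "species")
  pig_sheep <- ct[ct$label == "pig vs sheep", ]
  expect_equal(pig_sheep$estimate,
               unname(fit_sheep$coefficients["species:pig"]),
               tolerance = 1e-8)
  expect_equal(pig_sheep$se, unname(fit_sheep$se["species:pig"]),
               tolerance = 1e-8)
  # and the contrast equals the difference of dog-referenced coefficients
  expect_equal(pig_sheep$estimate,
               unname(fit_dog$coefficients["species:pig"] -
                        fit_dog$coefficients["species:sheep"]),
               tolerance = 1e-12)
})

test_that("coefficients are invariant to row order", {
  eff <- eff_fixture(k = 60, seed = 15, betas = list("species=pig" = 8))
  spec <- design_spec(c("species", "follow_up_hours"))
  f1 <- fit_meta_regression(X = build_design_matrix(eff, spec))
  set.seed(1); perm <- sample(nrow(eff))
  f2 <- fit_meta_regression(X = build_design_matrix(eff[perm, ], spec))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("r2 stays near zero for a pure-noise moderator", {
  set.seed(16)
  r2s <- replicate(200, {
    k <- 40
    y <- rnorm(k, 50, 6)          # tau2 = 36, no moderator effect
    v <- runif(k, 1, 4)
    X <- cbind(intercept = 1, noise = rnorm(k))
    fit_meta_regression(y, v, X)$r2
  })
  expect_lt(median(r2s), 0.05)
  expect_true(all(r2s >= 0 & r2s <= 1))
})

test_that("univariable battery mirrors the per-moderator table layout", {
  cfg <- synthetic_config(k_studies = 120, seed = 18,
                          true_betas = list("species=pig" = 15))
  ds <- suppressMessages(generate_arms(cfg))
  bat <- suppressWarnings(
    fit_univariable_battery(ds, "IS_AAR",
                            moderators = c("species", "sex", "follow_up_hours")))
  expect_named(bat, c("species", "sex", "follow_up_hours"))
  expect_identical(nrow(bat$species$subgroups),
                   length(bat$species$fit$xlevels$species))
  tab <- as.data.frame(bat)
  expect_true(all(c("variable", "category", "n", "mean", "ci_low",
                    "ci_high", "p") %in% names(tab)))
  # subgroup pooled means agree with direct per-level pooling
  eff <- effects_from_arms(ds, "IS_AAR")
  pig <- eff[eff$species == "pig", ]
  direct <- pool_random_effects(pig$yi, pig$vi)
  sg <- bat$species$subgroups
  expect_equal(sg$mean[sg$level == "pig"], direct$mu, tolerance = 1e-8)
})

test_that("a single active moderator dominates univariable detection", {
  set.seed(19)
  hits_true <- 0; hits_null <- 0; R <- 30
  for (r in 1:R) {
    cfg <- synthetic_config(k_studies = 100, tau2_true = 9,
                            true_betas = list("species=pig" = 15))
    ds <- suppressMessages(generate_arms(cfg))
    bat <- suppressWarnings(
      fit_univariable_battery(ds, "IS_AAR", moderators = c("species", "sex")))
    hits_true <- hits_true + (bat$species$fit$omnibus_p < 0.05)
    hits_null <- hits_null + (bat$sex$fit$omnibus_p < 0.05)
  }
  expect_gte(hits_true / R, 0.8)
  expect_lte(hits_null / R, 0.3)
})

test_that("multivariable fit handles separately added moderators", {
  cfg <- synthetic_config(k_studies = 160, seed = 20,
                          true_betas = list("ischemia_minutes" = 0.09),
                          missingness_rates = list(weight_kg = 0.04,
                                                   age_weeks = 0.97,
                                                   ischemia_minutes = 0.2))
  ds <- suppressMessages(generate_arms(cfg))
  spec <- design_spec(c("species", "follow_up_hours", "ischemia_minutes"),
                      add_separately = "ischemia_minutes")
  mv <- fit_multivariable(ds, "IS_AAR", spec)
  expect_s3_class(mv$joint, "reg_fit")
  expect_named(mv$separate, "ischemia_minutes")
  sep <- mv$separate$ischemia_minutes
  # the ischemia term exists, in points per minute, on temporary rows only
  expect_true("ischemia_minutes" %in% names(sep$coefficients))
  expect_match(sep$term_info$label[sep$term_info$term == "ischemia_minutes"],
               "/min")
  expect_lte(sep$k, sum(!is.na(ds$arms$ischemia_minutes)))

  mv0 <- fit_multivariable(ds, "IS_AAR", design_spec("species"))
  expect_length(mv0$separate, 0)
})

test_that("significance gate applies strict alpha = 0.05", {
  expect_true(significance_gate(0.049))
  expect_false(significance_gate(0.05))
  expect_false(significance_gate(0.33))
  expect_error(significance_gate(1.2), "\\[0, 1\\]")
})
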