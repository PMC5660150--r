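# Scenario prediction: expected outcomes for named experimental designs,
# computed from a fitted multivariable meta-regression, plus the auxiliary
# linear-regression association checks.

# EF measured very early after reperfusion is confounded by myocardial
# stunning (transient contractile dysfunction); predictions inside this
# window are flagged and withheld from the default report.
STUNNING_THRESHOLD_HOURS <- 72

#' Define a prediction scenario
#'
#' A named experimental design: a level for every categorical moderator in
#' the fitted model and a value for every continuous one. Follow-up hours
#' are usually left `NA` here and supplied per cell by [scenario_report()].
#'
#' @param name display name, e.g. `"Pig I/R (60 min) LAD model"`.
#' @param ... moderator assignments, e.g. `species = "pig"`,
#'   `occlusion = "temporary"`, `ischemia_minutes = 60`.
#' @return Object of class `prediction_scenario` (a named list).
#' @export
prediction_scenario <- function(name, ...) {
  values <- list(...)
  if (!length(names(values)) || any(!nzchar(names(values)))) {
    stop("all scenario values must be named by moderator", call. = FALSE)
  }
  structure(list(name = name, values = values),
            class = "prediction_scenario")
}

#' The common large-animal MI designs shipped by default
#'
#' Three frequently used models: a pig and a dog ischemia-reperfusion model
#' with 60 minutes of temporary LAD occlusion, and a pig permanent LAD
#' ligation model. Moderators not fixed by the design (sex, co-medication,
#' immunosuppression, surgical approach, quantification, study quality) are
#' held at typical values; these are assumptions of the scenario file, not
#' properties of the designs.
#'
#' @return List of three [prediction_scenario()] objects.
#' @export
default_scenarios <- function() {
  base <- list(sex = "both", approach = "open", comedication = "no",
               immunosuppression = "no", quality_score = 5)
  mk <- function(name, species, occlusion, ischemia) {
    do.call(prediction_scenario,
            c(list(name = name, species = species, occlusion = occlusion,
                   vessel = "LAD", ischemia_minutes = ischemia), base))
  }
  list(mk("Pig I/R (60 min) LAD model", "pig", "temporary", 60),
       mk("Dog I/R (60 min) LAD model", "dog", "temporary", 60),
       mk("Pig permanent LAD model", "pig", "permanent", NA_real_))
}

scenario_value <- function(scenario, what) {
  v <- scenario$values[[what]]
  if (is.null(v)) NA else v
}

#' Predict an outcome for a scenario
#'
#' Builds the design row x for the scenario, returns the linear predictor
#' `x' beta` with a 95% z-based interval from `sqrt(x' cov x)` (a
#' confidence interval for the conditional mean; add the residual tau2 via
#' `interval = "new_study"` for a new-study interval). Flags:
#' `extrapolated_follow_up` when a continuous value lies outside the range
#' seen by the fit, `stunning_window` for EF scenarios with follow-up below
#' `stunning_threshold_hours`.
#'
#' @param fit a `reg_fit` carrying term metadata (from
#'   [fit_multivariable()]'s components or [fit_meta_regression()] on a
#'   [build_design_matrix()] design).
#' @param scenario a [prediction_scenario()].
#' @param follow_up_hours optional follow-up overriding the scenario's own
#'   value.
#' @param interval `"mean"` (default) or `"new_study"`.
#' @param stunning_threshold_hours EF flagging threshold, in hours.
#' @return Object of class `predicted_outcome`: list with `point`, `se`,
#'   `ci_low`, `ci_high` (percent) and `flags` (character subset of
#'   `{"extrapolated_follow_up", "stunning_window"}`).
#' @export
predict_outcome <- function(fit, scenario, follow_up_hours = NULL,
                            interval = c("mean", "new_study"),
                            stunning_threshold_hours = STUNNING_THRESHOLD_HOURS) {
  stopifnot(inherits(fit, "reg_fit"), inherits(scenario, "prediction_scenario"))
  interval <- match.arg(interval)
  info <- fit$term_info
  x <- setNames(numeric(nrow(info)), info$term)
  flags <- character()
  fu <- if (!is.null(follow_up_hours)) follow_up_hours else
    scenario_value(scenario, "follow_up_hours")

  for (i in seq_len(nrow(info))) {
    if (identical(info$type[i], "intercept")) { x[i] <- 1; next }
    m <- info$moderator[i]
    if (identical(info$type[i], "categorical")) {
      lev <- scenario_value(scenario, m)
      if (is.na(lev) || is.null(lev)) {
        stop("configuration error: scenario '", scenario$name,
             "' does not assign moderator '", m, "'", call. = FALSE)
      }
      lev <- moderator_as_level(lev)
      if (!(lev %in% fit$xlevels[[m]])) {
        stop("configuration error: level '", lev, "' of '", m,
             "' was not in the fitted data", call. = FALSE)
      }
      x[i] <- as.numeric(lev == info$level[i])
    } else {
      val <- if (m == "follow_up_hours") fu else scenario_value(scenario, m)
      if (is.na(val) || is.null(val)) {
        stop("configuration error: scenario '", scenario$name,
             "' lacks a value for continuous moderator '", m, "'",
             call. = FALSE)
      }
      x[i] <- as.numeric(val)
      rng <- fit$xranges[[m]]
      if (!is.null(rng) && (x[i] < rng[1L] || x[i] > rng[2L])) {
        flags <- union(flags, "extrapolated_follow_up")
      }
    }
  }

  point <- sum(x * fit$coefficients)
  var_mean <- drop(t(x) %*% fit$cov %*% x)
  se <- sqrt(var_mean + if (interval == "new_study") fit$tau2_resid else 0)
  if (!is.null(fit$outcome) && identical(fit$outcome, "EF") &&
      !is.na(fu) && fu < stunning_threshold_hours) {
    flags <- union(flags, "stunning_window")
  }
  structure(list(point = point, se = se,
                 ci_low = point - Z_CRIT * se, ci_high = point + Z_CRIT * se,
                 flags = flags, scenario = scenario$name),
            class = "predicted_outcome")
}

#' @export
print.predicted_outcome <- function(x, digits = 1, ...) {
  cat(sprintf("%s: %.*f%% (95%% CI %.*f to %.*f)", x$scenario, digits,
              x$point, digits, x$ci_low, digits, x$ci_high))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Scenario-by-outcome prediction grid
#'
#' Evaluates every scenario at every follow-up time against one fitted model
#' per outcome, producing the design-planning table: one cell per
#' (scenario, outcome, follow-up). Cells extrapolating follow-up beyond the
#' fitted range are rendered in parentheses with a `*` (the predictions
#' assume a linear follow-up effect); EF cells inside the stunning window
#' are withheld and rendered as a dagger.
#'
#' @param fits named list of `reg_fit` objects, one per outcome (names are
#'   the outcome labels).
#' @param scenarios list of [prediction_scenario()]s; defaults to
#'   [default_scenarios()].
#' @param follow_up_hours follow-up grid in hours; defaults to 1 day, 1 week
#'   and 4 weeks.
#' @param digits digits for the rendered cell text.
#' @return Data frame with one row per cell: `scenario`, `outcome`,
#'   `follow_up_hours`, `point`, `ci_low`, `ci_high`, `flags`
#'   (comma-separated) and `rendered`.
#' @export
scenario_report <- function(fits, scenarios = default_scenarios(),
                            follow_up_hours = c(24, 168, 672),
                            digits = 0) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  if (inherits(scenarios, "prediction_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) < 1L) stop("need at least one scenario", call. = FALSE)
  rows <- list()
  for (sc in scenarios) {
    for (oc in names(fits)) {
      for (fu in follow_up_hours) {
        pr <- predict_outcome(fits[[oc]], sc, follow_up_hours = fu)
        withheld <- "stunning_window" %in% pr$flags
        extrap <- "extrapolated_follow_up" %in% pr$flags
        rendered <- if (withheld) {
          "—†"
        } else if (extrap) {
          sprintf("(%.*f%%)*", digits, pr$point)
        } else {
          sprintf("%.*f%%", digits, pr$point)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$name, outcome = oc, follow_up_hours = fu,
          point = if (withheld) NA_real_ else pr$point,
          ci_low = if (withheld) NA_real_ else pr$ci_low,
          ci_high = if (withheld) NA_real_ else pr$ci_high,
          flags = paste(pr$flags, collapse = ","),
          rendered = rendered, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares association between two study-level quantities
#'
#' Simple linear regression of `y` on `x` with the two-sided t-test on the
#' slope — used for the auxiliary checks: does the control-arm outcome of a
#' study correlate with the therapeutic effect observed in that study, and
#' do IS/AAR and EF correlate when measured in the same study.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with `slope`, `intercept`, `p` (slope p-value) and `r2`.
#' @export
ols_association <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("insufficient data: need at least 3 points",
                           call. = FALSE)
  if (var(x) == 0) stop("invalid input: x has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       p = unname(sm$coefficients[2L, 4L]), r2 = sm$r.squared)
}
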