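# Proportion meta-analysis of peri- and post-procedural mortality.
#
# Mortality enters as a ratio (dead animals / total animals) per comparison.
# Two measurements in the same procedural setting (e.g. mortality recorded
# both before and after randomization) are combined multiplicatively on the
# survival scale: 1 - p_total = (1 - p1)(1 - p2), with effective sample size
# (n1 + n2)/2. Each comparison is weighted through an explicit inverse-
# root-n convention (see mortality_weight).

WEIGHT_CONVENTIONS <- c("se_inverse_sqrt_n", "weight_inverse_sqrt_n")

#' Regression weight for a mortality comparison
#'
#' The weighting rule is stated as "1 over the square root of the total
#' number of animals", which admits two readings:
#'
#' * `se_inverse_sqrt_n` (default): 1/sqrt(n) is the *standard error* scale,
#'   so the inverse-variance regression weight is proportional to `n`. This
#'   is the statistically conventional reading (large studies weigh more).
#' * `weight_inverse_sqrt_n`: the *weight itself* is `1/sqrt(n)`
#'   (down-weighting large studies), the literal reading.
#'
#' Both are implemented; every result records which convention produced it.
#' Weights are used scale-free downstream (normalized to mean 1 within a
#' dataset), so only their ratios matter.
#'
#' @param n total number of animals (effective n after sequential
#'   combination); positive.
#' @param convention one of `"se_inverse_sqrt_n"`, `"weight_inverse_sqrt_n"`.
#' @return Numeric weight(s), same length as `n`.
#' @examples
#' mortality_weight(16, "weight_inverse_sqrt_n")  # 0.25
#' @export
mortality_weight <- function(n, convention = WEIGHT_CONVENTIONS) {
  convention <- match.arg(convention)
  n <- as.numeric(n)
  if (any(is.na(n)) || any(n <= 0)) {
    stop("invalid input: n must be positive", call. = FALSE)
  }
  switch(convention,
         se_inverse_sqrt_n = n,          # SE ~ 1/sqrt(n)  =>  weight ~ n
         weight_inverse_sqrt_n = 1 / sqrt(n))
}

#' Combine two sequential mortality proportions
#'
#' When mortality in one procedural setting is reported as two sequential
#' measurements, the overall death proportion follows from multiplying the
#' survival fractions: `1 - p_total = (1 - d1/t1) * (1 - d2/t2)`. The
#' effective number of animals is `(t1 + t2) / 2`, and the weight is the
#' module weighting rule applied to that effective n.
#'
#' @param deaths1,total1 first measurement (deaths <= total, total > 0).
#' @param deaths2,total2 second measurement.
#' @param convention weighting convention, see [mortality_weight()].
#' @return List of class `weighted_proportion` with `proportion`, `weight`,
#'   `n_effective` and `convention`.
#' @examples
#' combine_sequential_proportions(1, 10, 2, 10)$proportion  # 0.28
#' @export
combine_sequential_proportions <- function(deaths1, total1, deaths2, total2,
                                           convention = WEIGHT_CONVENTIONS) {
  convention <- match.arg(convention)
  if (any(c(total1, total2) <= 0)) {
    stop("invalid input: totals must be positive", call. = FALSE)
  }
  if (deaths1 < 0 || deaths1 > total1 || deaths2 < 0 || deaths2 > total2) {
    stop("invalid input: deaths must lie in [0, total]", call. = FALSE)
  }
  p1 <- deaths1 / total1
  p2 <- deaths2 / total2
  p_total <- 1 - (1 - p1) * (1 - p2)
  n_eff <- (total1 + total2) / 2
  structure(list(proportion = p_total,
                 weight = mortality_weight(n_eff, convention),
                 n_effective = n_eff, convention = convention),
            class = "weighted_proportion")
}

#' Effect table for mortality records
#'
#' Converts mortality records of one phase into per-comparison death
#' fractions (applying the sequential combination where a second measurement
#' is present) with their weights and effective sample sizes.
#'
#' @param records mortality data frame (the `mortality` element of an
#'   `mi_dataset`) or an `mi_dataset`.
#' @param phase `"peri"` or `"post"`; `NULL` keeps all rows.
#' @param convention weighting convention, see [mortality_weight()].
#' @return Data frame with `study_id`, `proportion`, `weight`, `n_effective`
#'   and the moderator columns; rows with fewer than 2 animals are kept but
#'   flagged in the `small_n` column.
#' @export
mortality_effects <- function(records, phase = NULL,
                              convention = WEIGHT_CONVENTIONS) {
  convention <- match.arg(convention)
  if (inherits(records, "mi_dataset")) records <- records$mortality
  if (!is.null(phase)) {
    phase <- match.arg(phase, PHASE_LEVELS)
    records <- records[records$phase == phase, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("insufficient data: no mortality records", call. = FALSE)
  }
  has2 <- !is.na(records$total2)
  p1 <- records$deaths / records$total
  p2 <- ifelse(has2, records$deaths2 / records$total2, 0)
  proportion <- 1 - (1 - p1) * (1 - p2)
  n_eff <- ifelse(has2, (records$total + records$total2) / 2, records$total)
  out <- data.frame(study_id = records$study_id,
                    proportion = proportion,
                    weight = mortality_weight(n_eff, convention),
                    n_effective = n_eff,
                    small_n = n_eff < 2,
                    stringsAsFactors = FALSE)
  out[MODERATOR_COLS] <- records[MODERATOR_COLS]
  attr(out, "convention") <- convention
  rownames(out) <- NULL
  out
}

#' Pool mortality proportions
#'
#' Weighted random-effects pooling of per-comparison death fractions, with
#' the module's weights (normalized to mean 1) serving as inverse-variance
#' proxies and tau2 REML-estimated on that scale. The confidence interval is
#' clipped to \[0, 1\] before conversion; all results are reported in
#' percent.
#'
#' @inheritParams mortality_effects
#' @return A `meta_fit` on the percent scale (`mu`, `ci_low`, `ci_high` in
#'   percent), with attribute `"convention"`.
#' @export
pool_mortality <- function(records, phase = NULL,
                           convention = WEIGHT_CONVENTIONS) {
  convention <- match.arg(convention)
  eff <- mortality_effects(records, phase, convention)
  w_norm <- eff$weight / mean(eff$weight)
  # The convention fixes only the weight *ratios*; put the proxy variances on
  # the binomial scale of the crude pooled proportion so the interval is in
  # meaningful units (and the fit stays invariant to weight rescaling).
  pbar <- sum(w_norm * eff$proportion) / sum(w_norm)
  pbar_c <- min(max(pbar, 1e-3), 1 - 1e-3)
  v_scale <- mean(pbar_c * (1 - pbar_c) / eff$n_effective)
  v_proxy <- v_scale / w_norm
  fit <- pool_random_effects(eff$proportion, v_proxy, labels = eff$study_id)
  fit$ci_low <- max(0, fit$ci_low)
  fit$ci_high <- min(1, fit$ci_high)
  for (f in c("mu", "se", "ci_low", "ci_high")) fit[[f]] <- 100 * fit[[f]]
  fit$yi <- 100 * fit$yi
  attr(fit, "convention") <- convention
  fit
}

#' Meta-regression on mortality fractions
#'
#' Regresses (combined) death fractions on study-design moderators,
#' delegating to [fit_meta_regression()] with the mortality weighting scheme
#' as `weights_override`. Ischemia duration only applies to temporary
#' occlusion models: when it appears in `spec$add_separately` its separate
#' fit is restricted to temporary-occlusion rows (which is where it is
#' non-missing by construction).
#'
#' @inheritParams mortality_effects
#' @param spec a [design_spec()].
#' @param uni `TRUE` fits one univariable model per moderator instead of the
#'   joint model.
#' @return A `reg_fit` (joint model), or a named list of `reg_fit` when
#'   `uni = TRUE`. Separate moderators are returned in the
#'   `separate` attribute of the joint fit.
#' @export
mortality_metareg <- function(records, spec, phase = NULL,
                              convention = WEIGHT_CONVENTIONS,
                              uni = FALSE) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "design_spec"))
  eff <- mortality_effects(records, phase, convention)
  eff$yi <- eff$proportion
  eff$vi <- 1  # placeholder; weights_override drives the fit

  fit_one <- function(mods) {
    sp <- design_spec(mods, reference_levels = spec$reference_levels)
    sub <- eff
    for (m in mods) sub <- sub[!is.na(sub[[m]]), , drop = FALSE]
    design <- build_design_matrix(sub, sp)
    fit <- fit_meta_regression(X = design,
                               weights_override = design$data$weight,
                               outcome = "mortality")
    attr(fit, "convention") <- convention
    fit
  }

  if (uni) {
    fits <- list()
    for (m in spec$moderators) {
      fits[[m]] <- tryCatch(fit_one(m), error = function(e) {
        warning("moderator '", m, "': ", conditionMessage(e), call. = FALSE)
        NULL
      })
    }
    return(fits)
  }

  joint_mods <- setdiff(spec$moderators, spec$add_separately)
  joint <- fit_one(joint_mods)
  separate <- list()
  for (m in spec$add_separately) {
    separate[[m]] <- tryCatch(fit_one(c(joint_mods, m)), error = function(e) {
      warning("separate moderator '", m, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  attr(joint, "separate") <- separate
  joint
}
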