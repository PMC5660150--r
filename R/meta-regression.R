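# Univariable and multivariable random-effects meta-regression.
#
# Model: y_i = x_i' beta + u_i + e_i, u_i ~ N(0, tau2), e_i ~ N(0, v_i).
# Residual tau2 is REML-estimated; beta is weighted least squares with
# w_i = 1/(v_i + tau2); all tests are z / chi-square referenced (no
# Knapp-Hartung adjustment) and post-hoc pairwise contrasts carry no
# multiplicity correction by default.

CAT_MODERATORS <- c("species", "strain", "sex", "occlusion", "vessel",
                    "approach", "comedication", "immunosuppression",
                    "quantification", "vf_excluded_untreated")
CONT_MODERATORS <- c("follow_up_hours", "ischemia_minutes", "quality_score",
                     "weight_kg", "age_weeks")

CONT_UNITS <- c(follow_up_hours = "/hour", ischemia_minutes = "/min",
                quality_score = "/point", weight_kg = "/kg",
                age_weeks = "/wk")

#' Default reference levels for categorical moderators
#'
#' References are chosen so that coefficients read the way the field reports
#' them ("+x if pig (vs dog)", "+x if permanent (vs temporary)", "+x if LAD
#' (vs LCX)"). Pairwise Wald contrasts are invariant to this choice, so it
#' only affects labelling.
#'
#' @return Named character vector, moderator -> reference level.
#' @export
default_reference_levels <- function() {
  c(species = "dog", strain = "regular_pig", sex = "female",
    occlusion = "temporary", vessel = "LCX", approach = "closed",
    comedication = "no", immunosuppression = "no",
    vf_excluded_untreated = "no")
}

#' Specify a meta-regression design
#'
#' @param moderators moderator names, in the order their terms should appear.
#' @param reference_levels named character vector overriding
#'   [default_reference_levels()] per categorical moderator; unnamed
#'   moderators fall back to the default, then to the alphabetically first
#'   observed level.
#' @param add_separately moderators fitted on their available-data subset as
#'   (joint model + that term) rather than inside the joint model — the
#'   treatment for sparsely reported continuous covariates such as ischemia
#'   duration, weight and age.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(moderators,
                        reference_levels = character(),
                        add_separately = character()) {
  moderators <- as.character(moderators)
  unknown <- setdiff(moderators, c(CAT_MODERATORS, CONT_MODERATORS))
  if (length(unknown)) {
    stop("unknown moderator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(add_separately %in% moderators)) {
    stop("add_separately must be a subset of moderators", call. = FALSE)
  }
  refs <- default_reference_levels()
  refs[names(reference_levels)] <- reference_levels
  structure(list(moderators = moderators, reference_levels = refs,
                 add_separately = as.character(add_separately)),
            class = "design_spec")
}

#' The moderator set analysed by default
#'
#' Species, sex, immunosuppression, co-medication, surgical approach,
#' occlusion type, occluded vessel, quantification method, follow-up duration
#' and study quality enter the joint model; ischemia duration (temporary
#' occlusions only), weight and age are added separately on their
#' available-data subsets because they are sparsely reported.
#'
#' @return A [design_spec()].
#' @export
default_design_spec <- function() {
  design_spec(
    moderators = c("species", "sex", "immunosuppression", "comedication",
                   "approach", "occlusion", "vessel", "quantification",
                   "follow_up_hours", "quality_score",
                   "ischemia_minutes", "weight_kg", "age_weeks"),
    add_separately = c("ischemia_minutes", "weight_kg", "age_weeks"))
}

is_categorical <- function(m) m %in% CAT_MODERATORS

# moderator columns as character, with logicals mapped to yes/no so they can
# be dummy-coded like any other categorical
moderator_as_level <- function(x) {
  if (is.logical(x)) c("no", "yes")[x + 1L] else as.character(x)
}

#' Build the meta-regression design matrix
#'
#' Dummy-codes categorical moderators against their reference levels and
#' enters continuous moderators untransformed in their canonical units
#' (hours, minutes, kg, weeks, quality points). Rows with a missing value in
#' any moderator not listed in `spec$add_separately` are dropped with a
#' logged count; `add_separately` moderators are excluded here (they are
#' fitted by [fit_multivariable()] on their own subsets).
#'
#' @param effects effects table from [effects_from_arms()] (or any data frame
#'   with `yi`, `vi` and moderator columns), or an `mi_dataset` together with
#'   `outcome`.
#' @param spec a [design_spec()].
#' @param outcome outcome to extract when `effects` is an `mi_dataset`.
#' @return List with `y`, `v`, `X` (first column the intercept), `term_info`
#'   (term id, display label, moderator, level, type per column), `xlevels`,
#'   `xranges`, `data` (the rows used) and `n_dropped`.
#' @export
build_design_matrix <- function(effects, spec, outcome = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (inherits(effects, "mi_dataset")) {
    effects <- effects_from_arms(effects, outcome)
  }
  mods <- setdiff(spec$moderators, spec$add_separately)
  missing_cols <- setdiff(mods, names(effects))
  if (length(missing_cols)) {
    stop("moderator(s) absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  keep <- rep(TRUE, nrow(effects))
  for (m in mods) {
    x <- effects[[m]]
    keep <- keep & !is.na(x)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for missing moderator values")
  }
  dat <- effects[keep, , drop = FALSE]
  if (nrow(dat) < 2L) {
    stop("insufficient data: fewer than 2 usable rows", call. = FALSE)
  }

  k <- nrow(dat)
  X <- matrix(1, k, 1L)
  info <- data.frame(term = "intercept", label = "intercept",
                     moderator = NA_character_, level = NA_character_,
                     type = "intercept", stringsAsFactors = FALSE)
  xlevels <- list()
  xranges <- list()

  for (m in mods) {
    if (is_categorical(m)) {
      x <- moderator_as_level(dat[[m]])
      lev <- sort(unique(x))
      ref <- spec$reference_levels[[m]]
      if (is.null(ref) || is.na(ref)) ref <- lev[1L]
      if (!(ref %in% lev)) {
        stop("configuration error: reference level '", ref,
             "' of moderator '", m, "' is absent from the data",
             call. = FALSE)
      }
      lev <- c(ref, setdiff(lev, ref))
      xlevels[[m]] <- lev
      if (length(lev) < 2L) {
        warning("moderator '", m, "' has a single level ('", ref,
                "'); no term added", call. = FALSE)
        next
      }
      for (l in lev[-1L]) {
        X <- cbind(X, as.numeric(x == l))
        info <- rbind(info, data.frame(
          term = paste0(m, ":", l),
          label = paste0(l, " (vs ", ref, ")"),
          moderator = m, level = l, type = "categorical",
          stringsAsFactors = FALSE))
      }
    } else {
      x <- as.numeric(dat[[m]])
      if (length(unique(x)) < 2L) {
        warning("continuous moderator '", m,
                "' is constant; no term added", call. = FALSE)
        next
      }
      xranges[[m]] <- range(x)
      X <- cbind(X, x)
      info <- rbind(info, data.frame(
        term = m, label = paste0(m, " (", CONT_UNITS[[m]], ")"),
        moderator = m, level = NA_character_, type = "continuous",
        stringsAsFactors = FALSE))
    }
  }
  colnames(X) <- info$term
  rownames(info) <- NULL
  list(y = dat$yi, v = dat$vi, X = X, term_info = info,
       xlevels = xlevels, xranges = xranges, data = dat,
       n_dropped = n_dropped)
}

check_rank <- function(X, terms) {
  sv <- svd(X, nu = 0, nv = 0)$d
  tol <- 1e-10 * sv[1L]
  rank <- sum(sv > tol)
  if (rank < ncol(X)) {
    qrX <- qr(X, tol = 1e-10)
    aliased <- terms[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("collinearity error: design matrix is rank deficient; aliased ",
         "term(s): ", paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(rank)
}

#' Fit a random-effects meta-regression
#'
#' REML-estimates the residual between-study variance, then solves the
#' weighted least-squares problem `beta = (X'WX)^-1 X'Wy` with
#' `W = diag(1/(v_i + tau2))` and coefficient covariance `(X'WX)^-1`. The
#' omnibus test is the Wald chi-square of all non-intercept terms;
#' `r2 = max(0, 1 - tau2_residual / tau2_null)` measures heterogeneity
#' explained relative to the intercept-only model on the same rows.
#'
#' When `weights_override` is supplied (the mortality analyses), the weights
#' are normalized to mean 1 within the dataset and their reciprocals are
#' treated as sampling variances, on which tau2 is then profiled as usual;
#' normalization makes the fit invariant to global rescaling of the weights.
#'
#' @param y response vector (percent, or death fractions).
#' @param v sampling variances; ignored when `weights_override` is given.
#' @param X design matrix; either a plain matrix or the list returned by
#'   [build_design_matrix()] (in which case `y` and `v` may be omitted).
#' @param term_info optional term metadata (as from [build_design_matrix()]).
#' @param weights_override optional positive weights replacing the
#'   inverse-variance weighting.
#' @param xlevels,xranges,outcome metadata carried into the fit for post-hoc
#'   contrasts and prediction.
#' @return An object of class `reg_fit` with elements `coefficients`, `se`,
#'   `zval`, `pval`, `cov`, `tau2_resid`, `tau2_null`, `r2`, `omnibus_p`,
#'   `omnibus_df`, `k`, `term_info`, `term_labels`, `xlevels`, `xranges`,
#'   `outcome`.
#' @export
fit_meta_regression <- function(y = NULL, v = NULL, X, term_info = NULL,
                                weights_override = NULL, xlevels = NULL,
                                xranges = NULL, outcome = NULL) {
  if (is.list(X) && !is.null(X$X)) {
    design <- X
    if (is.null(y)) y <- design$y
    if (is.null(v)) v <- design$v
    if (is.null(term_info)) term_info <- design$term_info
    if (is.null(xlevels)) xlevels <- design$xlevels
    if (is.null(xranges)) xranges <- design$xranges
    X <- design$X
  }
  X <- as.matrix(X)
  k <- nrow(X)
  p <- ncol(X)
  if (length(y) != k || length(v) != k) {
    stop("rows of X must match length of y and v", call. = FALSE)
  }
  if (k < p + 1L) {
    stop("insufficient data: need at least ", p + 1L, " rows for ", p,
         " terms", call. = FALSE)
  }
  if (is.null(term_info)) {
    term_info <- data.frame(
      term = if (!is.null(colnames(X))) colnames(X) else paste0("b", seq_len(p) - 1L),
      label = NA_character_, moderator = NA_character_,
      level = NA_character_, type = NA_character_, stringsAsFactors = FALSE)
    term_info$label <- term_info$term
  }
  check_rank(X, term_info$term)

  if (!is.null(weights_override)) {
    w0 <- as.numeric(weights_override)
    if (length(w0) != k || any(!is.finite(w0)) || any(w0 <= 0)) {
      stop("weights_override must be positive and match the rows",
           call. = FALSE)
    }
    # The weights fix only relative precisions. Calibrate their scale with
    # the WLS residual dispersion of a pilot fit so the proxies live on the
    # response scale; tau2 is then profiled on top as usual. The mean-1
    # normalization makes everything invariant to global weight rescaling.
    wn <- w0 / mean(w0)
    wls_dispersion <- function(D) {
      Dw <- D * wn
      b <- solve(crossprod(D, Dw), crossprod(Dw, y))
      s2 <- sum(wn * drop(y - D %*% b)^2) / (k - ncol(D))
      if (s2 <= 0 || !is.finite(s2)) 1 else s2
    }
    v_eff <- wls_dispersion(X) / wn
  } else {
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("invalid variances: v must be positive", call. = FALSE)
    }
    v_eff <- v
  }

  tau2 <- estimate_tau2_reml(y, v_eff, X)
  w <- 1 / (v_eff + tau2)
  Xw <- X * w
  M <- crossprod(X, Xw)
  cov <- solve(M)
  beta <- drop(cov %*% crossprod(Xw, y))
  names(beta) <- term_info$term
  dimnames(cov) <- list(term_info$term, term_info$term)
  se <- sqrt(diag(cov))
  zval <- beta / se
  pval <- 2 * pnorm(-abs(zval))

  nonint <- setdiff(seq_len(p), which(term_info$term == "intercept"))
  if (length(nonint)) {
    b <- beta[nonint]
    qm <- drop(t(b) %*% solve(cov[nonint, nonint, drop = FALSE], b))
    omnibus_p <- pchisq(qm, df = length(nonint), lower.tail = FALSE)
    omnibus_df <- length(nonint)
  } else {
    qm <- NA_real_; omnibus_p <- NA_real_; omnibus_df <- 0L
  }

  if (p > 1L) {
    # heterogeneity left by the intercept-only model on the same rows; on the
    # weighted path the null model gets its own dispersion calibration so
    # that r2 compares like with like
    v_null <- if (is.null(weights_override)) v_eff else
      wls_dispersion(matrix(1, k, 1L)) / wn
    tau2_null <- estimate_tau2_reml(y, v_null)
  } else {
    tau2_null <- tau2
  }
  r2 <- if (tau2_null > 0) max(0, min(1, 1 - tau2 / tau2_null)) else 0

  structure(list(coefficients = beta, se = se, zval = zval, pval = pval,
                 cov = cov, tau2_resid = tau2, tau2_null = tau2_null,
                 r2 = r2, omnibus_stat = qm, omnibus_p = omnibus_p,
                 omnibus_df = omnibus_df, k = k,
                 term_info = term_info, term_labels = term_info$label,
                 xlevels = xlevels, xranges = xranges, outcome = outcome,
                 weighted = !is.null(weights_override)),
            class = "reg_fit")
}

#' @export
print.reg_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects meta-regression (k = %d, residual tau2 = %.*f)\n",
              x$k, digits, x$tau2_resid))
  if (!is.na(x$omnibus_p)) {
    cat(sprintf("  omnibus Wald chi2(%d) = %.*f, p = %.4g; R2 = %.1f%%\n",
                x$omnibus_df, digits, x$omnibus_stat, x$omnibus_p, 100 * x$r2))
  }
  tab <- data.frame(term = x$term_labels,
                    beta = round(x$coefficients, digits),
                    se = round(x$se, digits),
                    z = round(x$zval, 2),
                    p = signif(x$pval, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Post-hoc pairwise Wald contrasts for a categorical moderator
#'
#' For every unordered pair of levels (a, b) of the moderator, tests
#' `beta_a - beta_b = 0` (the reference level has coefficient 0) using the
#' fitted coefficient covariance: `z = estimate / se`, two-sided normal p.
#' No multiplicity adjustment is applied by default, matching the reporting
#' convention of unadjusted post-hoc p-values; `p_adjust_method` enables one.
#'
#' @param fit a `reg_fit` whose design included `moderator`.
#' @param moderator a categorical moderator present in the fit.
#' @param p_adjust_method passed to [stats::p.adjust()]; default `"none"`.
#' @return Data frame of class `contrast_results` with columns `label`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
pairwise_category_tests <- function(fit, moderator, p_adjust_method = "none") {
  stopifnot(inherits(fit, "reg_fit"))
  lev <- fit$xlevels[[moderator]]
  if (is.null(lev)) {
    stop("configuration error: moderator '", moderator,
         "' is not part of this fit", call. = FALSE)
  }
  if (length(lev) < 2L) {
    stop("moderator '", moderator, "' has fewer than 2 levels", call. = FALSE)
  }
  terms <- names(fit$coefficients)
  term_of <- function(l) paste0(moderator, ":", l)
  pairs <- utils::combn(lev, 2L)
  out <- data.frame(label = character(), estimate = numeric(), se = numeric(),
                    z = numeric(), p = numeric(), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    cvec <- setNames(numeric(length(terms)), terms)
    if (term_of(a) %in% terms) cvec[term_of(a)] <- 1
    if (term_of(b) %in% terms) cvec[term_of(b)] <- -1
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$cov %*% cvec))
    z <- est / se
    out <- rbind(out, data.frame(
      label = paste(a, "vs", b), estimate = est, se = se, z = z,
      p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE))
  }
  out$p <- stats::p.adjust(out$p, method = p_adjust_method)
  rownames(out) <- NULL
  class(out) <- c("contrast_results", "data.frame")
  out
}

#' Univariable meta-regression battery
#'
#' Fits one random-effects meta-regression per moderator on that moderator's
#' available rows, reports per-category pooled means with 95% CI (subgroup
#' random-effects pooling), and post-hoc pairwise contrasts for categorical
#' moderators with more than two levels. Moderators with a single observed
#' level are skipped with a warning.
#'
#' @param ds an `mi_dataset` (or effects table from [effects_from_arms()]).
#' @param outcome outcome to analyse when `ds` is an `mi_dataset`.
#' @param moderators moderator names; defaults to the full analysed set.
#' @param reference_levels optional overrides of [default_reference_levels()].
#' @return Object of class `univariable_battery`: a named list, one element
#'   per fitted moderator, each holding `fit` (a `reg_fit`), `subgroups`
#'   (per-level pooled means, categorical only) and `contrasts`.
#'   `as.data.frame()` flattens it into a report table.
#' @export
fit_univariable_battery <- function(ds, outcome = NULL,
                                    moderators = default_design_spec()$moderators,
                                    reference_levels = character()) {
  effects <- if (inherits(ds, "mi_dataset")) {
    effects_from_arms(ds, outcome)
  } else ds
  out <- list()
  for (m in moderators) {
    spec_m <- design_spec(m, reference_levels = reference_levels)
    avail <- effects[!is.na(effects[[m]]), , drop = FALSE]
    if (nrow(avail) < 3L) {
      warning("moderator '", m, "': fewer than 3 rows with data; skipped",
              call. = FALSE)
      next
    }
    n_lev <- if (is_categorical(m)) {
      length(unique(moderator_as_level(avail[[m]])))
    } else length(unique(avail[[m]]))
    if (n_lev < 2L) {
      warning("moderator '", m, "' has a single level; skipped",
              call. = FALSE)
      next
    }
    design <- build_design_matrix(avail, spec_m)
    fit <- fit_meta_regression(X = design, outcome = outcome)
    subgroups <- NULL
    contrasts <- NULL
    if (is_categorical(m)) {
      lev <- fit$xlevels[[m]]
      subgroups <- do.call(rbind, lapply(lev, function(l) {
        idx <- moderator_as_level(design$data[[m]]) == l
        pf <- pool_random_effects(design$data$yi[idx], design$data$vi[idx])
        data.frame(level = l, k = pf$k, mean = pf$mu,
                   ci_low = pf$ci_low, ci_high = pf$ci_high,
                   stringsAsFactors = FALSE)
      }))
      contrasts <- pairwise_category_tests(fit, m)
    }
    out[[m]] <- list(fit = fit, subgroups = subgroups, contrasts = contrasts)
  }
  structure(out, class = "univariable_battery", outcome = outcome)
}

#' @export
as.data.frame.univariable_battery <- function(x, ...) {
  rows <- lapply(names(x), function(m) {
    e <- x[[m]]
    if (!is.null(e$subgroups)) {
      data.frame(variable = m, category = e$subgroups$level,
                 n = e$subgroups$k, mean = e$subgroups$mean,
                 ci_low = e$subgroups$ci_low, ci_high = e$subgroups$ci_high,
                 p = e$fit$omnibus_p, stringsAsFactors = FALSE)
    } else {
      beta <- e$fit$coefficients[2L]
      data.frame(variable = m, category = NA_character_, n = e$fit$k,
                 mean = beta, ci_low = beta - Z_CRIT * e$fit$se[2L],
                 ci_high = beta + Z_CRIT * e$fit$se[2L],
                 p = e$fit$omnibus_p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable meta-regression with separately added moderators
#'
#' One joint complete-case fit over all moderators not listed in
#' `spec$add_separately`; each `add_separately` moderator (typically ischemia
#' duration, weight, age — sparsely reported) is then refitted as the joint
#' model plus that single term on its complete-case subset.
#'
#' @inheritParams fit_univariable_battery
#' @param spec a [design_spec()]; defaults to [default_design_spec()].
#' @return List of class `multivariable_fit` with `joint` (a `reg_fit`) and
#'   `separate` (named list of `reg_fit`, possibly empty).
#' @export
fit_multivariable <- function(ds, outcome = NULL,
                              spec = default_design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  effects <- if (inherits(ds, "mi_dataset")) {
    effects_from_arms(ds, outcome)
  } else ds
  joint_spec <- design_spec(setdiff(spec$moderators, spec$add_separately),
                            reference_levels = spec$reference_levels)
  joint <- fit_meta_regression(X = build_design_matrix(effects, joint_spec),
                               outcome = outcome)
  separate <- list()
  for (m in spec$add_separately) {
    sub <- effects[!is.na(effects[[m]]), , drop = FALSE]
    aug_spec <- design_spec(c(joint_spec$moderators, m),
                            reference_levels = spec$reference_levels)
    separate[[m]] <- tryCatch(
      fit_meta_regression(X = build_design_matrix(sub, aug_spec),
                          outcome = outcome),
      error = function(e) {
        warning("separate moderator '", m, "' could not be fitted: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  structure(list(joint = joint, separate = separate),
            class = "multivariable_fit", outcome = outcome)
}

#' Significance gate at alpha = 0.05
#'
#' `TRUE` iff `p < 0.05` (strict). The pipeline uses it to decide whether an
#' omnibus test licenses post-hoc contrast testing.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Logical of the same length.
#' @export
significance_gate <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  p < ALPHA_GATE
}

#' Full analysis pipeline for one outcome
#'
#' Runs the univariable battery and the multivariable fit, then post-hoc
#' pairwise contrasts on the joint model — but only when the multivariable
#' omnibus test passes the [significance_gate()]; otherwise post-hoc testing
#' is skipped and recorded as such.
#'
#' @inheritParams fit_multivariable
#' @return List of class `outcome_analysis` with `univariable`,
#'   `multivariable`, `posthoc` (named list of contrast tables, or `NULL`)
#'   and `posthoc_skipped`.
#' @export
analyze_outcome <- function(ds, outcome = NULL,
                            spec = default_design_spec()) {
  uni <- fit_univariable_battery(ds, outcome, spec$moderators,
                                 spec$reference_levels)
  multi <- fit_multivariable(ds, outcome, spec)
  gate_open <- significance_gate(multi$joint$omnibus_p)
  posthoc <- NULL
  if (gate_open) {
    cats <- names(multi$joint$xlevels)
    cats <- cats[vapply(multi$joint$xlevels, length, 0L) >= 2L]
    posthoc <- lapply(setNames(cats, cats), function(m) {
      pairwise_category_tests(multi$joint, m)
    })
  }
  structure(list(univariable = uni, multivariable = multi,
                 posthoc = posthoc, posthoc_skipped = !gate_open),
            class = "outcome_analysis", outcome = outcome)
}
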