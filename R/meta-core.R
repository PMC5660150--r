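# Random-effects meta-analysis of raw-mean outcomes.
#
# Model: y_i = mu + u_i + e_i with u_i ~ N(0, tau2) and e_i ~ N(0, v_i),
# v_i = sd_i^2 / n_i known. tau2 is estimated by restricted maximum
# likelihood; inference on mu is z-based.

# Restricted log-likelihood of tau2, profiled over the fixed effects, for an
# arbitrary design matrix X (intercept-only pooling is X = 1). Constant terms
# are dropped.
reml_loglik <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  Xw <- X * w
  M <- crossprod(X, Xw)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xw, y)))
  resid <- y - X %*% beta
  ld <- 2 * sum(log(diag(R)))
  -0.5 * (sum(log(v + tau2)) + ld + sum(w * resid^2))
}

#' REML estimate of between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model over
#' tau-squared by bounded derivative-free scalar optimization on
#' \[0, `tau2_max`\], followed by a local refinement pass, with the boundary
#' value tau2 = 0 checked explicitly. Works for the intercept-only model
#' (plain pooling) and, via `X`, for any meta-regression design.
#'
#' @param yi effect estimates (raw means, percent).
#' @param vi sampling variances (points squared); all must be nonnegative and
#'   at least one positive.
#' @param X optional design matrix (defaults to a single intercept column).
#' @param tau2_max upper bound of the search interval, in points squared.
#' @param tol convergence tolerance on tau2.
#' @return The nonnegative REML estimate of tau2 (points squared).
#' @examples
#' estimate_tau2_reml(c(0, 2), c(1, 1))   # 1
#' @export
estimate_tau2_reml <- function(yi, vi, X = NULL, tau2_max = 1e4, tol = 1e-8) {
  yi <- as.numeric(yi); vi <- as.numeric(vi)
  k <- length(yi)
  if (k < 2L) stop("insufficient data: REML needs at least 2 studies",
                   call. = FALSE)
  if (length(vi) != k) stop("yi and vi must have equal length", call. = FALSE)
  if (any(is.na(yi)) || any(is.na(vi)) || any(vi < 0)) {
    stop("yi/vi must be non-missing with vi >= 0", call. = FALSE)
  }
  if (all(vi == 0)) stop("invalid variances: all sampling variances are 0",
                         call. = FALSE)
  if (is.null(X)) X <- matrix(1, k, 1L)
  X <- as.matrix(X)
  if (nrow(X) != k) stop("X must have one row per study", call. = FALSE)
  if (k <= ncol(X)) {
    stop("insufficient data: need more studies than fixed-effect terms",
         call. = FALSE)
  }
  # Stationarity condition dl/dtau2 = 0, i.e. tr(P) = y'P'Py with
  # P = W - WX(X'WX)^-1 X'W. Root-finding on the analytic score converges
  # far beyond what scalar maximization can deliver, which matters for
  # reparameterization invariance of downstream contrasts.
  score <- function(tau2) reml_score(tau2, yi, vi, X)
  s0 <- score(0)
  if (is.na(s0) || s0 <= 0) return(0)   # boundary maximum
  hi <- 1
  while (hi < tau2_max && score(hi) > 0) hi <- hi * 4
  if (score(hi) > 0) return(min(hi, tau2_max))  # increasing up to the cap
  root <- tryCatch(
    stats::uniroot(score, c(0, hi), tol = min(tol, 1e-10),
                   maxiter = 200)$root,
    error = function(e) NA_real_)
  if (is.na(root)) {
    opt <- optimize(reml_loglik, c(0, tau2_max), y = yi, v = vi, X = X,
                    maximum = TRUE, tol = tol)
    root <- if (reml_loglik(0, yi, vi, X) >= opt$objective) 0 else opt$maximum
  }
  max(root, 0)
}

# d/dtau2 of the restricted log-likelihood: -0.5 * (tr(P) - ||P y||^2)
reml_score <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  Xw <- X * w
  M <- crossprod(X, Xw)
  A <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(A)) return(NA_real_)
  beta <- A %*% crossprod(Xw, y)
  r <- drop(y - X %*% beta)
  trP <- sum(w) - sum(A * crossprod(Xw, Xw))
  -0.5 * (trP - sum((w * r)^2))
}

#' Cochran's Q and I-squared
#'
#' Q is the weighted sum of squared deviations of the effects from the
#' fixed-effect (inverse-variance) mean; I-squared is the fraction of total
#' variability attributable to between-study heterogeneity,
#' `max(0, (Q - (k - 1)) / Q)`.
#'
#' @inheritParams estimate_tau2_reml
#' @return List with elements `q_stat` and `i2` (a fraction in \[0, 1)).
#' @examples
#' heterogeneity_stats(c(0, 2), c(1, 1))  # Q = 2, I2 = 0.5
#' @export
heterogeneity_stats <- function(yi, vi) {
  k <- length(yi)
  if (k < 2L) stop("insufficient data: heterogeneity needs k >= 2",
                   call. = FALSE)
  if (any(vi <= 0)) stop("invalid variances: vi must be > 0", call. = FALSE)
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fe)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(q_stat = q, i2 = i2)
}

#' Random-effects pooling of raw-mean outcomes
#'
#' Pools study-level means under the random-effects model with REML
#' tau-squared: `mu = sum(w * y) / sum(w)` with `w = 1 / (v + tau2)`,
#' `se = 1 / sqrt(sum(w))`, and a 95% z-based confidence interval. A single
#' study is returned as-is (tau2 = 0) with a degenerate-fit flag so that
#' subset analyses shrinking to one study do not error.
#'
#' @inheritParams estimate_tau2_reml
#' @param labels optional study labels for the forest table.
#' @param tau2 optional fixed tau2; estimated by REML when `NULL`.
#' @return An object of class `meta_fit`: list with `mu`, `se`, `ci_low`,
#'   `ci_high`, `tau2`, `q_stat`, `i2`, `k`, `degenerate`, and the inputs
#'   (`yi`, `vi`, `labels`).
#' @examples
#' fit <- pool_random_effects(c(45, 52, 61), c(4, 6, 9))
#' fit$mu
#' @export
pool_random_effects <- function(yi, vi, labels = NULL, tau2 = NULL) {
  yi <- as.numeric(yi); vi <- as.numeric(vi)
  k <- length(yi)
  if (k == 0L) stop("insufficient data: no studies to pool", call. = FALSE)
  if (length(vi) != k) stop("yi and vi must have equal length", call. = FALSE)
  if (is.null(labels)) labels <- paste("study", seq_len(k))
  if (k == 1L) {
    se <- sqrt(vi)
    fit <- list(mu = yi, se = se,
                ci_low = yi - Z_CRIT * se, ci_high = yi + Z_CRIT * se,
                tau2 = 0, q_stat = 0, i2 = 0, k = 1L, degenerate = TRUE,
                yi = yi, vi = vi, labels = labels)
    return(structure(fit, class = "meta_fit"))
  }
  if (is.null(tau2)) tau2 <- estimate_tau2_reml(yi, vi)
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- heterogeneity_stats(yi, vi)
  structure(list(mu = mu, se = se,
                 ci_low = mu - Z_CRIT * se, ci_high = mu + Z_CRIT * se,
                 tau2 = tau2, q_stat = het$q_stat, i2 = het$i2, k = k,
                 degenerate = FALSE, yi = yi, vi = vi, labels = labels),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Random-effects pooled estimate (k = %d%s)\n", x$k,
              if (x$degenerate) ", degenerate single-study fit" else ""))
  cat(sprintf("  mu = %.*f%% (95%% CI %.*f to %.*f), SE = %.*f\n",
              digits, x$mu, digits, x$ci_low, digits, x$ci_high, digits, x$se))
  cat(sprintf("  tau2 = %.*f, Q = %.*f, I2 = %.1f%%\n",
              digits, x$tau2, digits, x$q_stat, 100 * x$i2))
  invisible(x)
}

#' Forest table of study estimates and the pooled summary
#'
#' One row per study with its estimate and 95% CI (`yi +/- 1.959964 sqrt(vi)`)
#' followed by a summary row carrying the pooled random-effects result.
#'
#' @param fit a `meta_fit` from [pool_random_effects()].
#' @return Data frame with columns `label`, `estimate`, `ci_low`, `ci_high`,
#'   `weight_pct` (random-effects weights, summing to 100 over the studies)
#'   and `type` (`"study"` / `"summary"`).
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  half <- Z_CRIT * sqrt(fit$vi)
  w <- 1 / (fit$vi + fit$tau2)
  rows <- data.frame(
    label = c(fit$labels, "RE summary"),
    estimate = c(fit$yi, fit$mu),
    ci_low = c(fit$yi - half, fit$ci_low),
    ci_high = c(fit$yi + half, fit$ci_high),
    weight_pct = c(100 * w / sum(w), 100),
    type = c(rep("study", fit$k), "summary"),
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  rows
}

#' Forest plot of a pooled fit
#'
#' Base-graphics forest plot: squares for study estimates with 95% CI
#' whiskers, a diamond for the pooled summary.
#'
#' @param fit a `meta_fit`.
#' @param xlab x-axis label.
#' @param main plot title.
#' @return The [forest_table()] used, invisibly.
#' @export
forest_plot <- function(fit, xlab = "Outcome (%)", main = "") {
  tab <- forest_table(fit)
  n <- nrow(tab)
  ys <- rev(seq_len(n))
  op <- par(mar = c(4, 10, if (nzchar(main)) 3 else 1, 2))
  on.exit(par(op))
  plot(NA, xlim = range(tab$ci_low, tab$ci_high), ylim = c(0.5, n + 0.5),
       yaxt = "n", ylab = "", xlab = xlab, main = main, bty = "n")
  axis(2, at = ys, labels = tab$label, las = 1, tick = FALSE, cex.axis = 0.8)
  st <- tab$type == "study"
  segments(tab$ci_low[st], ys[st], tab$ci_high[st], ys[st])
  points(tab$estimate[st], ys[st], pch = 15,
         cex = 0.5 + 1.5 * tab$weight_pct[st] / max(tab$weight_pct[st]))
  sm <- which(!st)
  polygon(c(tab$ci_low[sm], tab$estimate[sm], tab$ci_high[sm], tab$estimate[sm]),
          ys[sm] + c(0, 0.35, 0, -0.35), col = "grey40", border = NA)
  abline(v = tab$estimate[sm], lty = 3)
  invisible(tab)
}
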