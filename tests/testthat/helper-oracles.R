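# Independent oracles, deliberately naive: a dense grid search of the
# restricted log-likelihood for tau2, a from-first-principles weighted
# least-squares solver, and the DerSimonian-Laird moment estimator. These
# never call into the package's optimization path.

# restricted log-likelihood of the intercept-only model, vectorized over a
# tau2 grid (k x G matrices)
grid_reml_tau2 <- function(y, v, upper = 10, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  V <- outer(v, grid, "+")          # k x G
  W <- 1 / V
  mu <- colSums(W * y) / colSums(W)
  R <- sweep(W * 0 + y, 2, mu)      # y - mu per column
  ll <- -0.5 * (colSums(log(V)) + log(colSums(W)) +
                  colSums(W * R^2))
  grid[which.max(ll)]
}

# same, for an arbitrary design matrix (loop over grid; small instances only)
grid_reml_tau2_X <- function(y, v, X, upper = 50, step = 1e-3) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    Xw <- X * w
    M <- crossprod(X, Xw)
    beta <- solve(M, crossprod(Xw, y))
    r <- drop(y - X %*% beta)
    -0.5 * (sum(log(v + t2)) + determinant(M)$modulus + sum(w * r^2))
  }, 0)
  grid[which.max(ll)]
}

# brute-force WLS at a given tau2
wls_oracle <- function(y, v, X, tau2) {
  W <- diag(1 / (v + tau2))
  M <- t(X) %*% W %*% X
  beta <- solve(M) %*% t(X) %*% W %*% y
  list(beta = drop(beta), cov = solve(M))
}

# DerSimonian-Laird moment estimator (sanity cross-check only)
dl_tau2 <- function(y, v) {
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  max(0, (q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# small hand-built arms table satisfying every invariant
make_arms_fixture <- function(n = 3) {
  k <- n
  data.frame(
    study_id = sprintf("F%02d", seq_len(k)),
    outcome = "IS_AAR",
    mean = seq(40, 60, length.out = k),
    sd = rep(8, k),
    n_animals = rep(6L, k),
    species = rep_len(c("dog", "pig", "sheep"), k),
    strain = rep_len(c("not_applicable", "regular_pig", "not_applicable"), k),
    sex = rep_len(c("male", "female", "both"), k),
    occlusion = rep_len(c("temporary", "permanent", "temporary"), k),
    vessel = rep_len(c("LAD", "LCX", "LAD"), k),
    approach = rep_len(c("open", "closed", "open"), k),
    comedication = rep_len(c(FALSE, TRUE), k),
    immunosuppression = FALSE,
    quantification = "TTC",
    follow_up_hours = rep_len(c(24, 168, 672), k),
    ischemia_minutes = ifelse(rep_len(c(TRUE, FALSE, TRUE), k), 60, NA),
    quality_score = rep_len(4:6, k),
    weight_kg = rep_len(c(25, 60, NA), k),
    age_weeks = NA_real_,
    vf_excluded_untreated = rep_len(c(FALSE, FALSE, TRUE), k),
    stringsAsFactors = FALSE)
}

make_mortality_fixture <- function(n = 4) {
  m <- make_arms_fixture(n)
  data.frame(
    study_id = m$study_id,
    phase = "peri",
    deaths = rep_len(c(1L, 2L, 0L, 3L), n),
    total = rep_len(c(10L, 12L, 8L, 20L), n),
    deaths2 = rep_len(c(NA, 1L, NA, NA), n),
    total2 = rep_len(c(NA, 10L, NA, NA), n),
    m[, setdiff(names(m), c("study_id", "outcome", "mean", "sd", "n_animals"))],
    stringsAsFactors = FALSE)
}

# a reg_fit with fully known coefficients, for prediction oracles
make_known_fit <- function(outcome = "IS_AAR",
                           intercept = 40, b_pig = 21.6, b_fu = -0.03,
                           fu_range = c(24, 400)) {
  info <- data.frame(
    term = c("intercept", "species:pig", "follow_up_hours"),
    label = c("intercept", "pig (vs dog)", "follow_up_hours (/hour)"),
    moderator = c(NA, "species", "follow_up_hours"),
    level = c(NA, "pig", NA),
    type = c("intercept", "categorical", "continuous"),
    stringsAsFactors = FALSE)
  beta <- c(intercept = intercept, `species:pig` = b_pig,
            follow_up_hours = b_fu)
  names(beta) <- info$term
  cov <- diag(c(4, 1, 1e-6))
  dimnames(cov) <- list(info$term, info$term)
  structure(list(coefficients = beta, se = sqrt(diag(cov)),
                 zval = beta / sqrt(diag(cov)),
                 pval = 2 * pnorm(-abs(beta / sqrt(diag(cov)))),
                 cov = cov, tau2_resid = 25, tau2_null = 50, r2 = 0.5,
                 omnibus_stat = 10, omnibus_p = 0.001, omnibus_df = 2L,
                 k = 100L, term_info = info, term_labels = info$label,
                 xlevels = list(species = c("dog", "pig")),
                 xranges = list(follow_up_hours = fu_range),
                 outcome = outcome, weighted = FALSE),
            class = "reg_fit")
}
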