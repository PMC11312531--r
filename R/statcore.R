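# Shared statistical primitives. Everything downstream (factorial models,
# post-hocs, classifier comparisons, similarity models) reports through these
# so that coefficient tables, CIs and p-values have one consistent layout.

#' Ordinary least squares with a rank-revealing fit
#'
#' Fits `y ~ X` by QR with column pivoting (via [stats::lm]); aliased columns
#' are dropped deterministically, keeping the first of each collinear set.
#'
#' @param X numeric matrix or data.frame of predictors (no intercept column;
#'   one is added), or a formula.
#' @param y numeric response (ignored when `X` is a formula).
#' @param data data.frame used when `X` is a formula.
#' @return object of class `vtcwm_fit`: list with `coefficients` table
#'   (estimate, se, t, p, ci_lo, ci_hi), `residual_df`, `adj_r_squared`,
#'   `log_lik`, `n`, and the underlying `lm` object.
#' @export
ols_fit <- function(X, y = NULL, data = NULL) {
  if (inherits(X, "formula")) {
    fit <- lm(X, data = data)
  } else {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == length(y))
    dat <- cbind(.y = y, X)
    fit <- lm(.y ~ ., data = dat)
  }
  as_vtcwm_fit(fit)
}

#' Summarize an lm/glm into the package's coefficient-table layout
#' @param fit an `lm` or `glm` object.
#' @return `vtcwm_fit` list; see [ols_fit()].
#' @export
as_vtcwm_fit <- function(fit) {
  sm <- summary(fit)
  tab <- coef(sm)
  kept <- rownames(tab)
  df <- if (inherits(fit, "glm")) Inf else fit$df.residual
  crit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  coefs <- data.frame(
    term = kept,
    estimate = tab[, 1], se = tab[, 2], statistic = tab[, 3], p = tab[, 4],
    ci_lo = tab[, 1] - crit * tab[, 2], ci_hi = tab[, 1] + crit * tab[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    residual_df = fit$df.residual,
    adj_r_squared = if (!inherits(fit, "glm")) sm$adj.r.squared else NA_real_,
    log_lik = as.numeric(logLik(fit)),
    n = length(fit$residuals),
    dropped = names(coef(fit))[is.na(coef(fit))],
    lm = fit
  ), class = "vtcwm_fit")
}

#' @exportS3Method
print.vtcwm_fit <- function(x, ...) {
  cat("Linear model fit: n =", x$n, ", residual df =", x$residual_df, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Sequential (type-I) ANOVA with effect sizes
#'
#' Decomposes a fitted linear model into sequential sums of squares in the
#' model's term order and adds eta-squared (`SS_effect / SS_total`).
#'
#' @param fit a `vtcwm_fit` (from [ols_fit()]) or an `lm` object.
#' @return data.frame: term, df, sum_sq, F, p, eta_sq (residual row last).
#' @export
sequential_anova <- function(fit) {
  if (inherits(fit, "vtcwm_fit")) fit <- fit$lm
  a <- anova(fit)
  ss_total <- sum(a[, "Sum Sq"])
  out <- data.frame(
    term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
    F = a$`F value`, p = a$`Pr(>F)`,
    eta_sq = a$`Sum Sq` / ss_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' One-sample and paired t tests with Cohen's d
#'
#' @param x numeric vector (differences already taken for `paired = FALSE`
#'   against `mu`, or first member of each pair).
#' @param y optional second member of each pair (paired test on `x - y`).
#' @param mu null value for the one-sample test.
#' @return list: estimate (mean), t, df, p, ci (95%), cohens_d, sd. If the
#'   sample SD is zero the t statistic is 0 when the mean equals `mu` and a
#'   `degenerate` flag is set.
#' @export
t_test_d <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[is.finite(d)]
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (isTRUE(all.equal(s, 0)) || n < 2) {
    # zero-SD sentinel: identical values are either exactly at the null
    # (t = 0, p = 1) or deterministically away from it (t = +/-Inf, p = 0)
    at_null <- isTRUE(all.equal(m, mu)) || n < 2
    return(list(estimate = m,
                t = if (at_null) 0 else sign(m - mu) * Inf,
                df = n - 1, p = if (at_null) 1 else 0, ci = c(m, m),
                cohens_d = NA_real_, sd = s, n = n, degenerate = TRUE))
  }
  tt <- t.test(d, mu = mu)
  list(estimate = m, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(tt$conf.int),
       cohens_d = (m - mu) / s, sd = s, n = n, degenerate = FALSE)
}

#' Binomial logistic regression with odds ratios
#'
#' @param y 0/1 outcome vector.
#' @param group factor-like predictor (e.g. classification task).
#' @return list: `fit` (`vtcwm_fit` on the logit scale) and `odds_ratios`
#'   data.frame (term, or, ci_lo, ci_hi, p) from Wald intervals.
#' @export
binomial_logit <- function(y, group) {
  stopifnot(all(y %in% c(0, 1)))
  group <- factor(group)
  fit <- glm(y ~ group, family = binomial())
  vf <- as_vtcwm_fit(fit)
  tab <- vf$coefficients[-1, , drop = FALSE]
  ors <- data.frame(
    term = sub("^group", "", tab$term),
    or = exp(tab$estimate),
    ci_lo = exp(tab$estimate - qnorm(0.975) * tab$se),
    ci_hi = exp(tab$estimate + qnorm(0.975) * tab$se),
    p = tab$p, stringsAsFactors = FALSE
  )
  list(fit = vf, odds_ratios = ors)
}

#' Fisher z transform and inverse
#'
#' `fisher_z` is atanh with |r| clipped at `1 - eps` so boundary correlations
#' stay finite; `fisher_z_inv` is tanh.
#'
#' @param r correlations in \[-1, 1\].
#' @param eps clip margin.
#' @export
fisher_z <- function(r, eps = 1e-12) {
  atanh(pmax(pmin(r, 1 - eps), -1 + eps))
}

#' @rdname fisher_z
#' @param z Fisher-z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Bonferroni adjustment
#'
#' @param p p-values; @param m number of comparisons (default `length(p)`).
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(p * m, 1)
}
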