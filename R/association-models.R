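# Bivariate group comparisons, binary logistic regression with forward
# selection, calibration and pseudo-R2, and Pearson correlations: the
# association layer that complements the discrimination (ROC/CV) layer.
# Standard tests and the IRLS fit are delegated to stats::t.test,
# wilcox.test, chisq.test, fisher.test and glm(binomial); the normality
# screen uses the Kolmogorov-Smirnov test with estimated parameters
# (Lilliefors correction) from nortest.

#' Compare a variable between SBT outcome groups
#'
#' Continuous variables are screened for normality per group (Lilliefors /
#' Kolmogorov-Smirnov at alpha = 0.05); if both groups pass, Student's
#' t-test is used, otherwise the Mann-Whitney U-test. Categorical variables
#' use the chi-square test, falling back to Fisher's exact test when any
#' expected cell count is below 5. All p-values are two-sided.
#'
#' @param values Variable values (numeric, or logical/factor for
#'   categorical).
#' @param groups Two-level group labels.
#' @param kind "continuous" or "categorical".
#' @return A list of class `comparison_result`: `test` used, `statistic`,
#'   `p_value`, per-group summaries.
#' @export
compare_groups <- function(values, groups,
                           kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  g <- unique(groups)
  if (length(g) != 2) stop("exactly two groups required")
  x <- values[groups == g[1]]
  y <- values[groups == g[2]]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (kind == "continuous") {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    normal <- function(v) {
      if (length(v) < 5 || stats::sd(v) == 0) return(FALSE)
      nortest::lillie.test(v)$p.value > 0.05
    }
    if (normal(x) && normal(y)) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      test <- "t"
    } else {
      ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      test <- "mann-whitney"
    }
    summ <- list(mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
                 median = c(stats::median(x), stats::median(y)))
  } else {
    tab <- table(factor(groups), factor(values))
    if (any(dim(tab) < 2)) stop("constant variable: cannot test association")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- stats::fisher.test(tab)
      test <- "fisher"
    } else {
      ht <- stats::chisq.test(tab, correct = FALSE)
      test <- "chi-square"
    }
    summ <- list(table = tab)
  }
  structure(list(
    test = test,
    statistic = if (!is.null(ht$statistic)) unname(ht$statistic) else NA_real_,
    p_value = ht$p.value,
    groups = g,
    summary = summ
  ), class = "comparison_result")
}

#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) of a
#' binary SBT outcome on a set of covariates, reporting per-covariate odds
#' ratios on a caller-chosen unit scale with Wald 95% confidence intervals
#' and p-values, the log-likelihoods, Nagelkerke's R2, and the
#' Hosmer-Lemeshow calibration test. Non-convergence and (quasi-)complete
#' separation raise explicit errors rather than returning a silently
#' unstable fit.
#'
#' @param data Data frame of covariates.
#' @param outcome 0/1 outcome vector (1 = SBT failure).
#' @param covariates Character vector of column names to include
#'   (default: all columns of `data`).
#' @param unit_scale Named numeric vector: odds ratios are reported per
#'   `unit_scale[v]` units of covariate `v` (default 1 for all), e.g.
#'   `c(pi_1 = 1000)` for an OR per 1000 cmH2O^2/min.
#' @param hl_groups Bins for the Hosmer-Lemeshow test (default 10).
#' @return A list of class `logistic_fit`.
#' @export
fit_logistic <- function(data, outcome, covariates = names(data),
                         unit_scale = NULL, hl_groups = 10) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(outcome) <= length(covariates) + 1) {
    stop("need more observations than parameters")
  }
  df <- data[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
    if (is.numeric(df[[v]]) && stats::sd(df[[v]]) == 0) {
      stop("constant covariate: ", v)
    }
  }
  df$.y <- outcome
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- stats::coef(fit)
  # under (quasi-)complete separation the deviance collapses to zero while
  # the coefficients diverge; a merely strong predictor keeps a positive
  # deviance from its misclassified observations
  if (sep_warn && fit$deviance < 1e-4) {
    stop("complete or quasi-complete separation detected; ",
         "coefficients diverge")
  }
  if (!fit$converged) stop("logistic regression did not converge in 50 IRLS iterations")
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  z <- stats::qnorm(0.975)
  terms <- names(coefs)[-1]
  scale_of <- function(v) {
    if (!is.null(unit_scale) && v %in% names(unit_scale)) unit_scale[[v]] else 1
  }
  or_tab <- do.call(rbind, lapply(terms, function(v) {
    s <- scale_of(sub("TRUE$", "", v))
    b <- coefs[[v]] * s; sd_b <- se[[v]] * s
    data.frame(term = v, coef = coefs[[v]], se = se[[v]], unit = s,
               or = exp(b), or_lo = exp(b - z * sd_b), or_hi = exp(b + z * sd_b),
               p = sm$coefficients[v, "Pr(>|z|)"], stringsAsFactors = FALSE)
  }))
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(.y ~ 1, data = df, family = stats::binomial())))
  res <- structure(list(
    glm = fit,
    coefficients = coefs, se = se, odds_ratios = or_tab,
    log_lik = ll, null_log_lik = ll0,
    n = length(outcome),
    converged = fit$converged, iterations = fit$iter
  ), class = "logistic_fit")
  res$nagelkerke_r2 <- nagelkerke_r2(res)
  res$hosmer_lemeshow <- if (length(terms) > 0 && length(outcome) >= 2 * hl_groups)
    hosmer_lemeshow(res, groups = hl_groups) else NULL
  res
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression: n = %d, logLik %.2f (null %.2f), R2_N %.3f\n",
              x$n, x$log_lik, x$null_log_lik, x$nagelkerke_r2))
  if (!is.null(x$odds_ratios) && nrow(x$odds_ratios)) {
    tab <- x$odds_ratios
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s: OR %.3f (%.3f-%.3f) per %g unit(s), p = %.3g\n",
                  tab$term[i], tab$or[i], tab$or_lo[i], tab$or_hi[i],
                  tab$unit[i], tab$p[i]))
    }
  }
  if (!is.null(x$hosmer_lemeshow)) {
    hl <- x$hosmer_lemeshow
    cat(sprintf("  Hosmer-Lemeshow chi2 %.2f, df %d, p = %.3f\n",
                hl$statistic, hl$df, hl$p_value))
  }
  invisible(x)
}

#' Nagelkerke's R-squared
#'
#' Cox-Snell R2 rescaled by its attainable maximum; 0 for the
#' intercept-only model, approaching 1 for a near-perfect predictor.
#'
#' @param fit A `logistic_fit` (needs `log_lik`, `null_log_lik`, `n`).
#' @return R2 in [0, 1].
#' @export
nagelkerke_r2 <- function(fit) {
  cs <- 1 - exp(2 * (fit$null_log_lik - fit$log_lik) / fit$n)
  max_cs <- 1 - exp(2 * fit$null_log_lik / fit$n)
  if (max_cs <= 0) return(0)
  max(0, min(1, cs / max_cs))
}

#' Hosmer-Lemeshow calibration test
#'
#' Partitions patients into bins of fitted risk (deciles by default) and
#' compares observed with expected outcome counts via a chi-square
#' statistic on `groups - 2` degrees of freedom. When the model yields
#' fewer distinct fitted values than requested bins, bins are merged and
#' the degrees of freedom adjusted (with a warning).
#'
#' @param fit A `logistic_fit`.
#' @param groups Number of risk bins (default 10).
#' @return List with `statistic`, `df`, `p_value`, and the bin `table`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  p <- stats::fitted(fit$glm)
  y <- fit$glm$y
  if (length(y) < 2 * groups) stop("need at least 2 x groups observations")
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  if (length(breaks) - 1 < groups) {
    warning("fewer distinct risk levels than requested bins; bins merged, df adjusted")
  }
  if (length(breaks) - 1 < 3) stop("too few distinct risk bins (df would be <= 0)")
  bin <- cut(p, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(y, bin, sum)
  n_g <- tapply(y, bin, length)
  exp1 <- tapply(p, bin, sum)
  stat <- sum((obs1 - exp1)^2 / (exp1 * (1 - exp1 / n_g)))
  df <- length(levels(bin)) - 2
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(bin = levels(bin), n = as.vector(n_g),
                          observed = as.vector(obs1),
                          expected = as.vector(exp1)))
}

#' Forward selection for the multivariable logistic model
#'
#' Screens candidate covariates by their univariable association with the
#' outcome (entering the pool when p < `screen_p`), adds the a-priori
#' covariates unconditionally, then builds the model greedily: at each step
#' the candidate with the smallest likelihood-ratio p-value joins the model
#' if that p-value is below `entry_p`. Ties are broken alphabetically, so
#' selection is deterministic for a given input.
#'
#' @param data Data frame holding all covariates.
#' @param outcome 0/1 outcome vector.
#' @param candidates Character vector of candidate covariate names.
#' @param a_priori Covariates included in the pool regardless of screening
#'   (default none).
#' @param entry_p Likelihood-ratio entry threshold (default 0.05).
#' @param screen_p Univariable screening threshold (default 0.2).
#' @param unit_scale Passed to [fit_logistic()] for the final model.
#' @return A `logistic_fit` for the selected model (intercept-only if
#'   nothing enters), with attribute `selected` listing the covariates in
#'   order of entry and `screened` the post-screen pool.
#' @export
forward_select <- function(data, outcome, candidates,
                           a_priori = character(0),
                           entry_p = 0.05, screen_p = 0.2,
                           unit_scale = NULL) {
  uni_p <- vapply(candidates, function(v) {
    f <- fit_logistic(data, outcome, covariates = v)
    f$odds_ratios$p[1]
  }, numeric(1))
  pool <- sort(union(candidates[uni_p < screen_p], a_priori))
  selected <- character(0)
  ll_fit <- function(vars) {
    if (length(vars) == 0) {
      df <- data.frame(.y = outcome)
      f <- stats::glm(.y ~ 1, data = df, family = stats::binomial())
      return(as.numeric(stats::logLik(f)))
    }
    fit_logistic(data, outcome, covariates = vars)$log_lik
  }
  current_ll <- ll_fit(selected)
  repeat {
    remaining <- sort(setdiff(pool, selected))
    if (length(remaining) == 0) break
    lrt <- vapply(remaining, function(v) {
      ll1 <- ll_fit(c(selected, v))
      stats::pchisq(2 * (ll1 - current_ll), df = 1, lower.tail = FALSE)
    }, numeric(1))
    best <- remaining[which.min(lrt)] # ties resolved by alphabetical order
    if (min(lrt) >= entry_p) break
    selected <- c(selected, best)
    current_ll <- ll_fit(selected)
  }
  if (length(selected) == 0) {
    df <- data.frame(.y = outcome)
    g <- stats::glm(.y ~ 1, data = df, family = stats::binomial())
    ll0 <- as.numeric(stats::logLik(g))
    fit <- structure(list(glm = g, coefficients = stats::coef(g),
                          se = summary(g)$coefficients[, "Std. Error"],
                          odds_ratios = NULL, log_lik = ll0,
                          null_log_lik = ll0, n = length(outcome),
                          converged = g$converged, iterations = g$iter),
                     class = "logistic_fit")
    fit$nagelkerke_r2 <- nagelkerke_r2(fit)
  } else {
    fit <- fit_logistic(data, outcome, covariates = selected,
                        unit_scale = unit_scale)
  }
  attr(fit, "selected") <- selected
  attr(fit, "screened") <- pool
  fit
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 4, finite, non-constant).
#' @return List with `r`, `lo`, `hi`, `p_value`, `n`.
#' @export
pearson_with_ci <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), lo = ct$conf.int[1], hi = ct$conf.int[2],
       p_value = ct$p.value, n = length(x))
}
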