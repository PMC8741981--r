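test_that("group comparison picks the right test and matches reference p-values", {
  set.seed(12)
  x <- rnorm(50); y <- rnorm(50)
  groups <- rep(c("s", "f"), each = 50)
  cr <- compare_groups(c(x, y), groups, "continuous")
  expect_equal(cr$test, "t")
  expect_equal(cr$p_value, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  # heavy-tailed data routes to Mann-Whitney
  xs <- rcauchy(60); ys <- rcauchy(60) + 2
  cr2 <- compare_groups(c(xs, ys), rep(c("s", "f"), each = 60), "continuous")
  expect_equal(cr2$test, "mann-whitney")
  expect_equal(cr2$p_value,
               wilcox.test(xs, ys, exact = FALSE)$p.value, tolerance = 1e-10)
})

test_that("identical groups give non-significant p, well-separated groups tiny p", {
  set.seed(14)
  v <- rnorm(40)
  same <- compare_groups(c(v, v), rep(c("a", "b"), each = 40), "continuous")
  expect_gt(same$p_value, 0.9)
  shifted <- compare_groups(c(rnorm(50), rnorm(50) + 5),
                            rep(c("a", "b"), each = 50), "continuous")
  expect_lt(shifted$p_value, 1e-6)
})

test_that("categorical comparisons reproduce the COPD prevalence contrast", {
  copd <- c(rep(TRUE, 16), rep(FALSE, 84), rep(TRUE, 14), rep(FALSE, 16))
  groups <- rep(c("success", "failure"), c(100, 30))
  cr <- compare_groups(copd, groups, "categorical")
  expect_equal(cr$test, "chi-square")
  expect_lt(cr$p_value, 0.001)
  expect_equal(cr$p_value,
               chisq.test(table(groups, copd), correct = FALSE)$p.value,
               tolerance = 1e-10)
  # sparse table falls back to Fisher
  rare <- c(rep(TRUE, 2), rep(FALSE, 98), rep(TRUE, 3), rep(FALSE, 27))
  cr2 <- compare_groups(rare, groups, "categorical")
  expect_equal(cr2$test, "fisher")
  expect_error(compare_groups(rep(TRUE, 130), groups, "categorical"),
               "constant")
})

test_that("logistic fit satisfies the score equations and unit-scaling identity", {
  set.seed(16)
  n <- 400
  d <- data.frame(x = rnorm(n, 5000, 2000))
  y <- rbinom(n, 1, plogis(-3 + 0.0004 * d$x))
  f <- fit_logistic(d, y, "x", unit_scale = c(x = 1000))
  X <- cbind(1, d$x)
  expect_lt(max(abs(t(X) %*% (y - fitted(f$glm)))) /
              max(abs(t(X) %*% y)), 1e-8)
  expect_equal(f$odds_ratios$or, exp(f$odds_ratios$coef * 1000))
  # rescaling the covariate scales the coefficient, not the likelihood
  d2 <- data.frame(x = d$x / 1000)
  f2 <- fit_logistic(d2, y, "x")
  expect_equal(f2$coefficients[["x"]], f$coefficients[["x"]] * 1000,
               tolerance = 1e-6)
  expect_equal(f2$log_lik, f$log_lik, tolerance = 1e-9)
})

test_that("a null covariate's OR confidence interval behaves like a 95% interval", {
  set.seed(18)
  covered <- vapply(1:40, function(i) {
    d <- data.frame(x = rnorm(800))
    y <- rbinom(800, 1, 0.25)
    or <- fit_logistic(d, y, "x")$odds_ratios
    or$or_lo <= 1 && 1 <= or$or_hi
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("the true odds ratio of a simulated mechanism is recovered", {
  beta1 <- log(1.48) / 1000
  d <- generate_logistic_cohort(5000, beta0 = qlogis(0.23) - beta1 * 5696,
                                beta1 = beta1, mean = 5696, sd = 2884,
                                seed = 1)
  f <- fit_logistic(d, d$outcome, "index", unit_scale = c(index = 1000))
  or <- f$odds_ratios
  expect_gt(1.48, or$or_lo)
  expect_lt(1.48, or$or_hi)
  expect_equal(or$or, 1.48, tolerance = 0.08)
})

test_that("complete separation raises an explicit error", {
  d <- data.frame(x = 1:10)
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  expect_error(fit_logistic(d, y, "x"), "separation")
})

test_that("forward selection finds a single strong predictor among noise", {
  set.seed(20)
  hits <- vapply(1:10, function(i) {
    n <- 2000
    d <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                    strong = rnorm(n))
    y <- rbinom(n, 1, plogis(-1.2 + 1.1 * d$strong))
    sel <- attr(forward_select(d, y, names(d)), "selected")
    identical(sel, "strong")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("all-noise candidates mostly yield the intercept-only model", {
  set.seed(22)
  sizes <- vapply(1:20, function(i) {
    d <- data.frame(n1 = rnorm(300), n2 = rnorm(300))
    y <- rbinom(300, 1, 0.3)
    length(attr(forward_select(d, y, names(d)), "selected"))
  }, numeric(1))
  expect_gte(mean(sizes == 0), 0.7)
  # intercept-only fit reports zero pseudo-R2
  d <- data.frame(n1 = rnorm(200))
  y <- rbinom(200, 1, 0.3)
  f0 <- forward_select(d, y, character(0))
  expect_equal(f0$nagelkerke_r2, 0)
})

test_that("a-priori covariates always enter the candidate pool", {
  set.seed(24)
  d <- data.frame(noise = rnorm(500), forced = rnorm(500))
  y <- rbinom(500, 1, 0.3)
  f <- forward_select(d, y, candidates = "noise", a_priori = "forced")
  expect_true("forced" %in% attr(f, "screened"))
})

test_that("Nagelkerke R2 spans its range and matches a strong predictor", {
  set.seed(26)
  n <- 1000
  d <- data.frame(x = rnorm(n))
  y_strong <- rbinom(n, 1, plogis(5 * d$x))
  f <- fit_logistic(d, y_strong, "x")
  expect_gt(f$nagelkerke_r2, 0.6)
  expect_lte(f$nagelkerke_r2, 1)
  y_null <- rbinom(n, 1, 0.3)
  f0 <- fit_logistic(d, y_null, "x")
  expect_lt(f0$nagelkerke_r2, 0.05)
})

test_that("Hosmer-Lemeshow is calibrated for the true model and rejects misspecification", {
  set.seed(28)
  ps <- vapply(1:30, function(i) {
    d <- data.frame(x = rnorm(1000))
    y <- rbinom(1000, 1, plogis(-1 + 0.8 * d$x))
    fit_logistic(d, y, "x")$hosmer_lemeshow$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2) # roughly nominal rejection under truth
  expect_gt(mean(ps), 0.3)
  # quadratic truth fitted as linear is flagged
  d <- data.frame(x = rnorm(4000))
  y <- rbinom(4000, 1, plogis(-1.5 + 1.5 * d$x^2))
  f <- fit_logistic(d, y, "x")
  expect_lt(f$hosmer_lemeshow$p_value, 0.01)
  expect_error(hosmer_lemeshow(f, groups = 2), "df|bins|groups")
})

test_that("Pearson correlation with Fisher-z CI matches hand computation", {
  out <- pearson_with_ci(c(1, 2, 3, 4), c(2, 4, 7, 8))
  ref <- cor.test(c(1, 2, 3, 4), c(2, 4, 7, 8))
  expect_equal(out$r, unname(ref$estimate))
  expect_equal(c(out$lo, out$hi), as.numeric(ref$conf.int))
  expect_equal(round(cor(c(1, 2, 3), c(2, 4, 7)), 4), 0.9934)
  ident <- pearson_with_ci(1:10, 1:10)
  expect_equal(ident$r, 1)
  set.seed(30)
  indep <- pearson_with_ci(rnorm(10000), rnorm(10000))
  expect_lt(abs(indep$r), 0.05)
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_with_ci(1:3, c(2, 4, 7)), "4")
})
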