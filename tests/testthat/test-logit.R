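test_that("intercept-only binary fit has the closed-form MLE", {
  fit <- fit_binary_logit(NULL, c(rep(1, 3), rep(0, 7)))
  expect_equal(unname(coef(fit)), log(3 / 7), tolerance = 1e-10)
  expect_equal(unname(predict(fit)[1]), 0.3, tolerance = 1e-10)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-8)
})

test_that("theta = 0 gives probability one half", {
  ## perfectly symmetric data pin both intercept and slope at 0
  fit <- fit_binary_logit(cbind(x = c(-1, -1, 1, 1)), c(0, 1, 0, 1))
  expect_equal(unname(coef(fit)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(predict(fit))[1], 0.5, tolerance = 1e-9)
  ## slope exactly 0 makes the Wald p exactly 1
  expect_equal(wald_test(fit, "x")$p.value, 1, tolerance = 1e-8)
})

test_that("binary fit matches glm (independent implementation)", {
  set.seed(11)
  for (i in 1:5) {
    n <- 150
    x1 <- rnorm(n); x2 <- runif(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.9 * x1 - 1.1 * x2))
    fit <- fit_binary_logit(cbind(x1 = x1, x2 = x2), y)
    g <- stats::glm(y ~ x1 + x2, family = binomial)
    expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-7)
    expect_equal(unname(fit$se),
                 unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
    expect_equal(fit$aic, AIC(g), tolerance = 1e-6)
  }
})

test_that("ordinal fit matches MASS::polr (independent implementation)", {
  skip_if_not_installed("MASS")
  set.seed(12)
  for (i in 1:4) {
    n <- 300
    x <- rnorm(n)
    y <- sim_ordinal(0.9 * x, c(-1.2, -0.2, 0.6, 1.4))
    fit <- fit_ordinal_logit(cbind(x = x), y)
    m <- MASS::polr(factor(y, levels = 0:4) ~ x, method = "logistic",
                    Hess = TRUE)
    expect_equal(unname(coef(fit)), unname(coef(m)), tolerance = 1e-4)
    expect_equal(unname(fit$zeta), unname(m$zeta), tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(m)))),
                 tolerance = 1e-3)
  }
})

test_that("intercept-only ordinal thresholds are cumulative-proportion logits", {
  fit <- fit_ordinal_logit(NULL, c(rep(0, 5), rep(1, 5)))
  expect_equal(unname(fit$zeta), 0, tolerance = 1e-9)

  fit <- fit_ordinal_logit(NULL, c(rep(0, 2), rep(1, 2), rep(2, 2)))
  expect_equal(unname(fit$zeta), qlogis(c(1 / 3, 2 / 3)), tolerance = 1e-8)
})

test_that("two-level ordinal fit is the binary fit reparameterized", {
  set.seed(13)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.5 + x))
  fo <- fit_ordinal_logit(cbind(x = x), y)
  fb <- fit_binary_logit(cbind(x = x), y)
  expect_equal(fo$coefficients[["x"]], fb$coefficients[["x"]],
               tolerance = 1e-7)
  expect_equal(unname(fo$zeta), -fb$coefficients[["(Intercept)"]],
               tolerance = 1e-7)
  expect_equal(fo$loglik, fb$loglik, tolerance = 1e-9)
})

test_that("fits reach the grid-search oracle log-likelihood", {
  ## two instances here; the full fixture suite runs in test-acceptance.R
  fx <- oracle_fixtures()[c(1, 5)]
  for (f in fx) {
    if (f$kind == "binary") {
      fit <- fit_binary_logit(cbind(x = f$x), f$y)
      o <- oracle_grid_min(function(p) oracle_bin_nll(p, f$x, f$y),
                           lower = c(-8, -8), upper = c(8, 8))
    } else {
      fit <- fit_ordinal_logit(cbind(x = f$x), f$y)
      o <- oracle_grid_min(function(p) oracle_ord_nll(p, f$x, f$y, 3L),
                           lower = c(-8, -8, -8), upper = c(8, 8, 8))
    }
    expect_lt(abs(fit$loglik - (-o$value)), 1e-6)
  }
})

test_that("Wald and LR tests behave as defined", {
  set.seed(14)
  x <- rnorm(200)
  y <- sim_ordinal(0.7 * x, c(-1, 0, 1))
  fit <- fit_ordinal_logit(cbind(x = x), y)
  w <- wald_test(fit, "x")
  expect_equal(sign(w$statistic), sign(coef(fit)[["x"]]))
  expect_equal(w$p.value, 2 * pnorm(-abs(coef(fit)[["x"]] / fit$se[["x"]])))
  expect_true(w$p.value > 0 && w$p.value <= 1)
  expect_error(wald_test(fit, "nope"), "not in fit")

  null_fit <- fit_ordinal_logit(NULL, y)
  lr <- lr_test(fit, null_fit)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 1)
  expect_equal(lr$p.value, pchisq(lr$statistic, 1, lower.tail = FALSE))

  self <- lr_test(fit, fit)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)

  ## LR agrees with the glm deviance difference on a binary model
  yb <- rbinom(200, 1, plogis(0.5 * x))
  fb <- fit_binary_logit(cbind(x = x), yb)
  fb0 <- fit_binary_logit(NULL, yb)
  g <- stats::glm(yb ~ x, family = binomial)
  expect_equal(lr_test(fb, fb0)$statistic,
               unname(g$null.deviance - g$deviance), tolerance = 1e-6)

  expect_error(lr_test(fb, fit), "different outcome kinds|different numbers")
})

test_that("translation of a predictor moves only intercept and thresholds", {
  set.seed(15)
  x <- rnorm(150)
  y <- sim_ordinal(0.8 * x, c(-0.8, 0.4))
  f1 <- fit_ordinal_logit(cbind(x = x), y)
  f2 <- fit_ordinal_logit(cbind(x = x + 5), y)
  expect_equal(coef(f1)[["x"]], coef(f2)[["x"]], tolerance = 1e-8)
  expect_equal(unname(f2$zeta - f1$zeta),
               rep(5 * coef(f1)[["x"]], 2), tolerance = 1e-6)

  yb <- rbinom(150, 1, plogis(x))
  b1 <- fit_binary_logit(cbind(x = x), yb)
  b2 <- fit_binary_logit(cbind(x = x + 5), yb)
  expect_equal(coef(b1)[["x"]], coef(b2)[["x"]], tolerance = 1e-8)
})

test_that("degenerate inputs raise diagnostic errors", {
  ## complete separation
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_binary_logit(cbind(x = x), y), "separation")
  ## constant predictor
  expect_error(fit_binary_logit(cbind(z = rep(1, 6)), y),
               "constant.*z")
  ## collinear predictors
  set.seed(16)
  x1 <- rnorm(40); y2 <- rbinom(40, 1, 0.5)
  expect_error(fit_binary_logit(cbind(a = x1, b = 2 * x1), y2),
               "collinear")
  ## single outcome class
  expect_error(fit_binary_logit(cbind(x = rnorm(5)), rep(1, 5)),
               "each outcome class")
  ## declared but unused ordinal level dropped with warning
  yf <- factor(sample(c(0, 1, 4), 30, replace = TRUE), levels = c(0, 1, 2, 4))
  expect_warning(fit_ordinal_logit(cbind(x = rnorm(30)), yf),
                 "not observed")
})

test_that("predicted category probabilities are a proper distribution", {
  set.seed(17)
  x <- rnorm(100)
  y <- sim_ordinal(x, c(-1, 0, 1, 2))
  fit <- fit_ordinal_logit(cbind(x = x), y)
  pr <- predict(fit, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 100), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  ## larger theta shifts mass to higher levels (stochastic ordering)
  hi <- predict(fit, newdata = cbind(x = 3), type = "prob")
  lo <- predict(fit, newdata = cbind(x = -3), type = "prob")
  expect_gt(hi[, "4"], lo[, "4"])
  expect_lt(hi[, "0"], lo[, "0"])
})

test_that("the formula interface and simulate method round-trip", {
  set.seed(18)
  d <- data.frame(x = rnorm(400))
  d$y <- sim_ordinal(1.2 * d$x, c(-1, 0.5))
  fit <- eslogit(y ~ x, d, kind = "ordinal")
  expect_s3_class(fit, "eslogit")
  sims <- simulate(fit, nsim = 3, seed = 7)
  expect_equal(dim(sims), c(400L, 3L))
  expect_true(all(unlist(sims) %in% 0:2))
  ## refitting on simulated data recovers the coefficient roughly
  refit <- fit_ordinal_logit(cbind(x = d$x), sims[[1]])
  expect_lt(abs(coef(refit)[["x"]] - coef(fit)[["x"]]), 0.5)
})
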