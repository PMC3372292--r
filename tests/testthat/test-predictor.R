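test_that("pES is the logistic transform of the linear score", {
  cs <- coefficient_set(list(kind = "binary", intercept = 0,
                             coefficients = c(a = 1, b = -2)))
  f <- data.frame(a = c(0, 2, log(9)), b = c(0, 1, 0))
  expect_equal(pes_score(f, cs), plogis(c(0, 0, log(9))))
  expect_equal(pes_score(f, cs)[1], 0.5)
  expect_equal(pes_score(f, cs)[3], 0.9)
  expect_equal(pes_score(f, cs, what = "theta"), c(0, 0, log(9)))

  ## all-zero coefficients: every construct scores the intercept
  cs0 <- coefficient_set(list(kind = "binary", intercept = 1.2,
                              coefficients = c(a = 0, b = 0)))
  expect_equal(pes_score(f, cs0), rep(plogis(1.2), 3))

  ## strictly increasing in theta, invariant to feature column order
  expect_equal(pes_score(f[, c("b", "a")], cs), pes_score(f, cs))
  expect_error(pes_score(f[, "a", drop = FALSE], cs), "missing: b")
  f_na <- f; f_na$a[2] <- NA
  expect_error(pes_score(f_na, cs), "missing values: a")
})

test_that("ordinal score distributions are proper and threshold-consistent", {
  cs <- coefficient_set(list(kind = "ordinal",
                             coefficients = c(x = 1),
                             thresholds = c(-1.5, -0.5, 0.2, 0.8, 1.8),
                             levels = 0:5))
  f <- data.frame(x = c(-3, 0, 0.2, 50))
  pr <- predict_score_distribution(f, cs)
  expect_equal(unname(rowSums(pr)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  ## theta = 50: essentially all mass on the top level
  expect_gt(pr[4, "5"], 1 - 1e-10)
  ## theta equal to a threshold: P(Y <= that level) = 0.5
  expect_equal(sum(pr[3, 1:3]), 0.5, tolerance = 1e-12)

  ## ensemble self-consistency: mean predicted distribution matches
  ## empirical level frequencies within 2% per level
  set.seed(51)
  n <- 5000
  fx <- data.frame(x = rnorm(n))
  pr <- predict_score_distribution(fx, cs)
  y <- sim_ordinal(fx$x, unlist(cs$thresholds))
  emp <- tabulate(factor(y, levels = 0:5), 6) / n
  expect_true(all(abs(colMeans(pr) - emp) < 0.02))
})

test_that("binomial intervals match the Beta-quantile oracle", {
  ci <- binomial_ci(5, 10)
  expect_equal(unname(ci[1]), oracle_beta_quantile(0.025, 5.5, 5.5),
               tolerance = 1e-6)
  expect_equal(unname(ci[2]), oracle_beta_quantile(0.975, 5.5, 5.5),
               tolerance = 1e-6)
  ## symmetry about one half at s = n/2
  expect_equal(ci[[1]], 1 - ci[[2]], tolerance = 1e-12)
  ## boundary conventions
  expect_equal(binomial_ci(0, 7)[[1]], 0)
  expect_equal(binomial_ci(7, 7)[[2]], 1)
  ## uniform prior equals Beta(s+1, n-s+1) quantiles
  cu <- binomial_ci(3, 12, prior = "uniform")
  expect_equal(unname(cu[1]), qbeta(0.025, 4, 10), tolerance = 1e-12)
})

test_that("calibration bins partition theta and cover observed fractions", {
  theta <- c(0.05, 0.07, rep(0.15, 10), 0.31)
  usable <- c(TRUE, FALSE, rep(TRUE, 10), FALSE)
  cal <- calibration_curve(theta, usable, bin_width = 0.1)
  expect_equal(nrow(cal), 3)          # empty bins omitted
  expect_equal(sum(cal$n), 13)
  mid <- cal[cal$bin_lo == 0.1, ]
  expect_equal(mid$observed, 1)       # 10/10 usable
  expect_equal(mid$upper, 1)          # CI upper bound at the boundary
  expect_true(all(cal$lower <= cal$observed & cal$observed <= cal$upper))
  expect_true(all(cal$lower >= 0 & cal$upper <= 1))

  ## all records in one bin
  one <- calibration_curve(rep(0.42, 5), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(one), 1)
  expect_equal(one$observed, 0.8)
})

test_that("cutoff trade-off reports kept fraction and yield increase", {
  ## 10 records, 4 usable; above the cutoff: 5 records, 3 usable
  pes <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.3, 0.2, 0.15, 0.1, 0.05)
  usable <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
              FALSE)
  tt <- cutoff_tradeoff(pes, usable, cutoffs = c(0.5, 0, 0.95))
  r1 <- tt[tt$cutoff == 0.5, ]
  expect_equal(r1$kept_fraction, 0.5)
  expect_equal(r1$yield_increase_pct, 50)  # 0.6 / 0.4 - 1
  r0 <- tt[tt$cutoff == 0, ]
  expect_equal(r0$yield_increase_pct, 0)   # keeping everything
  r9 <- tt[tt$cutoff == 0.95, ]
  expect_true(is.na(r9$yield_increase_pct) && r9$kept_n == 0)

  ## monotone-calibrated cohort: yield increase non-decreasing in cutoff
  set.seed(52)
  th <- runif(5000, -2, 2)
  us <- runif(5000) < plogis(th)
  tt2 <- cutoff_tradeoff(plogis(th), us, cutoffs = c(0.2, 0.4, 0.6))
  expect_true(all(diff(tt2$yield_increase_pct) > -5))
})

test_that("scoring the training data reproduces the fit's log-likelihood", {
  set.seed(53)
  n <- 400
  f <- data.frame(a = rnorm(n), b = runif(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * f$a - 0.8 * f$b))
  fit <- fit_binary_logit(as.matrix(f), y)
  cs <- coefficient_set(fit)
  p <- pes_score(f, cs)
  ll <- sum(log(ifelse(y == 1, p, 1 - p)))
  expect_equal(ll, fit$loglik, tolerance = 1e-8)

  yo <- sim_ordinal(1.1 * f$a, c(-1, 0, 1))
  fo <- fit_ordinal_logit(as.matrix(f[, "a", drop = FALSE]), yo)
  cso <- coefficient_set(fo)
  pro <- predict_score_distribution(f[, "a", drop = FALSE], cso)
  llo <- sum(log(pro[cbind(seq_len(n), yo + 1L)]))
  expect_equal(llo, fo$loglik, tolerance = 1e-8)
})

test_that("coefficient sets survive a JSON round trip", {
  set.seed(54)
  f <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- rbinom(100, 1, plogis(f$a))
  fit <- fit_binary_logit(as.matrix(f), y)
  cs <- coefficient_set(fit, metadata = list(variant = "analysis-max",
                                             note = "unit test"))
  path <- tempfile(fileext = ".json")
  write_coefficient_set(cs, path)
  cs2 <- read_coefficient_set(path)
  expect_equal(cs2$kind, "binary")
  expect_equal(unlist(cs2$coefficients), unlist(cs$coefficients),
               tolerance = 1e-12)
  expect_equal(cs2$intercept, cs$intercept, tolerance = 1e-12)
  expect_equal(cs2$metadata$variant, "analysis-max")
  expect_equal(pes_score(f, cs2), pes_score(f, cs), tolerance = 1e-12)

  yo <- sim_ordinal(f$a, c(-0.5, 0.5))
  fo <- fit_ordinal_logit(as.matrix(f[, "a", drop = FALSE]), yo)
  cso <- coefficient_set(fo)
  write_coefficient_set(cso, path)
  cso2 <- read_coefficient_set(path)
  expect_equal(unlist(cso2$thresholds), unname(unlist(cso$thresholds)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict_score_distribution(f[, "a", drop = FALSE], cso2),
               predict_score_distribution(f[, "a", drop = FALSE], cso),
               tolerance = 1e-12)
})

test_that("held-out validation keeps a real effect significant", {
  ## mirrors the analysis/test split design: fit on 80%, test the fitted
  ## score on the held-out 20% by likelihood ratio
  set.seed(55)
  n <- 2500
  f <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * f$x))
  train <- runif(n) < 0.8
  fit <- fit_binary_logit(as.matrix(f[train, , drop = FALSE]), y[train])
  cs <- coefficient_set(fit)
  th_test <- pes_score(f[!train, , drop = FALSE], cs, what = "theta")
  full <- fit_binary_logit(cbind(theta = th_test), y[!train])
  nullf <- fit_binary_logit(NULL, y[!train])
  expect_lt(lr_test(full, nullf)$p.value, 1e-4)
})
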