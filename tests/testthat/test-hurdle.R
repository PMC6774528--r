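# Maximum-likelihood machinery: inverse Mills ratio, probit, zero-truncated
# normal, Tobit, the separable Cragg likelihood, and the LR test.

test_that("inverse Mills ratio matches closed forms and the deep tail", {
  expect_equal(inverse_mills(0), 2 * dnorm(0), tolerance = 1e-12)
  expect_equal(inverse_mills(0), 0.7978845608, tolerance = 1e-9)
  expect_lt(inverse_mills(10), 1e-15)
  # left tail: asymptotic series lambda(-t) = t + 1/t - 2/t^3 + 10/t^5
  t <- 30
  series <- t + 1 / t - 2 / t^3 + 10 / t^5
  expect_equal(inverse_mills(-30), series, tolerance = 1e-6)
  expect_true(all(is.finite(inverse_mills(seq(-40, 40, by = 0.5)))))
})

test_that("intercept-only probit equals the quantile and a grid oracle", {
  set.seed(2)
  dh <- rbinom(400, 1, 0.35)
  X <- matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_probit(dh, X)
  expect_equal(unname(f$gamma), qnorm(mean(dh)), tolerance = 1e-7)
  # 1-D brute-force grid oracle
  grid <- seq(qnorm(mean(dh)) - 0.3, qnorm(mean(dh)) + 0.3, length.out = 4001)
  ll <- vapply(grid, function(g) {
    sum(dh * pnorm(g, log.p = TRUE) + (1 - dh) * pnorm(-g, log.p = TRUE))
  }, numeric(1))
  expect_lt(abs(unname(f$gamma) - grid[which.max(ll)]), 2e-4)
  expect_gte(f$ll, max(ll))
})

test_that("probit recovers known coefficients within 3 standard errors", {
  d <- make_dh_data(n = 5000, seed = 6)
  f <- fit_probit(d$dh, d$X)
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(f$gamma - d$gamma) < 3 * se))
  expect_true(f$convergence$converged)
  expect_lt(f$gradient_norm, 1e-6 * (1 + abs(f$ll)))
})

test_that("probit refuses degenerate, separated, or deficient designs", {
  X <- cbind("(Intercept)" = 1, x = rnorm(50))
  expect_error(fit_probit(rep(1, 50), X), "degenerate")
  # rank deficiency names the offending column
  Xr <- cbind(X, x_copy = X[, "x"])
  expect_error(fit_probit(rbinom(50, 1, 0.5), Xr), "x_copy")
  # perfect separation on a continuous covariate
  x <- c(seq(-2, -0.1, length.out = 25), seq(0.1, 2, length.out = 25))
  Xs <- cbind("(Intercept)" = 1, x = x)
  expect_error(fit_probit(as.numeric(x > 0), Xs), "separation")
})

test_that("truncated regression approaches OLS as the truncation vanishes", {
  set.seed(9)
  n <- 600
  d <- data.frame(x1 = rnorm(n))
  Z <- build_design(d, "x1")
  y <- drop(Z %*% c(500, 40)) + rnorm(n, 0, 1e-3)
  # near-degenerate noise: the fit may flag the gradient tolerance but must
  # still return parameters (the documented non-convergence contract)
  f <- suppressWarnings(fit_truncated_normal(y, Z))
  ols <- lm.fit(Z, y)$coefficients
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-5)
  expect_lt(f$sigma, 0.01)
})

test_that("intercept-only truncated MLE beats every point on a 2-D grid", {
  set.seed(10)
  raw <- rnorm(500, 120, 100)
  y <- raw[raw > 0]
  Z <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_truncated_normal(y, Z)
  grid_b <- seq(f$beta - 30, f$beta + 30, length.out = 41)
  grid_s <- seq(f$sigma * 0.8, f$sigma * 1.2, length.out = 41)
  ll_fit <- f$ll
  for (b in grid_b) {
    for (s in grid_s) {
      ll <- sum(dnorm((y - b) / s, log = TRUE) - log(s) -
                  pnorm(b / s, log.p = TRUE))
      expect_lte(ll, ll_fit + 1e-8)
    }
  }
})

test_that("truncated regression recovers known parameters within 3 SEs", {
  d <- make_dh_data(n = 5000, seed = 7)
  pos <- d$dh == 1
  f <- fit_truncated_normal(d$qh[pos], d$Z[pos, , drop = FALSE])
  se <- sqrt(diag(f$vcov))
  k <- length(f$beta)
  expect_true(all(abs(f$beta - d$beta) < 3 * se[seq_len(k)]))
  # delta method on log sigma for the sigma SE
  expect_lt(abs(log(f$sigma) - log(d$sigma)), 3 * se[k + 1L])
  expect_error(fit_truncated_normal(c(-1, d$qh[pos]), rbind(1, d$Z[pos, ])),
               "positive")
})

test_that("analytic scores agree with numerical gradients", {
  d <- make_dh_data(n = 300, seed = 15)
  set.seed(16)
  for (i in 1:5) {
    g <- d$gamma + rnorm(4, 0, 0.2)
    expect_equal(btcoi:::probit_score(g, d$dh, d$X),
                 num_grad(function(p) btcoi:::probit_loglik(p, d$dh, d$X), g),
                 tolerance = 1e-5)
    th <- c(d$beta + rnorm(4, 0, 10), log(d$sigma) + rnorm(1, 0, 0.1))
    pos <- d$dh == 1
    yq <- d$qh[pos]
    Zq <- d$Z[pos, , drop = FALSE]
    expect_equal(btcoi:::truncnorm_score(th, yq, Zq),
                 num_grad(function(p) btcoi:::truncnorm_loglik(p, yq, Zq),
                          th),
                 tolerance = 1e-5)
    expect_equal(btcoi:::tobit_score(th, d$qh, d$Z),
                 num_grad(function(p) btcoi:::tobit_loglik(p, d$qh, d$Z), th),
                 tolerance = 1e-5)
  }
})

test_that("the two-stage fit equals the jointly maximized likelihood", {
  d <- make_dh_data(n = 800, seed = 20)
  f2 <- fit_double_hurdle(d$dh, d$qh, d$X, d$Z)
  fj <- fit_double_hurdle(d$dh, d$qh, d$X, d$Z, method = "joint")
  expect_equal(fj$ll_total, f2$ll_total, tolerance = 1e-6)
  expect_equal(fj$gamma, f2$gamma, tolerance = 1e-4)
  expect_equal(fj$beta, f2$beta, tolerance = 1e-3)
  expect_equal(f2$ll_total, f2$ll_probit + f2$ll_truncated)
  expect_equal(f2$n_positive, sum(d$dh))
})

test_that("dh/qh inconsistencies are reported with row identifiers", {
  d <- make_dh_data(n = 100, seed = 22)
  qh_bad <- d$qh
  qh_bad[d$dh == 0][1] <- 5
  expect_error(fit_double_hurdle(d$dh, qh_bad, d$X, d$Z), "row")
})

test_that("uncensored Tobit equals the normal-regression MLE", {
  set.seed(23)
  n <- 400
  d <- data.frame(x1 = rnorm(n))
  Z <- build_design(d, "x1")
  y <- drop(Z %*% c(800, 30)) + rnorm(n, 0, 50)  # never near zero
  stopifnot(all(y > 0))
  f <- fit_tobit(y, Z)
  ols <- lm(y ~ x1, data = d)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f$sigma, sqrt(mean(residuals(ols)^2)), tolerance = 1e-6)
  expect_equal(f$n_censored, 0L)
  expect_error(fit_tobit(rep(0, 50), matrix(1, 50, 1)), "all zero")
})

test_that("Tobit recovers its own DGP and is dominated by the double hurdle", {
  td <- make_tobit_data(n = 2000, seed = 24)
  f <- fit_tobit(td$y, td$Z)
  se <- sqrt(diag(f$vcov))
  k <- length(f$beta)
  expect_true(all(abs(f$beta - td$beta) < 3 * se[seq_len(k)]))
  dh <- as.numeric(td$y > 0)
  fdh <- fit_double_hurdle(dh, td$y, td$Z, td$Z)
  expect_gte(fdh$ll_total, f$ll)
  lt <- lr_test(fdh, f)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$df, 3L)           # hurdle-1 slope count convention
  expect_equal(lr_test(fdh, f, df = 4L)$df, 4L)
})

test_that("LR bookkeeping follows 2*(llDH - llTobit) and flags bad optima", {
  lt <- lr_from_loglik(-100, -200, -330, 3)
  expect_equal(lt$statistic, 60)
  expect_equal(lt$p_value, pchisq(60, 3, lower.tail = FALSE))
  expect_error(lr_from_loglik(-100, -200, -250, 3), "negative LR")
})

test_that("rescaling a covariate rescales beta and leaves the fit invariant", {
  d <- make_dh_data(n = 700, seed = 26)
  f1 <- fit_double_hurdle(d$dh, d$qh, d$X, d$Z)
  Z2 <- d$Z
  Z2[, "x1"] <- Z2[, "x1"] * 10
  f2 <- fit_double_hurdle(d$dh, d$qh, d$X, Z2)
  expect_equal(f2$ll_total, f1$ll_total, tolerance = 1e-7)
  expect_equal(f2$beta[["x1"]], f1$beta[["x1"]] / 10, tolerance = 1e-5)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-5)
})
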