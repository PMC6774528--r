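# Average marginal effects: analytic formulas against numerical oracles,
# limiting cases, and the bootstrap.

fake_fit <- function(gamma, beta, sigma) {
  structure(list(gamma = gamma, beta = beta, sigma = sigma),
            class = "btcoi_dh")
}

eff_data <- function(n = 300, seed = 30) {
  set.seed(seed)
  data.frame(x1 = rnorm(n), x2 = runif(n, -1, 1), d1 = rbinom(n, 1, 0.4))
}

test_that("zero coefficients give zero effects", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 0.4, x1 = 0, x2 = 0.5, d1 = -0.2),
                c("(Intercept)" = 300, x1 = 0, x2 = 40, d1 = -40), 120)
  cm <- came(f, d, "x1")
  expect_equal(unname(cm[["h1"]]), 0)
  expect_equal(unname(cm[["h2"]]), 0)
  expect_equal(uame(f, d, "x1"), 0)
  expect_error(came(f, d, "not_there"), "neither hurdle")
})

test_that("continuous effects match central-difference oracles to 1e-6", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 0.4, x1 = 0.7, x2 = -0.5, d1 = 0.3),
                c("(Intercept)" = 350, x1 = 60, x2 = -80, d1 = 45), 140)
  h <- 1e-5
  for (v in c("x1", "x2")) {
    dp <- dm <- d
    dp[[v]] <- dp[[v]] + h
    dm[[v]] <- dm[[v]] - h
    # hurdle 2: conditional mean difference
    num_h2 <- mean((predict_costs(f, dp)$cond_cost -
                      predict_costs(f, dm)$cond_cost) / (2 * h))
    expect_equal(unname(came(f, d, v)[["h2"]]), num_h2, tolerance = 1e-6)
    # hurdle 1: probability difference
    num_h1 <- mean((predict_costs(f, dp)$p_treat -
                      predict_costs(f, dm)$p_treat) / (2 * h))
    expect_equal(unname(came(f, d, v)[["h1"]]), num_h1, tolerance = 1e-6)
    # unconditional
    num_u <- mean((predict_costs(f, dp)$uncond_cost -
                     predict_costs(f, dm)$uncond_cost) / (2 * h))
    expect_equal(uame(f, d, v), num_u, tolerance = 1e-6)
  }
})

test_that("dummy effects equal independent row-wise discrete differences", {
  d <- eff_data()
  gamma <- c("(Intercept)" = 0.4, x1 = 0.7, x2 = -0.5, d1 = 0.3)
  beta <- c("(Intercept)" = 350, x1 = 60, x2 = -80, d1 = 45)
  sigma <- 140
  f <- fake_fit(gamma, beta, sigma)
  # independent reconstruction with raw pnorm/dnorm arithmetic
  e7 <- function(d1val) {
    eta1 <- gamma[1] + gamma[2] * d$x1 + gamma[3] * d$x2 + gamma[4] * d1val
    eta2 <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 + beta[4] * d1val
    t0 <- eta2 / sigma
    pnorm(eta1) * (eta2 + sigma * dnorm(t0) / pnorm(t0))
  }
  rowdiff <- e7(1) - e7(0)
  expect_equal(uame(f, d, "d1"), mean(rowdiff), tolerance = 1e-10)
  # UAME of a dummy lies inside the range of per-row changes
  expect_gte(uame(f, d, "d1"), min(rowdiff))
  expect_lte(uame(f, d, "d1"), max(rowdiff))
})

test_that("sign coherence: negative coefficients in both hurdles give a negative UAME", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 0.4, x1 = -0.3, x2 = 0.5, d1 = -0.4),
                c("(Intercept)" = 350, x1 = -50, x2 = 40, d1 = -60), 140)
  expect_lt(uame(f, d, "x1"), 0)
  expect_lt(uame(f, d, "d1"), 0)
})

test_that("the sigma -> 0 limit reduces the hurdle-2 effect to beta", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 0.4, x1 = 0.7, x2 = -0.5, d1 = 0.3),
                c("(Intercept)" = 350, x1 = 60, x2 = -80, d1 = 45), 1e-6)
  expect_equal(unname(came(f, d, "x1")[["h2"]]), 60, tolerance = 1e-6)
})

test_that("a saturated first hurdle collapses UAME onto the conditional effect", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 30, x1 = 0.7, x2 = -0.5, d1 = 0.3),
                c("(Intercept)" = 350, x1 = 60, x2 = -80, d1 = 45), 140)
  expect_equal(uame(f, d, "x1"), unname(came(f, d, "x1")[["h2"]]),
               tolerance = 1e-8)
})

test_that("a covariate absent from one hurdle reports NA there, not zero", {
  d <- eff_data()
  f <- fake_fit(c("(Intercept)" = 0.4, x1 = 0.7, x2 = -0.5, d1 = 0.3),
                c("(Intercept)" = 350, x1 = 60, d1 = 45), 140)
  cm <- came(f, d, "x2")
  expect_false(is.na(cm[["h1"]]))
  expect_true(is.na(cm[["h2"]]))
  expect_true(is.finite(uame(f, d, "x2")))
})

test_that("unconditional expected cost equals the row-wise mean and the LLN limit", {
  d <- make_dh_data(n = 30000, seed = 33)
  f <- fake_fit(setNames(d$gamma, colnames(d$X)),
                setNames(d$beta, colnames(d$Z)), d$sigma)
  ue <- unconditional_expected_cost(f, d$data)
  # row-wise oracle
  pc <- predict_costs(f, d$data)
  expect_equal(ue, mean(pc$p_treat * pc$cond_cost), tolerance = 1e-12)
  # large-sample agreement with the empirical mean of qh
  se <- sd(d$qh) / sqrt(length(d$qh))
  expect_lt(abs(ue - mean(d$qh)), 3 * se)
})

test_that("bootstrap SEs: constant statistic, determinism, closed form", {
  set.seed(40)
  d <- data.frame(y = rnorm(400, 10, 2))
  se_const <- bootstrap_se(function(df) c(k = 42), d, reps = 50, seed = 1)
  expect_equal(unname(se_const[["k"]]), 0)
  se1 <- bootstrap_se(function(df) c(m = mean(df$y)), d, reps = 400, seed = 2)
  se2 <- bootstrap_se(function(df) c(m = mean(df$y)), d, reps = 400, seed = 2)
  expect_identical(se1, se2)
  # closed form sigma/sqrt(n) within Monte-Carlo error
  closed <- sd(d$y) / sqrt(nrow(d))
  mc_se <- closed / sqrt(2 * 400)
  expect_lt(abs(unname(se1[["m"]]) - closed), 4 * mc_se)
  expect_error(bootstrap_se(function(df) c(m = 1), d, reps = 1), "reps")
})

test_that("full effects analysis refits per replicate and is reproducible", {
  s <- generate_survey(dgp_config(n_farmers = 500, seed = 44))
  cfg <- dgp_config()
  e1 <- dh_effects(s, cfg$h1_covariates, cfg$h2_covariates,
                   covariates = c("true_bt", "weak_bt"), reps = 25, seed = 9)
  e2 <- dh_effects(s, cfg$h1_covariates, cfg$h2_covariates,
                   covariates = c("true_bt", "weak_bt"), reps = 25, seed = 9)
  expect_equal(e1$table, e2$table)
  expect_true(all(e1$table[c("se_came_h1", "se_came_h2", "se_uame")] >= 0))
  expect_true(is.finite(e1$unconditional_expected_cost))
  expect_equal(e1$metadata$reps, 25)
})
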