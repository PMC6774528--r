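# Average marginal effects for the double-hurdle model, Burke-style:
# effects are averaged over the estimation sample (not evaluated at the
# mean), continuous covariates by analytic derivative and dummies by the
# discrete 0 -> 1 change. The conditional level is the truncated-normal
# mean E[Q | Q > 0, z] = beta z + sigma * lambda(beta z / sigma); the
# unconditional level multiplies it by the hurdle-1 probability Phi(gamma x).
# Standard errors come from a nonparametric bootstrap that re-estimates both
# hurdles on each replicate.

h1_names <- function(fit) names(fit$gamma)[-1L]
h2_names <- function(fit) names(fit$beta)[-1L]

# E[Q | Q > 0] per row
cond_mean <- function(eta2, sigma) {
  eta2 + sigma * inverse_mills(eta2 / sigma)
}

# d/d(eta2) of cond_mean: 1 + lambda'(t) with lambda'(t) = -lambda(t)(t+lambda(t))
cond_mean_deriv <- function(eta2, sigma) {
  t0 <- eta2 / sigma
  lam <- inverse_mills(t0)
  1 - lam * (t0 + lam)
}

fit_designs <- function(fit, data) {
  list(X = build_design(data, h1_names(fit)),
       Z = build_design(data, h2_names(fit)))
}

#' Model-implied conditional and unconditional cost per farmer
#'
#' @param fit a `btcoi_dh` fit.
#' @param data data frame holding the fit's covariate columns.
#' @return data.frame with per-row `p_treat` (hurdle-1 probability),
#'   `cond_cost` (Rs, given positive) and `uncond_cost` (Rs).
#' @export
predict_costs <- function(fit, data) {
  d <- fit_designs(fit, data)
  eta1 <- drop(d$X %*% fit$gamma)
  eta2 <- drop(d$Z %*% fit$beta)
  p <- pnorm(eta1)
  cc <- cond_mean(eta2, fit$sigma)
  data.frame(p_treat = p, cond_cost = cc, uncond_cost = p * cc)
}

#' Unconditional expected cost of illness (Rs)
#'
#' Sample mean of the model-implied unconditional cost
#' \eqn{\Phi(\gamma x)[\beta z + \sigma\lambda(\beta z/\sigma)]} over the
#' estimation sample -- the baseline against which unconditional marginal
#' effects are expressed as relative reductions.
#'
#' @inheritParams predict_costs
#' @return single numeric value (Rs).
#' @export
unconditional_expected_cost <- function(fit, data) {
  mean(predict_costs(fit, data)$uncond_cost)
}

resolve_dummy <- function(data, covariate, dummy) {
  if (!is.null(dummy)) return(isTRUE(dummy))
  is_binary_col(data[[covariate]])
}

#' Conditional average marginal effects (per hurdle)
#'
#' Hurdle-1 effect: average change in the treatment probability
#' \eqn{\Phi(\gamma x)}; hurdle-2 effect: average change in the conditional
#' cost \eqn{\beta z + \sigma\lambda(\beta z/\sigma)} (Rs). Continuous
#' covariates use the analytic derivative, dummies the discrete 0 to 1
#' difference, both averaged over the sample. A covariate absent from one
#' hurdle gets `NA` for that hurdle (its effect is undefined there, not
#' zero); a covariate absent from both is an error.
#'
#' @param fit a `btcoi_dh` fit.
#' @param data estimation-sample data frame.
#' @param covariate single covariate name.
#' @param dummy force the discrete-change (`TRUE`) or derivative (`FALSE`)
#'   convention; default auto-detects 0/1 columns.
#' @return named numeric vector `c(h1 = ..., h2 = ...)`.
#' @export
came <- function(fit, data, covariate, dummy = NULL) {
  in1 <- covariate %in% h1_names(fit)
  in2 <- covariate %in% h2_names(fit)
  if (!in1 && !in2) {
    stop("covariate '", covariate, "' is in neither hurdle design",
         call. = FALSE)
  }
  dummy <- resolve_dummy(data, covariate, dummy)
  d <- fit_designs(fit, data)
  h1 <- NA_real_
  h2 <- NA_real_
  if (in1) {
    if (dummy) {
      X1 <- X0 <- d$X
      X1[, covariate] <- 1
      X0[, covariate] <- 0
      h1 <- mean(pnorm(drop(X1 %*% fit$gamma)) -
                   pnorm(drop(X0 %*% fit$gamma)))
    } else {
      h1 <- mean(dnorm(drop(d$X %*% fit$gamma))) * fit$gamma[[covariate]]
    }
  }
  if (in2) {
    if (dummy) {
      Z1 <- Z0 <- d$Z
      Z1[, covariate] <- 1
      Z0[, covariate] <- 0
      h2 <- mean(cond_mean(drop(Z1 %*% fit$beta), fit$sigma) -
                   cond_mean(drop(Z0 %*% fit$beta), fit$sigma))
    } else {
      eta2 <- drop(d$Z %*% fit$beta)
      h2 <- fit$beta[[covariate]] * mean(cond_mean_deriv(eta2, fit$sigma))
    }
  }
  c(h1 = h1, h2 = h2)
}

#' Unconditional average marginal effect (Rs)
#'
#' Average effect of a covariate on the unconditional expected cost
#' \eqn{\Phi(\gamma x)[\beta z + \sigma\lambda(\beta z/\sigma)]}, combining
#' both hurdles. For dummies the covariate is flipped 0 to 1 in every
#' design in which it appears; for continuous covariates the analytic
#' derivative uses a zero coefficient for a hurdle the covariate is absent
#' from.
#'
#' @inheritParams came
#' @return single numeric effect in Rs.
#' @export
uame <- function(fit, data, covariate, dummy = NULL) {
  in1 <- covariate %in% h1_names(fit)
  in2 <- covariate %in% h2_names(fit)
  if (!in1 && !in2) {
    stop("covariate '", covariate, "' is in neither hurdle design",
         call. = FALSE)
  }
  dummy <- resolve_dummy(data, covariate, dummy)
  d <- fit_designs(fit, data)
  if (dummy) {
    flip <- function(M, v) {
      M1 <- M0 <- M
      if (v %in% colnames(M)) {
        M1[, v] <- 1
        M0[, v] <- 0
      }
      list(M1, M0)
    }
    Xf <- flip(d$X, covariate)
    Zf <- flip(d$Z, covariate)
    e7 <- function(X, Z) {
      pnorm(drop(X %*% fit$gamma)) *
        cond_mean(drop(Z %*% fit$beta), fit$sigma)
    }
    return(mean(e7(Xf[[1]], Zf[[1]]) - e7(Xf[[2]], Zf[[2]])))
  }
  eta1 <- drop(d$X %*% fit$gamma)
  eta2 <- drop(d$Z %*% fit$beta)
  gk <- if (in1) fit$gamma[[covariate]] else 0
  bk <- if (in2) fit$beta[[covariate]] else 0
  per_row <- dnorm(eta1) * gk * cond_mean(eta2, fit$sigma) +
    pnorm(eta1) * bk * cond_mean_deriv(eta2, fit$sigma)
  mean(per_row)
}

#' Marginal-effects table for a set of covariates
#'
#' @inheritParams came
#' @param covariates covariate names; default: union of both hurdles'
#'   covariates.
#' @param dummy optional named logical vector overriding the automatic
#'   dummy detection per covariate.
#' @return data.frame with one row per covariate: `came_h1` (probability
#'   change), `came_h2` (Rs), `uame` (Rs).
#' @export
marginal_effects <- function(fit, data, covariates = NULL, dummy = NULL) {
  if (is.null(covariates)) {
    covariates <- union(h1_names(fit), h2_names(fit))
  }
  rows <- lapply(covariates, function(v) {
    dv <- if (!is.null(dummy) && v %in% names(dummy)) dummy[[v]] else NULL
    cm <- came(fit, data, v, dummy = dv)
    data.frame(covariate = v, came_h1 = cm[["h1"]], came_h2 = cm[["h2"]],
               uame = uame(fit, data, v, dummy = dv))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric bootstrap standard errors
#'
#' Resamples rows (farmers) with replacement, re-evaluates `estimator` on
#' each replicate, and returns the standard deviation across replicates per
#' reported quantity. Replicates on which the estimator fails (e.g. a
#' non-converged refit) are dropped and counted; more than 10% dropped
#' raises a warning. Deterministic given `seed`.
#'
#' @param estimator function taking a data frame and returning a named
#'   numeric vector.
#' @param data data frame to resample.
#' @param reps number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @return named numeric vector of standard errors, with attributes
#'   `n_failed` and `reps`.
#' @export
bootstrap_se <- function(estimator, data, reps = 500L, seed = 1L) {
  if (reps < 2L) stop("'reps' must be at least 2", call. = FALSE)
  set.seed(seed)
  n <- nrow(data)
  draws <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[[r]] <- tryCatch(estimator(data[idx, , drop = FALSE]),
                           error = function(e) NULL)
  }
  ok <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * reps) {
    warning(n_failed, " of ", reps, " bootstrap replicates failed and were ",
            "dropped", call. = FALSE)
  }
  if (sum(ok) < 2L) {
    stop("fewer than 2 successful bootstrap replicates", call. = FALSE)
  }
  est <- do.call(rbind, draws[ok])
  se <- apply(est, 2L, stats::sd)
  attr(se, "n_failed") <- n_failed
  attr(se, "reps") <- reps
  se
}

#' Full marginal-effects analysis with bootstrap standard errors
#'
#' Fits the double hurdle on `data`, computes the marginal-effects table
#' and the unconditional expected cost, and attaches bootstrap standard
#' errors obtained by re-estimating both hurdles on each resample.
#'
#' @param data survey data frame with `dh`, `qh` and covariate columns.
#' @param h1_covariates,h2_covariates hurdle design covariate names.
#' @param covariates covariates to report effects for (default: all).
#' @param reps bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list of class `btcoi_effects`: `fit`, `table` (with `se_*`
#'   columns), `unconditional_expected_cost` and its `se`, `metadata`.
#' @export
dh_effects <- function(data, h1_covariates, h2_covariates,
                       covariates = NULL, reps = 500L, seed = 1L) {
  fit_on <- function(df) {
    fit_double_hurdle(df$dh, df$qh, build_design(df, h1_covariates),
                      build_design(df, h2_covariates))
  }
  fit <- fit_on(data)
  tab <- marginal_effects(fit, data, covariates)
  ucost <- unconditional_expected_cost(fit, data)
  estimator <- function(df) {
    f <- fit_on(df)
    if (!f$convergence$converged) stop("replicate fit did not converge")
    m <- marginal_effects(f, df, tab$covariate)
    c(stats::setNames(m$came_h1, paste0("came_h1.", m$covariate)),
      stats::setNames(m$came_h2, paste0("came_h2.", m$covariate)),
      stats::setNames(m$uame, paste0("uame.", m$covariate)),
      uncond_cost = unconditional_expected_cost(f, df))
  }
  se <- bootstrap_se(estimator, data, reps = reps, seed = seed)
  tab$se_came_h1 <- unname(se[paste0("came_h1.", tab$covariate)])
  tab$se_came_h2 <- unname(se[paste0("came_h2.", tab$covariate)])
  tab$se_uame <- unname(se[paste0("uame.", tab$covariate)])
  structure(list(fit = fit, table = tab,
                 unconditional_expected_cost = ucost,
                 unconditional_expected_cost_se = se[["uncond_cost"]],
                 metadata = list(n = nrow(data), reps = reps, seed = seed,
                                 n_failed = attr(se, "n_failed"))),
            class = "btcoi_effects")
}
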