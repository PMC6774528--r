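# Synthetic farm-survey generator. Emulates the statistical structure of a
# 2013-14 survey of cotton growers in Punjab and Sindh: household and farm
# covariates, a lab-verifiable Bt adoption status with belief
# misclassification, category-specific Bt toxin expression (ELISA, ug/g) and
# strip-test outcomes at 70 days after sowing, and a zero-inflated seasonal
# cost-of-illness outcome produced by a latent two-stage (probit +
# zero-truncated normal) process with independent hurdle errors.

default_h1_covariates <- function() {
  c("weak_bt", "true_bt", "cotton_area", "self_spray", "protective_gear",
    "off_farm", "sc_habits", "age", "education", "punjab")
}

default_h2_covariates <- function() {
  # off-farm employment enters the participation hurdle only
  setdiff(default_h1_covariates(), "off_farm")
}

default_gamma_true <- function() {
  c("(Intercept)" = 0.82, weak_bt = -0.32, true_bt = -0.68,
    cotton_area = 0.00, self_spray = 1.29, protective_gear = 0.03,
    off_farm = 0.07, sc_habits = -0.01, age = -0.01, education = -0.08,
    punjab = 0.26)
}

default_beta_true <- function() {
  c("(Intercept)" = 741.38, weak_bt = -36.46, true_bt = -95.06,
    cotton_area = 0.76, self_spray = -47.54, protective_gear = -40.46,
    sc_habits = -21.46, age = -3.72, education = -25.50, punjab = 130.49)
}

default_covariate_params <- function() {
  list(
    age = list(mean = 46.4, sd = 11.7, lower = 18, upper = 90),
    education = list(mean = 4.7, sd = 4.4, lower = 0, upper = 18),
    household_size = list(mean = 8.9, sd = 4.5, lower = 1, upper = 30),
    off_farm = list(p = 0.20),
    farm_size = list(mean = 8.4, sd = 16, lower = 0.5, upper = Inf),
    cotton_area = list(mean = 5.5, sd = 12, lower = 0.25, upper = Inf),
    self_spray = list(p = 0.60),
    # protective items worn (0-4): heavily dispersed in the field data
    protective_gear = list(probs = c(0.35, 0.12, 0.12, 0.12, 0.29)),
    sc_habits = list(p = 0.41),
    wage = list(mean = 300, sd = 75, lower = 100, upper = 800),
    pesticide = list(
      non_bt = list(mean = 2.73, sd = 1.84),
      weak_bt = list(mean = 2.29, sd = 2.12),
      true_bt = list(mean = 1.98, sd = 2.05)))
}

default_expression_params <- function() {
  # target mean/SD of the (truncated) lognormal per lab category, ug/g
  list(non_bt = list(mean = 0.37, sd = 0.47),
       weak_bt = list(mean = 0.90, sd = 0.47),
       true_bt = list(mean = 3.09, sd = 1.31))
}

#' Configuration of the synthetic-survey data-generating process
#'
#' Bundles and validates every parameter of the generator. The defaults are
#' calibrated to published descriptive statistics from a 2013-14 survey of
#' 564 cotton farmers in Punjab and Sindh: covariate moments, the pooled
#' shares of the three lab-based adoption categories, truth-conditional
#' belief-misreport rates, category-specific Bt expression distributions,
#' and double-hurdle coefficients (`gamma_true`, `beta_true`, `sigma_true`)
#' equal to the published estimates for the lab-dummy model specification.
#'
#' @param n_farmers number of survey households to generate.
#' @param seed integer seed; the generated table is a deterministic function
#'   of the full configuration including the seed.
#' @param province_share_punjab fraction of farmers in Punjab.
#' @param category_probs named probabilities for the true lab categories
#'   `non_bt`, `weak_bt`, `true_bt` (must sum to 1).
#' @param misclass list of marginal misreport probabilities: `type1_rate`
#'   (a lab-negative farmer reports Bt), `type2_rate` (a lab-positive
#'   farmer reports non-Bt) and `dontknow_rate` (the farmer answers "don't
#'   know", independent of lab status); the three draws are mutually
#'   exclusive, so `dontknow_rate + max(type1_rate, type2_rate) <= 1`.
#'   Defaults follow the pooled published cross-tab (62/112 lab-negative
#'   farmers reporting Bt, 31/452 lab-positive farmers reporting non-Bt,
#'   ~18% "don't know").
#' @param gamma_true named hurdle-1 coefficient vector (probit scale);
#'   names must be `"(Intercept)"` followed by `h1_covariates`.
#' @param beta_true named hurdle-2 coefficient vector (Rs per unit);
#'   names must be `"(Intercept)"` followed by `h2_covariates`.
#' @param sigma_true positive SD of the hurdle-2 error (Rs).
#' @param h1_covariates,h2_covariates covariate name lists for the two
#'   hurdles (off-farm employment enters hurdle 1 only by default).
#' @param expression_params per-category target mean/SD of Bt toxin
#'   expression (ug/g).
#' @param covariate_params distribution parameters per covariate
#'   (truncated normals for continuous ones, Bernoulli/categorical for
#'   dummies and counts).
#' @param threshold ELISA effectiveness threshold (ug/g) separating weak
#'   from true Bt.
#' @param n_strips strip-test tissue samples per farmer.
#' @param strip_pos_prob per-sample positive probability for Bt-positive
#'   plots (at least one positive is enforced).
#' @param indirect_share_shape Beta shape parameters for the share of the
#'   cost of illness attributable to lost work days.
#' @return a validated list of class `btcoi_dgp`.
#' @export
dgp_config <- function(n_farmers = 564L,
                       seed = 1L,
                       province_share_punjab = 435 / 564,
                       category_probs = c(non_bt = 112 / 564,
                                          weak_bt = 356 / 564,
                                          true_bt = 96 / 564),
                       misclass = list(type1_rate = 0.55,
                                       type2_rate = 0.07,
                                       dontknow_rate = 0.18),
                       gamma_true = default_gamma_true(),
                       beta_true = default_beta_true(),
                       sigma_true = 147.42,
                       h1_covariates = default_h1_covariates(),
                       h2_covariates = default_h2_covariates(),
                       expression_params = default_expression_params(),
                       covariate_params = default_covariate_params(),
                       threshold = 1.90,
                       n_strips = 2L,
                       strip_pos_prob = 0.85,
                       indirect_share_shape = c(2, 3)) {
  if (!is.numeric(n_farmers) || length(n_farmers) != 1L ||
      is.na(n_farmers) || n_farmers < 1 || n_farmers != round(n_farmers)) {
    stop("'n_farmers' must be a positive integer", call. = FALSE)
  }
  check_fraction(province_share_punjab, "province_share_punjab")
  if (length(category_probs) != 3L ||
      !setequal(names(category_probs), c("non_bt", "weak_bt", "true_bt")) ||
      any(category_probs < 0) || abs(sum(category_probs) - 1) > 1e-8) {
    stop("'category_probs' must be probabilities for non_bt/weak_bt/true_bt ",
         "summing to 1", call. = FALSE)
  }
  for (r in c("type1_rate", "type2_rate", "dontknow_rate")) {
    check_fraction(misclass[[r]], paste0("misclass$", r))
  }
  if (misclass$dontknow_rate +
      max(misclass$type1_rate, misclass$type2_rate) > 1 + 1e-12) {
    stop("'misclass' rates inconsistent: dontknow_rate + max(type1_rate, ",
         "type2_rate) must not exceed 1", call. = FALSE)
  }
  check_positive(sigma_true, "sigma_true")
  check_positive(threshold, "threshold")
  check_fraction(strip_pos_prob, "strip_pos_prob")
  if (n_strips < 1L) stop("'n_strips' must be >= 1", call. = FALSE)
  expect_g <- c("(Intercept)", h1_covariates)
  expect_b <- c("(Intercept)", h2_covariates)
  if (!identical(names(gamma_true), expect_g)) {
    stop("'gamma_true' names must be (Intercept) + h1_covariates, in order",
         call. = FALSE)
  }
  if (!identical(names(beta_true), expect_b)) {
    stop("'beta_true' names must be (Intercept) + h2_covariates, in order",
         call. = FALSE)
  }
  structure(list(n_farmers = as.integer(n_farmers), seed = as.integer(seed),
                 province_share_punjab = province_share_punjab,
                 category_probs = category_probs[c("non_bt", "weak_bt",
                                                   "true_bt")],
                 misclass = misclass, gamma_true = gamma_true,
                 beta_true = beta_true, sigma_true = sigma_true,
                 h1_covariates = h1_covariates,
                 h2_covariates = h2_covariates,
                 expression_params = expression_params,
                 covariate_params = covariate_params,
                 threshold = threshold, n_strips = as.integer(n_strips),
                 strip_pos_prob = strip_pos_prob,
                 indirect_share_shape = indirect_share_shape),
            class = "btcoi_dgp")
}

## ---- truncated lognormal calibration (Bt expression) ----

# k-th moment of a lognormal(ml, sl) truncated to [lo, hi]
tlnorm_moment <- function(k, ml, sl, lo, hi) {
  a <- if (lo <= 0) -Inf else (log(lo) - ml) / sl
  b <- if (is.infinite(hi)) Inf else (log(hi) - ml) / sl
  denom <- pnorm(b) - pnorm(a)
  exp(k * ml + k^2 * sl^2 / 2) * (pnorm(b - k * sl) - pnorm(a - k * sl)) /
    denom
}

# Find (meanlog, sdlog) so the TRUNCATED lognormal hits a target mean/SD.
# Keeps the category-conditional expression moments at their published
# values while the support stays consistent with the classification rule.
calibrate_tlnorm <- function(target_mean, target_sd, lo = 0, hi = Inf) {
  start_sl2 <- log(1 + (target_sd / target_mean)^2)
  start <- c(log(target_mean) - start_sl2 / 2, sqrt(start_sl2))
  if (lo <= 0 && is.infinite(hi)) {
    return(c(meanlog = start[1], sdlog = start[2]))
  }
  obj <- function(p) {
    sl <- exp(p[2])
    m1 <- tlnorm_moment(1, p[1], sl, lo, hi)
    m2 <- tlnorm_moment(2, p[1], sl, lo, hi)
    v <- m2 - m1^2
    if (!is.finite(m1) || !is.finite(v) || v <= 0) return(1e10)
    (m1 / target_mean - 1)^2 + (sqrt(v) / target_sd - 1)^2
  }
  fit <- stats::optim(c(start[1], log(start[2])), obj,
                      control = list(maxit = 2000L, reltol = 1e-14))
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

rtlnorm <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  u <- runif(n, plo, phi)
  q <- qlnorm(u, meanlog, sdlog)
  pmin(pmax(q, lo), hi)
}

## ---- misclassification ----

#' Turn true lab adoption categories into self-reported beliefs
#'
#' Applies truth-conditional misreporting with mutually exclusive draws:
#' with probability `dontknow_rate` a farmer answers "don't know"
#' (independently of lab status); with probability `type2_rate` a
#' lab-positive farmer (weak or true Bt) reports non-Bt and with
#' probability `type1_rate` a lab-negative farmer reports Bt; otherwise the
#' report is truthful. The rates are marginal probabilities, so
#' `dontknow_rate + max(type1_rate, type2_rate)` must not exceed 1.
#' Consumes the current RNG state.
#'
#' @param true_label character vector in `{"non_bt","weak_bt","true_bt"}`.
#' @param rates list with `type1_rate`, `type2_rate`, `dontknow_rate`.
#' @return character vector of beliefs in `{"bt","non_bt","dont_know"}`.
#' @export
apply_misclassification <- function(true_label, rates) {
  for (r in c("type1_rate", "type2_rate", "dontknow_rate")) {
    check_fraction(rates[[r]], paste0("rates$", r))
  }
  if (rates$dontknow_rate +
      max(rates$type1_rate, rates$type2_rate) > 1 + 1e-12) {
    stop("rates inconsistent: dontknow_rate + max(type1_rate, type2_rate) ",
         "must not exceed 1", call. = FALSE)
  }
  if (!all(true_label %in% c("non_bt", "weak_bt", "true_bt"))) {
    stop("unknown true adoption label", call. = FALSE)
  }
  n <- length(true_label)
  lab_pos <- true_label != "non_bt"
  belief <- ifelse(lab_pos, "bt", "non_bt")
  u <- runif(n)
  flip_rate <- ifelse(lab_pos, rates$type2_rate, rates$type1_rate)
  dk <- u < rates$dontknow_rate
  flipped <- !dk & u < rates$dontknow_rate + flip_rate
  belief[flipped & lab_pos] <- "non_bt"
  belief[flipped & !lab_pos] <- "bt"
  belief[dk] <- "dont_know"
  belief
}

#' Solve truth-conditional misreport rates from belief-conditional targets
#'
#' Survey error rates are naturally reported conditional on the *belief*
#' (e.g. "17% of self-reported Bt users were lab-negative") while the
#' generator misreports conditional on the *true* lab status. Given the
#' lab-positive share `p_labpos` and the two belief-conditional targets,
#' this solves the 2x2 linear system for the conditional-on-answered
#' misreport probabilities and scales them by `1 - dontknow_rate` into the
#' marginal `type1_rate` / `type2_rate` that [dgp_config()] expects
#' ("don't know" answers are assigned independently of lab status and
#' therefore drop out of the belief-conditional rates).
#'
#' @param p_labpos fraction of farmers whose plots are lab-positive.
#' @param type1_belief target P(lab-negative | belief = Bt).
#' @param type2_belief target P(lab-positive | belief = non-Bt).
#' @param dontknow_rate marginal "don't know" rate of the target
#'   configuration (default 0).
#' @return list with `type1_rate` and `type2_rate` (marginal rates).
#' @export
calibrate_misclassification <- function(p_labpos, type1_belief,
                                        type2_belief, dontknow_rate = 0) {
  check_fraction(p_labpos, "p_labpos")
  check_fraction(type1_belief, "type1_belief")
  check_fraction(type2_belief, "type2_belief")
  check_fraction(dontknow_rate, "dontknow_rate")
  p <- p_labpos
  t1 <- type1_belief
  t2 <- type2_belief
  A <- rbind(c((1 - p) * (1 - t1), t1 * p),
             c(t2 * (1 - p), p * (1 - t2)))
  rhs <- c(t1 * p, t2 * (1 - p))
  ab <- solve(A, rhs)
  if (any(ab < -1e-9) || any(ab > 1 + 1e-9)) {
    stop("belief-conditional targets are infeasible for p_labpos = ",
         format(p), call. = FALSE)
  }
  list(type1_rate = min(max(ab[1], 0), 1) * (1 - dontknow_rate),
       type2_rate = min(max(ab[2], 0), 1) * (1 - dontknow_rate))
}

## ---- latent health-cost process ----

#' Simulate the two-stage cost-of-illness outcome
#'
#' Draws the treatment indicator from the probit hurdle,
#' \eqn{dh = 1(\gamma x + \mu > 0)} with \eqn{\mu \sim N(0,1)}, and -- for
#' farmers who cross it -- the positive cost from the normal
#' \eqn{N(\beta z, \sigma^2)} truncated at zero, so `qh > 0` exactly when
#' `dh = 1` (the corner-solution rule). Consumes the current RNG state.
#'
#' @param X hurdle-1 design matrix (intercept first column).
#' @param Z hurdle-2 design matrix (intercept first column).
#' @param gamma_true,beta_true coefficient vectors conformable with `X`,
#'   `Z`.
#' @param sigma_true positive hurdle-2 error SD (Rs); the degenerate limit
#'   `sigma_true -> 0` collapses `qh` to `max(beta z, 0)`-type values.
#' @return data.frame with columns `dh` (0/1) and `qh` (Rs).
#' @export
simulate_health_outcome <- function(X, Z, gamma_true, beta_true,
                                    sigma_true) {
  check_positive(sigma_true, "sigma_true", strict = FALSE)
  eta1 <- drop(X %*% gamma_true)
  eta2 <- drop(Z %*% beta_true)
  n <- length(eta1)
  mu <- rnorm(n)
  dh <- as.numeric(eta1 + mu > 0)
  qh <- numeric(n)
  pos <- dh == 1
  if (any(pos)) {
    q <- rtruncnorm(sum(pos), mean = eta2[pos], sd = sigma_true, lower = 0)
    q[!is.finite(q)] <- pmax(eta2[pos], 0)[!is.finite(q)] + 1e-9
    qh[pos] <- pmax(q, .Machine$double.xmin)
  }
  data.frame(dh = dh, qh = qh)
}

## ---- the generator ----

#' Generate a synthetic farm survey
#'
#' Produces one row per farmer: province and household covariates, the true
#' lab-based adoption category with consistent strip-test and ELISA
#' expression outcomes, a self-reported belief with configurable
#' misclassification, pesticide use, the latent-model cost-of-illness
#' outcome (`dh`, `qh`), and a decomposition of `qh` into treatment cost
#' components (self-treatment, consultation, medication, travel) plus lost
#' work days valued at the farmer's wage, such that rebuilding the outcome
#' from the components recovers (`dh`, `qh`).
#'
#' The output is a deterministic function of the configuration (including
#' its seed).
#'
#' @param config a [dgp_config()] object.
#' @return data.frame with one row per farmer.
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "btcoi_dgp")) {
    config <- do.call(dgp_config, config)
  }
  set.seed(config$seed)
  n <- config$n_farmers
  cp <- config$covariate_params

  province <- ifelse(runif(n) < config$province_share_punjab,
                     "punjab", "sindh")
  punjab <- as.numeric(province == "punjab")
  age <- rtruncnorm(n, cp$age$mean, cp$age$sd, cp$age$lower, cp$age$upper)
  education <- rtruncnorm(n, cp$education$mean, cp$education$sd,
                          cp$education$lower, cp$education$upper)
  household_size <- round(rtruncnorm(n, cp$household_size$mean,
                                     cp$household_size$sd,
                                     cp$household_size$lower,
                                     cp$household_size$upper))
  off_farm <- as.numeric(runif(n) < cp$off_farm$p)
  farm_size <- rtruncnorm(n, cp$farm_size$mean, cp$farm_size$sd,
                          cp$farm_size$lower, cp$farm_size$upper)
  cotton_area <- pmin(rtruncnorm(n, cp$cotton_area$mean, cp$cotton_area$sd,
                                 cp$cotton_area$lower, cp$cotton_area$upper),
                      farm_size)
  self_spray <- as.numeric(runif(n) < cp$self_spray$p)
  protective_gear <- sample(0:4, n, replace = TRUE,
                            prob = cp$protective_gear$probs)
  sc_habits <- as.numeric(runif(n) < cp$sc_habits$p)

  true_category <- sample(names(config$category_probs), n, replace = TRUE,
                          prob = config$category_probs)
  weak_bt <- as.numeric(true_category == "weak_bt")
  true_bt <- as.numeric(true_category == "true_bt")

  # strip tests: all negative for non-Bt plots; at least one positive
  # (enforced) for Bt-positive plots
  strips <- matrix(0L, nrow = n, ncol = config$n_strips)
  pos_plot <- true_category != "non_bt"
  if (any(pos_plot)) {
    draws <- matrix(rbinom(sum(pos_plot) * config$n_strips, 1L,
                           config$strip_pos_prob),
                    nrow = sum(pos_plot))
    none <- rowSums(draws) == 0L
    if (any(none)) {
      fix_col <- sample.int(config$n_strips, sum(none), replace = TRUE)
      draws[cbind(which(none), fix_col)] <- 1L
    }
    strips[pos_plot, ] <- draws
  }
  colnames(strips) <- paste0("strip_", seq_len(config$n_strips))

  # Bt expression: per-category (truncated) lognormal with moments matched
  # to the configured targets on the truncated support
  ep <- config$expression_params
  thr <- config$threshold
  pars <- list(
    non_bt = calibrate_tlnorm(ep$non_bt$mean, ep$non_bt$sd, 0, Inf),
    weak_bt = calibrate_tlnorm(ep$weak_bt$mean, ep$weak_bt$sd, 0, thr),
    true_bt = calibrate_tlnorm(ep$true_bt$mean, ep$true_bt$sd, thr, Inf))
  bounds <- list(non_bt = c(0, Inf), weak_bt = c(0, thr),
                 true_bt = c(thr, Inf))
  bt_expression <- numeric(n)
  for (cat in names(pars)) {
    idx <- true_category == cat
    if (any(idx)) {
      bt_expression[idx] <- rtlnorm(sum(idx), pars[[cat]]["meanlog"],
                                    pars[[cat]]["sdlog"],
                                    bounds[[cat]][1], bounds[[cat]][2])
    }
  }

  pesticide_qty <- numeric(n)
  for (cat in c("non_bt", "weak_bt", "true_bt")) {
    idx <- true_category == cat
    if (any(idx)) {
      pesticide_qty[idx] <- rtruncnorm(sum(idx), cp$pesticide[[cat]]$mean,
                                       cp$pesticide[[cat]]$sd, lower = 0)
    }
  }

  belief <- apply_misclassification(true_category, config$misclass)

  covars <- data.frame(age = age, education = education,
                       household_size = household_size, off_farm = off_farm,
                       farm_size = farm_size, cotton_area = cotton_area,
                       self_spray = self_spray,
                       protective_gear = protective_gear,
                       sc_habits = sc_habits, punjab = punjab,
                       weak_bt = weak_bt, true_bt = true_bt)
  X <- build_design(covars, config$h1_covariates)
  Z <- build_design(covars, config$h2_covariates)
  outcome <- simulate_health_outcome(X, Z, config$gamma_true,
                                     config$beta_true, config$sigma_true)

  # decompose qh into cost components so the accounting round-trips
  wage <- rtruncnorm(n, cp$wage$mean, cp$wage$sd, cp$wage$lower,
                     cp$wage$upper)
  ish <- rbeta(n, config$indirect_share_shape[1],
               config$indirect_share_shape[2])
  indirect <- outcome$qh * ish
  days_lost <- indirect / wage
  direct <- outcome$qh - indirect
  w <- matrix(rgamma(4 * n, shape = 1), nrow = n)
  w <- w / rowSums(w)
  comp <- direct * w

  out <- data.frame(farmer_id = sprintf("F%05d", seq_len(n)),
                    province = province, covars,
                    true_category = true_category, belief = belief,
                    strips, bt_expression = bt_expression,
                    pesticide_qty = pesticide_qty,
                    self_treatment = comp[, 1], consultation = comp[, 2],
                    medication = comp[, 3], travel = comp[, 4],
                    days_lost = days_lost, wage = wage,
                    dh = outcome$dh, qh = outcome$qh,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
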