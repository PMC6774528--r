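# Shared fixtures: small data-generating helpers used across test files.

# Simple hurdle data with a compact design shared by both hurdles.
make_dh_data <- function(n = 800, seed = 1,
                         gamma = c(0.5, 0.6, -0.7, 0.4),
                         beta = c(300, 80, -120, 60),
                         sigma = 150) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = runif(n), d1 = rbinom(n, 1, 0.4))
  Z <- build_design(d, c("x1", "x2", "d1"))
  out <- simulate_health_outcome(Z, Z, gamma, beta, sigma)
  list(data = d, X = Z, Z = Z, dh = out$dh, qh = out$qh,
       gamma = gamma, beta = beta, sigma = sigma)
}

# Tobit-true data: one index drives both censoring and level.
make_tobit_data <- function(n = 400, seed = 1,
                            beta = c(120, 40, -60, 30), sigma = 150) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = runif(n), d1 = rbinom(n, 1, 0.5))
  Z <- build_design(d, c("x1", "x2", "d1"))
  y <- pmax(0, drop(Z %*% beta) + rnorm(n, 0, sigma))
  list(data = d, Z = Z, y = y, beta = beta, sigma = sigma)
}

# Central-difference numerical gradient.
num_grad <- function(fn, theta, h = 1e-6) {
  vapply(seq_along(theta), function(j) {
    hp <- hm <- theta
    step <- h * max(1, abs(theta[j]))
    hp[j] <- hp[j] + step
    hm[j] <- hm[j] - step
    (fn(hp) - fn(hm)) / (2 * step)
  }, numeric(1))
}
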