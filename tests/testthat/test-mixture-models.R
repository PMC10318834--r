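# simulate from the ALDVMM generative model: latent normal per component,
# censored to 1 above psi and to the floor below it
sim_aldvmm <- function(X, beta, sigma, pi_k, psi, floor_u, seed) {
  set.seed(seed)
  n <- nrow(X)
  K <- length(sigma)
  comp <- sample.int(K, n, replace = TRUE, prob = pi_k)
  mu <- vapply(seq_len(K), function(k) drop(X %*% beta[, k]), numeric(n))
  z <- rnorm(n, mu[cbind(seq_len(n), comp)], sigma[comp])
  y <- ifelse(z > psi, 1, ifelse(z < floor_u, floor_u, z))
  y
}

sim_betamix <- function(X, gamma, delta, phi, bounds, seed) {
  set.seed(seed)
  n <- nrow(X)
  p1 <- plogis(drop(X %*% gamma))
  at_one <- runif(n) < p1
  mu <- plogis(drop(X %*% delta))
  ystar <- rbeta(n, mu * phi, (1 - mu) * phi)
  y <- bounds[1] + (bounds[2] - bounds[1]) * ystar
  ifelse(at_one, 1, y)
}

psi_cn <- 1 - min(vs_cn$decrements[, 2])  # largest feasible utility < 1

test_that("ALDVMM with one component and no boundary mass tracks OLS", {
  d <- sim_linear(800, c(0.3, 0.2, 0.05, 0.05, 0.05, 0.05), sd = 0.05,
                  seed = 101)
  fit <- fit_aldvmm(d$X, d$y, K = 1, psi = 2, floor = -2, vs = vs_cn,
                    n_starts = 4, seed = 3)
  ols <- fit_ols(d$X, d$y)
  expect_lt(max(abs(fit$beta[, 1] - ols$coefficients)), 0.01)
})

test_that("ALDVMM recovers a 2-component generating process at n = 5000", {
  sc <- make_scores(5000, 111)
  X <- build_design(sc)
  beta_true <- cbind(c(0.45, 0.15, 0.02, 0.03, 0.05, 0.08),
                     c(0.75, 0.30, 0.04, 0.05, 0.08, 0.10))
  sigma_true <- c(0.16, 0.05)
  pi_true <- c(0.35, 0.65)
  y <- sim_aldvmm(X, beta_true, sigma_true, pi_true, psi_cn, -0.391,
                  seed = 112)
  expect_gt(mean(y == 1), 0.1)  # real ceiling mass present
  fit <- fit_aldvmm(X, y, K = 2, vs = vs_cn, n_starts = 8, seed = 5)
  expect_lt(max(abs(fit$beta - beta_true)), 0.08)
  expect_lt(max(abs(fit$sigma - sigma_true)), 0.02)
  expect_lt(max(abs(fit$pi - pi_true)), 0.05)
})

test_that("gap observations are rejected and predictions stay in bounds", {
  sc <- make_scores(50, 121)
  X <- build_design(sc)
  expect_error(fit_aldvmm(X, rep(c(0.98, 0.5), 25), vs = vs_cn,
                          n_starts = 2),
               class = "saqmap_validation_error")
  y <- sim_aldvmm(X, cbind(rep(0.5, 6), rep(0.9, 6)), c(0.2, 0.1),
                  c(0.5, 0.5), psi_cn, -0.391, seed = 122)
  fit <- fit_aldvmm(X, y, K = 1, vs = vs_cn, n_starts = 3, seed = 1)
  pred <- predict(fit, X)
  expect_true(all(pred <= 1 & pred >= -0.391))
})

test_that("ALDVMM expected value matches a brute-force sampling oracle", {
  sc <- make_scores(30, 131)
  X <- build_design(sc)
  beta_true <- cbind(c(0.45, 0.15, 0.02, 0.03, 0.05, 0.08),
                     c(0.78, 0.25, 0.04, 0.05, 0.08, 0.10))
  y <- sim_aldvmm(X, beta_true, c(0.15, 0.05), c(0.4, 0.6), psi_cn,
                  -0.391, seed = 132)
  fit <- fit_aldvmm(build_design(make_scores(2000, 133)),
                    sim_aldvmm(build_design(make_scores(2000, 133)),
                               beta_true, c(0.15, 0.05), c(0.4, 0.6),
                               psi_cn, -0.391, seed = 134),
                    K = 2, vs = vs_cn, n_starts = 6, seed = 7)
  x0 <- X[1, , drop = FALSE]
  pred <- predict(fit, x0)
  draws <- sim_aldvmm(x0[rep(1, 1e6), , drop = FALSE], fit$beta,
                      fit$sigma, fit$pi, fit$psi, fit$floor, seed = 135)
  mc_se <- sd(draws) / sqrt(1e6)
  expect_lt(abs(pred - mean(draws)), 3 * mc_se)
})

test_that("beta mixture recovers a one-inflated beta process at n = 5000", {
  sc <- make_scores(5000, 141)
  X <- build_design(sc)
  gamma_true <- c(-4.0, 2.0, 0.6, 0.8, 0.8, 2.5)
  delta_true <- c(-0.8, 2.0, 0.25, 0.35, 0.35, 0.8)
  phi_true <- 18
  y <- sim_betamix(X, gamma_true, delta_true, phi_true, c(-0.391, 1),
                   seed = 142)
  fit <- fit_betamix(X, y, C = 1, vs = vs_cn, n_starts = 6, seed = 9)
  expect_lt(max(abs(fit$gamma - gamma_true)), 0.6)
  expect_lt(max(abs(fit$delta[, 1] - delta_true)), 0.15)
  expect_lt(abs(fit$phi - phi_true) / phi_true, 0.10)
})

test_that("symmetric uninformative rescaled responses give a ~0 mean link", {
  set.seed(151)
  n <- 3000
  X <- cbind("(Intercept)" = rep(1, n))
  ystar <- rbeta(n, 8, 8)  # symmetric around 0.5
  y <- -0.391 + 1.391 * ystar
  fit <- fit_betamix(X, y, C = 1, bounds = c(-0.391, 1), vs = vs_cn,
                     n_starts = 4, seed = 2)
  expect_lt(abs(fit$delta[1, 1]), 0.05)
})

test_that("beta mixture predictions respect the ceiling and bounds", {
  sc <- make_scores(1000, 161)
  X <- build_design(sc)
  y <- sim_betamix(X, c(-4, 2, 0.6, 0.8, 0.8, 2.5),
                   c(-0.8, 2, 0.25, 0.35, 0.35, 0.8), 18, c(-0.391, 1),
                   seed = 162)
  fit <- fit_betamix(X, y, vs = vs_cn, n_starts = 4, seed = 4)
  pred <- predict(fit, X)
  expect_true(all(pred <= 1 & pred >= -0.391))
  # continuous-part means strictly inside the bounds
  mu <- plogis(drop(X %*% fit$delta[, 1]))
  expect_true(all(mu > 0 & mu < 1))
  # ceiling limit: forcing p1 -> 1 drives the prediction to 1
  fit2 <- fit
  fit2$gamma <- c(50, 0, 0, 0, 0, 0)
  expect_equal(unname(predict(fit2, X)), rep(1, 1000), tolerance = 1e-10)
})

test_that("beta mixture expected value matches a sampling oracle", {
  sc <- make_scores(1500, 171)
  X <- build_design(sc)
  y <- sim_betamix(X, c(-4, 2, 0.6, 0.8, 0.8, 2.5),
                   c(-0.8, 2, 0.25, 0.35, 0.35, 0.8), 18, c(-0.391, 1),
                   seed = 172)
  fit <- fit_betamix(X, y, vs = vs_cn, n_starts = 4, seed = 4)
  x0 <- X[7, , drop = FALSE]
  draws <- sim_betamix(x0[rep(1, 1e6), , drop = FALSE], fit$gamma,
                       fit$delta[, 1], fit$phi,
                       fit$bounds, seed = 173)
  mc_se <- sd(draws) / sqrt(1e6)
  expect_lt(abs(predict(fit, x0) - mean(draws)), 3 * mc_se)
})

test_that("mixture log-likelihood matches a naive oracle and is additive", {
  sc <- make_scores(400, 181)
  X <- build_design(sc)
  beta_true <- cbind(c(0.5, 0.2, 0.03, 0.04, 0.06, 0.09),
                     c(0.8, 0.25, 0.04, 0.05, 0.08, 0.10))
  y <- sim_aldvmm(X, beta_true, c(0.15, 0.05), c(0.4, 0.6), psi_cn,
                  -0.391, seed = 182)
  fit <- fit_aldvmm(X, y, K = 2, vs = vs_cn, n_starts = 5, seed = 11)
  # naive unvectorised oracle
  oracle <- 0
  for (i in seq_along(y)) {
    li <- 0
    for (k in 1:2) {
      mu <- sum(X[i, ] * fit$beta[, k])
      s <- fit$sigma[k]
      contrib <- if (y[i] == 1) {
        1 - pnorm((fit$psi - mu) / s)
      } else if (y[i] == fit$floor) {
        pnorm((fit$floor - mu) / s)
      } else {
        dnorm((y[i] - mu) / s) / s
      }
      li <- li + fit$pi[k] * contrib
    }
    oracle <- oracle + log(li)
  }
  ll <- mixture_loglik(fit, X, y)
  expect_equal(ll, oracle, tolerance = 1e-8)
  expect_equal(mixture_loglik(fit, rbind(X, X), c(y, y)), 2 * ll,
               tolerance = 1e-8)
  expect_equal(ll, fit$loglik, tolerance = 1e-6)
})

test_that("fitted parameters are a local optimum of the likelihood", {
  sc <- make_scores(600, 191)
  X <- build_design(sc)
  y <- sim_aldvmm(X, cbind(c(0.6, 0.2, 0.03, 0.04, 0.06, 0.09)),
                  0.12, 1, psi_cn, -0.391, seed = 192)
  fit <- fit_aldvmm(X, y, K = 1, vs = vs_cn, n_starts = 4, seed = 13)
  ll0 <- mixture_loglik(fit, X, y)
  set.seed(193)
  for (r in 1:100) {
    pert <- fit
    pert$beta <- fit$beta + matrix(rnorm(6, 0, 0.02), ncol = 1)
    pert$sigma <- fit$sigma * exp(rnorm(1, 0, 0.05))
    expect_lte(mixture_loglik(pert, X, y), ll0 + 1e-6)
  }
})

test_that("more starts never lower the best log-likelihood; K=2 >= K=1", {
  sc <- make_scores(800, 201)
  X <- build_design(sc)
  y <- sim_aldvmm(X, cbind(c(0.45, 0.15, 0.02, 0.03, 0.05, 0.08),
                           c(0.75, 0.3, 0.04, 0.05, 0.08, 0.10)),
                  c(0.16, 0.05), c(0.35, 0.65), psi_cn, -0.391, seed = 202)
  f1 <- fit_aldvmm(X, y, K = 2, vs = vs_cn, n_starts = 1, seed = 17)
  f5 <- fit_aldvmm(X, y, K = 2, vs = vs_cn, n_starts = 5, seed = 17)
  expect_gte(f5$loglik, f1$loglik - 1e-6)
  k1 <- fit_aldvmm(X, y, K = 1, vs = vs_cn, n_starts = 4, seed = 17)
  expect_gte(f5$loglik, k1$loglik - 1e-6)
})

test_that("predictions are invariant to component relabelling", {
  sc <- make_scores(500, 211)
  X <- build_design(sc)
  y <- sim_aldvmm(X, cbind(c(0.45, 0.15, 0.02, 0.03, 0.05, 0.08),
                           c(0.75, 0.3, 0.04, 0.05, 0.08, 0.10)),
                  c(0.16, 0.05), c(0.35, 0.65), psi_cn, -0.391, seed = 212)
  fit <- fit_aldvmm(X, y, K = 2, vs = vs_cn, n_starts = 5, seed = 19)
  swapped <- fit
  swapped$beta <- fit$beta[, 2:1]
  swapped$sigma <- fit$sigma[2:1]
  swapped$pi <- fit$pi[2:1]
  expect_equal(predict(swapped, X), predict(fit, X), tolerance = 1e-12)
})
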