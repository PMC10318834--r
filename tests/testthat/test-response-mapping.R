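# simulate proportional-odds levels: logit P(Y<=j) = cut_j - x'beta
sim_polr <- function(X, beta, cuts, seed) {
  set.seed(seed)
  eta <- drop(X %*% beta)
  u <- runif(nrow(X))
  lv <- rep(1L, nrow(X))
  for (j in seq_along(cuts)) {
    lv <- lv + as.integer(u > plogis(cuts[j] - eta))
  }
  lv
}

make_states <- function(Xr, seed) {
  beta_d <- list(mo = c(-3, -0.4, -0.3, -0.5, 0.3),
                 sc = c(-2.5, -0.2, -0.5, -0.3, 0.5),
                 ua = c(-2.8, -0.3, -0.4, -0.6, 0.1),
                 pd = c(-1.5, -0.5, -0.5, -0.8, -1.2),
                 ad = c(-0.4, -0.3, -0.5, 0.4, -2.2))
  cuts_d <- list(mo = c(-3.2, -1.5, 0.2), sc = c(-1.8, -0.5, 0.6),
                 ua = c(-3.0, -1.4, 0.1), pd = c(-3.5, -1.8, -0.2),
                 ad = c(-2.2, -0.8, 0.8))
  st <- as.data.frame(lapply(seq_along(beta_d), function(i) {
    sim_polr(Xr, beta_d[[i]], cuts_d[[i]], seed + i)
  }))
  names(st) <- eq5d_dimensions()
  st
}

test_that("proportional-odds parameters are recovered at n = 5000", {
  beta_true <- c(-3, -0.4, -0.3, -0.5, 0.3)
  cuts_true <- c(-3.4, -1.6, 0.2, 1.4)
  checks <- unlist(lapply(1:6, function(r) {
    Xr <- build_design(make_scores(5000, 700 + r), intercept = FALSE)
    lv <- sim_polr(Xr, beta_true, cuts_true, 800 + r)
    st <- data.frame(mo = lv, sc = rep(1:2, 2500), ua = rep(1:2, 2500),
                     pd = rep(1:2, 2500), ad = rep(1:2, 2500))
    fit <- fit_response_models(Xr, st)$models$mo
    se <- sqrt(diag(fit$vcov))
    est <- c(fit$beta, fit$cuts)
    abs(est - c(beta_true, cuts_true)) <= 2 * se
  }))
  expect_gte(mean(checks), 0.85)
})

test_that("an intercept-only model reproduces empirical category shares", {
  # with beta = 0 the cuts sit at the logit of the cumulative frequencies;
  # feed that model through the prediction path and compare to the shares
  shares <- c(0.45, 0.30, 0.15, 0.10)
  cuts <- qlogis(cumsum(shares))[1:3]
  model <- structure(list(
    models = setNames(lapply(eq5d_dimensions(), function(d) {
      list(dimension = d, type = "ordered",
           beta = setNames(rep(0, 5), saq_subscales()),
           cuts = cuts, category_levels = 1:4,
           convergence = list(converged = TRUE, separation = FALSE))
    }), eq5d_dimensions()),
    columns = saq_subscales(), type = "ordered"),
    class = "saq_response_fit")
  Xr <- build_design(make_scores(10, 901), intercept = FALSE)
  probs <- predict(model, Xr)
  for (d in eq5d_dimensions()) {
    expect_equal(unname(probs[[d]][1, 1:4]), shares, tolerance = 1e-12)
    expect_equal(unname(probs[[d]][, 5]), rep(0, 10))
  }
})

test_that("health-improving subscales get negative severity coefficients", {
  cal <- default_calibration()
  co <- generate_cohort(default_cfg, vs_cn, seed = 5, calibration = cal)
  Xr <- build_design(co, intercept = FALSE)
  fit <- fit_response_models(Xr, co[eq5d_dimensions()])
  # in each dimension the dominant loadings should be negative: higher
  # subscale scores mean fewer problems, i.e. lower levels
  for (d in c("mo", "ua", "pd", "ad")) {
    expect_lt(sum(fit$models[[d]]$beta), 0)
  }
})

test_that("predicted probabilities telescope to 1 and respect limits", {
  Xr <- build_design(make_scores(200, 911), intercept = FALSE)
  st <- make_states(Xr, 912)
  fit <- fit_response_models(Xr, st)
  probs <- predict(fit, Xr)
  for (d in eq5d_dimensions()) {
    expect_equal(rowSums(probs[[d]]), rep(1, 200), tolerance = 1e-12)
    expect_true(all(probs[[d]] >= 0))
  }
  # limit: an extreme positive index puts all mass on the lowest category
  m <- fit$models$mo
  hi <- matrix(0, 1, 5, dimnames = list(NULL, saq_subscales()))
  hi[1, ] <- ifelse(m$beta < 0, 1, 0)  # drive x'beta very negative
  hi_prob <- saqmap:::ordered_probs(m$beta * 50, m$cuts, hi)
  expect_equal(hi_prob[1, 1], 1, tolerance = 1e-6)
})

test_that("predicted probabilities equal the scalar logistic formula", {
  Xr <- build_design(make_scores(5, 921), intercept = FALSE)
  st <- make_states(build_design(make_scores(300, 922),
                                 intercept = FALSE), 923)
  fit <- fit_response_models(build_design(make_scores(300, 922),
                                          intercept = FALSE), st)
  probs <- predict(fit, Xr)
  for (d in eq5d_dimensions()) {
    m <- fit$models[[d]]
    for (i in 1:5) {
      eta <- sum(Xr[i, ] * m$beta)
      cum <- c(plogis(m$cuts - eta), 1)
      hand <- diff(c(0, cum))
      expect_equal(unname(probs[[d]][i, m$category_levels]), hand,
                   tolerance = 1e-10)
    }
  }
})

test_that("collapsed categories keep zero mass and exact renormalisation", {
  Xr <- build_design(make_scores(400, 931), intercept = FALSE)
  st <- make_states(Xr, 932)
  st[] <- lapply(st, function(v) pmin(v, 3L))  # collapse levels 4,5 away
  fit <- fit_response_models(Xr, st)
  probs <- predict(fit, Xr)
  for (d in eq5d_dimensions()) {
    expect_equal(unname(probs[[d]][, 4:5]),
                 matrix(0, nrow = 400, ncol = 2))
    expect_equal(rowSums(probs[[d]]), rep(1, 400), tolerance = 1e-12)
  }
})

test_that("single observed category is rejected", {
  Xr <- build_design(make_scores(50, 941), intercept = FALSE)
  st <- make_states(Xr, 942)
  st$sc <- 1L
  expect_error(fit_response_models(Xr, st),
               class = "saqmap_validation_error")
})

test_that("expected utility: boundary cases and method agreement", {
  one_hot <- function(level) {
    pm <- matrix(0, 1, 5)
    pm[1, level] <- 1
    pm
  }
  full <- setNames(lapply(1:5, function(i) one_hot(1)), eq5d_dimensions())
  expect_equal(expected_utility(full, vs_cn), 1)
  worst <- setNames(lapply(1:5, function(i) one_hot(5)), eq5d_dimensions())
  expect_equal(expected_utility(worst, vs_cn), -0.391)

  # closed form vs monte-carlo oracle at a non-degenerate probability row
  set.seed(951)
  probs <- setNames(lapply(1:5, function(i) {
    p <- rexp(5)
    matrix(p / sum(p), 1, 5)
  }), eq5d_dimensions())
  ed <- expected_utility(probs, vs_cn)
  draws <- 1e6
  mc <- expected_utility(probs, vs_cn, method = "monte-carlo",
                         draws = draws, seed = 99)
  # MC standard error of the utility mean, bounded by the utility range
  mc_se <- 1.391 / 2 / sqrt(draws)
  expect_lt(abs(ed - mc), 3 * mc_se)

  # modal method scores the argmax state
  expect_equal(expected_utility(full, vs_cn, method = "modal"), 1)
})

test_that("expected utility is monotone under better-level mass shifts", {
  set.seed(961)
  for (r in 1:20) {
    probs <- setNames(lapply(1:5, function(i) {
      p <- rexp(5)
      matrix(p / sum(p), 1, 5)
    }), eq5d_dimensions())
    d <- sample(eq5d_dimensions(), 1)
    worse_l <- sample(2:5, 1)
    shift <- probs[[d]][1, worse_l] * runif(1)
    better <- probs
    better[[d]][1, worse_l] <- better[[d]][1, worse_l] - shift
    better[[d]][1, worse_l - 1] <- better[[d]][1, worse_l - 1] + shift
    expect_gte(expected_utility(better, vs_cn),
               expected_utility(probs, vs_cn))
  }
})

test_that("invalid probability rows are rejected", {
  bad <- setNames(lapply(1:5, function(i) matrix(0.3, 1, 5)),
                  eq5d_dimensions())
  expect_error(expected_utility(bad, vs_cn),
               class = "saqmap_validation_error")
})

test_that("multinomial sensitivity variant produces valid probabilities", {
  Xr <- build_design(make_scores(400, 971), intercept = FALSE)
  st <- make_states(Xr, 972)
  fit <- fit_response_models(Xr, st, type = "multinomial")
  probs <- predict(fit, Xr)
  for (d in eq5d_dimensions()) {
    expect_equal(rowSums(probs[[d]]), rep(1, 400), tolerance = 1e-6)
  }
})
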