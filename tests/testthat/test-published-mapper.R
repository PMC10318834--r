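table1_means <- data.frame(pl = 70.83, as = 36.18, af = 64.55,
                           ts = 67.69, dp = 51.80)

test_that("published direct equations reproduce the printed mean predictions", {
  # evaluating each published column at the mean subscale profile must
  # reproduce the corresponding printed full-sample mean prediction
  expect_equal(map_direct(table1_means, "ols"), 0.8725, tolerance = 5e-4)
  expect_equal(map_direct(table1_means, "tobit"), 0.9090, tolerance = 5e-4)
  expect_equal(map_direct(table1_means, "rmm"), 0.9008, tolerance = 5e-4)
})

test_that("the log-link equation shows the expected Jensen gap at the means", {
  # exp(mean index) sits below the printed mean prediction of 0.8729 —
  # a consistency note on the published GLM column, not an equality
  glm_at_means <- map_direct(table1_means, "glm")
  expect_equal(glm_at_means, 0.866, tolerance = 1e-3)
  expect_lt(glm_at_means, 0.8729)
})

test_that("zero scores return the printed constants", {
  zero <- data.frame(pl = 0, as = 0, af = 0, ts = 0, dp = 0)
  expect_equal(map_direct(zero, "ols"), 0.3046)
  expect_equal(map_direct(zero, "tobit"), 0.1855)
  expect_equal(map_direct(zero, "clad"), 0.4421)
  expect_equal(map_direct(zero, "glm"), exp(-0.7661))
})

test_that("direct equations are affine: differences scale with scores", {
  pub <- published_coefficients()$direct$ols
  s1 <- table1_means
  s2 <- table1_means
  s2$pl <- s2$pl + 10
  # +10 points of PL must move the OLS utility by exactly 10/100 * beta_pl
  expect_equal(map_direct(s2, "ols") - map_direct(s1, "ols"),
               0.1 * pub$pl, tolerance = 1e-12)
  # linearity in a second subscale simultaneously
  s3 <- s2
  s3$dp <- s3$dp - 20
  expect_equal(map_direct(s3, "ols") - map_direct(s1, "ols"),
               0.1 * pub$pl - 0.2 * pub$dp, tolerance = 1e-12)
})

test_that("published coefficients round-trip through JSON bit-exactly", {
  pub <- published_coefficients()
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(pub, tf, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_identical(back$direct, pub$direct)
  expect_identical(back$indirect, pub$indirect)
  expect_identical(back$mixture, pub$mixture)
  # spot-check stored values against the printed tables
  expect_identical(pub$direct$ols$pl, 0.5271)
  expect_identical(pub$mixture$bm$pm_ub$dp, 10.2317)
  expect_identical(pub$indirect$mo$cuts, c(-10.2116, -6.5813, -3.3392))
})

test_that("published beta-mixture column evaluates per the two-part formula", {
  # hand evaluation of the printed coefficients at the mean profile
  x <- unlist(table1_means) / 100
  pub <- published_coefficients()$mixture$bm
  p1 <- plogis(pub$pm_ub$constant + sum(unlist(pub$pm_ub[names(x)]) * x))
  mu <- plogis(pub$c1_mu$constant + sum(unlist(pub$c1_mu[names(x)]) * x))
  hand <- p1 + (1 - p1) * (-0.391 + 1.391 * mu)
  expect_equal(map_direct_mixture(table1_means, "bm"), hand,
               tolerance = 1e-12)
  expect_lte(map_direct_mixture(table1_means, "bm"), 1)

  # ceiling limit: perfect scores drive the inflation probability up and
  # the prediction towards (but never past) 1
  perfect <- data.frame(pl = 100, as = 100, af = 100, ts = 100, dp = 100)
  u_hi <- map_direct_mixture(perfect, "bm")
  expect_gt(u_hi, 0.99)
  expect_lte(u_hi, 1)
  # continuous-part mean strictly inside the rescaling bounds
  mu_hi <- plogis(pub$c1_mu$constant + sum(unlist(pub$c1_mu[names(x)])))
  expect_true(mu_hi > 0 && mu_hi < 1)
})

test_that("published ALDVMM column demands the unprinted parameters", {
  expect_error(map_direct_mixture(table1_means, "aldvmm"),
               "sigma", class = "saqmap_validation_error")
  u <- map_direct_mixture(table1_means, "aldvmm",
                          assumptions = list(sigma = c(0.15, 0.05),
                                             pi = c(0.3, 0.7),
                                             psi = 0.954))
  expect_lte(u, 1)
  expect_gte(u, -0.391)
})

test_that("published indirect mapping yields coherent probabilities", {
  res <- map_indirect(table1_means)
  for (d in eq5d_dimensions()) {
    expect_equal(rowSums(res$probabilities[[d]]), 1, tolerance = 1e-12)
    expect_equal(unname(res$probabilities[[d]][, 5]), 0)  # default map 1-4
  }
  expect_gte(res$utility, -0.391)
  expect_lte(res$utility, 1)

  # at perfect scores every dimension's modal category is level 1
  perfect <- data.frame(pl = 100, as = 100, af = 100, ts = 100, dp = 100)
  res_hi <- map_indirect(perfect)
  for (d in eq5d_dimensions()) {
    expect_equal(which.max(res_hi$probabilities[[d]][1, ]), c(L1 = 1L))
  }
})

test_that("indirect expected utility rises with protective subscales", {
  # PL, AS, AF carry negative printed coefficients in every dimension, so
  # expected utility must be non-decreasing along each of them; TS and DP
  # have mixed signs across dimensions and are excluded by design
  for (sub in c("pl", "as", "af")) {
    grid <- seq(0, 100, by = 10)
    u <- sapply(grid, function(v) {
      s <- table1_means
      s[[sub]] <- v
      map_indirect(s)$utility
    })
    expect_true(all(diff(u) >= -1e-12))
  }
})

test_that("level-map overrides are validated and honoured", {
  expect_error(map_indirect(table1_means, level_map = c(1, 1, 2, 3)),
               class = "saqmap_validation_error")
  expect_error(map_indirect(table1_means, level_map = c(1, 2, 3)),
               class = "saqmap_validation_error")
  res <- map_indirect(table1_means, level_map = c(1, 2, 3, 5))
  expect_equal(unname(res$probabilities$mo[, 4]), 0)
})

test_that("score validation rejects unknown methods and bad inputs", {
  expect_error(map_direct(table1_means, "ridge"))
  expect_error(map_direct(data.frame(pl = 50), "ols"),
               class = "saqmap_validation_error")
  expect_error(map_direct(data.frame(pl = 120, as = 1, af = 1, ts = 1,
                                     dp = 1), "ols"),
               class = "saqmap_validation_error")
})
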