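# Shared fixtures. Everything is generated in code; the default-config
# calibration is computed once per session (and disk-cached) through the
# package's own cache.

vs_cn <- load_value_set("china-5L")

default_cfg <- generator_config()

default_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- calibrate_generator(default_cfg, vs_cn)
    cal
  }
})

# random subscale data on 0-100 and its design matrix
make_scores <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(pl = runif(n, 0, 100), as = runif(n, 0, 100),
             af = runif(n, 0, 100), ts = runif(n, 0, 100),
             dp = runif(n, 0, 100))
}

# linear-model data with gaussian noise
sim_linear <- function(n, beta, sd = 0.08, seed = 1) {
  sc <- make_scores(n, seed)
  X <- build_design(sc)
  y <- drop(X %*% beta) + rnorm(n, 0, sd)
  list(X = X, y = y, scores = sc)
}

rlaplace <- function(n, scale) {
  rexp(n, 1 / scale) - rexp(n, 1 / scale)
}

true_beta <- c(0.30, 0.50, 0.04, 0.06, 0.10, 0.15)

# share of coefficient estimates within z standard errors of the truth
se_coverage <- function(fits, truth, z = 2) {
  checks <- unlist(lapply(fits, function(f) {
    se <- sqrt(diag(f$vcov))
    abs(f$coefficients - truth) <= z * se
  }))
  mean(checks)
}
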