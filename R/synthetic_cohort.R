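#' Generator configuration for synthetic SAQ/EQ-5D cohorts
#'
#' The generator emulates the joint structure a SAQ-to-EQ-5D mapping
#' study assumes: a single latent severity factor per patient drives
#' both the five SAQ subscales (as truncated affine transforms) and the
#' five EQ-5D dimension levels (through ordered thresholds), so utilities
#' show the characteristic left skew, ceiling mass at full health and
#' strong rank correlation with the subscales. Default targets are the
#' descriptives of a Chinese coronary-heart-disease cohort: mean utility
#' 0.87 (SD 0.14), 31.1% at full health, Spearman(DP, utility) 0.7093,
#' subscale means/SDs as listed below, and a mean paired follow-up
#' utility improvement of 0.1256.
#'
#' @param n cohort size (baseline rows; default 380).
#' @param followup_fraction share of patients given a paired second wave
#'   by \code{\link{generate_followup}} (default 75/380).
#' @param seed default RNG seed used by \code{\link{generate_cohort}}.
#' @param subscale_targets data.frame with columns \code{subscale, mean,
#'   sd} on the 0-100 scale.
#' @param utility_targets list with \code{mean}, \code{sd},
#'   \code{ceiling} (share at full health).
#' @param correlation_target list with \code{subscales} (named vector of
#'   Spearman subscale-utility targets used to calibrate free loadings),
#'   \code{dp} (the headline DP-utility correlation) and \code{band}
#'   (the plausible range the non-DP correlations should fall in).
#' @param change_target mean paired utility improvement at follow-up.
#' @param lambda named loadings of each subscale on the latent factor,
#'   in \code{[-1, 1]}; \code{NA} (the default for every subscale) lets
#'   \code{\link{calibrate_generator}} choose each loading to hit that
#'   subscale's entry in \code{correlation_target$subscales}.
#' @param calibration_n batch size for the calibration search (default
#'   50000).
#' @return object of class \code{saq_generator_config}.
#' @export
generator_config <- function(n = 380,
                             followup_fraction = 75 / 380,
                             seed = 1L,
                             subscale_targets = data.frame(
                               subscale = c("pl", "as", "af", "ts", "dp"),
                               mean = c(70.83, 36.18, 64.55, 67.69, 51.80),
                               sd = c(14.41, 34.07, 28.06, 11.62, 13.77)
                             ),
                             utility_targets = list(mean = 0.87, sd = 0.14,
                                                    ceiling = 0.311),
                             correlation_target = list(
                               subscales = c(pl = 0.6416, as = 0.6502,
                                             af = 0.6676, ts = 0.6184,
                                             dp = 0.7093),
                               dp = 0.7093,
                               band = c(0.62, 0.71)),
                             change_target = 0.1256,
                             lambda = c(pl = NA, as = NA, af = NA,
                                        ts = NA, dp = NA),
                             calibration_n = 50000) {
  cfg <- list(n = n, followup_fraction = followup_fraction, seed = seed,
              subscale_targets = subscale_targets,
              utility_targets = utility_targets,
              correlation_target = correlation_target,
              change_target = change_target, lambda = lambda,
              calibration_n = calibration_n,
              covariates = list(age_mean = 63.04, age_sd = 9.68,
                                male_share = 0.5372,
                                disease_shares = c(stable = 0.2170,
                                                   unstable = 0.7005,
                                                   mi = 0.0824),
                                duration_mean = 2.50, duration_sd = 5.54))
  validate_generator_config(cfg)
  structure(cfg, class = "saq_generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 2) {
    stop_saqmap("n must be >= 2", class = "saqmap_validation_error")
  }
  if (cfg$followup_fraction < 0 || cfg$followup_fraction > 1) {
    stop_saqmap("followup_fraction must lie in [0, 1]",
                class = "saqmap_validation_error")
  }
  if (any(cfg$subscale_targets$sd <= 0)) {
    stop_saqmap("subscale target SDs must be positive",
                class = "saqmap_validation_error")
  }
  ut <- cfg$utility_targets
  if (ut$ceiling <= 0 || ut$ceiling >= 1) {
    stop_saqmap("ceiling share must lie strictly in (0, 1); a degenerate ",
                "ceiling target is infeasible for the threshold model",
                class = "saqmap_validation_error")
  }
  if (ut$sd <= 0) {
    stop_saqmap("utility SD target must be positive",
                class = "saqmap_validation_error")
  }
  invisible(cfg)
}

# fixed structural constants of the latent threshold model: baseline
# per-dimension first cut (standard-normal scale; larger => more of the
# cohort at level 1) and the baseline spacing of the four cuts.
dim_base_cuts <- function() {
  c(mo = 0.13, sc = 1.04, ua = 0.00, pd = -0.25, ad = 0.13)
}
base_gap <- 1.0

# simulate dimension levels for latent severity w = -theta
draw_levels <- function(w, a, thresholds, nu) {
  b <- sqrt(1 - a^2)
  dims <- eq5d_dimensions()
  lv <- matrix(1L, nrow = length(w), ncol = 5,
               dimnames = list(NULL, dims))
  for (j in seq_along(dims)) {
    z <- a * w + b * nu[, j]
    lv[, j] <- 1L + findInterval(z, thresholds[j, ])
  }
  lv
}

cfg_cache_key <- function(cfg, vs) {
  vals <- c(cfg$subscale_targets$mean, cfg$subscale_targets$sd,
            unlist(cfg$utility_targets), cfg$correlation_target$dp,
            cfg$correlation_target$subscales %||% numeric(0),
            cfg$correlation_target$band, cfg$change_target,
            cfg$lambda, cfg$calibration_n, vs$floor,
            as.numeric(vs$decrements))
  key <- paste(format(signif(vals, 8), trim = TRUE), collapse = "_")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(key, tf)
  paste0("cal_", unname(tools::md5sum(tf)))
}

.saqmap_cal_cache <- new.env(parent = emptyenv())

#' Calibrate the synthetic-cohort generator
#'
#' Coordinate search (Nelder-Mead over up to four free parameters: the
#' shared dimension loading on the latent factor, a global shift of the
#' first cuts, a scale on the cut spacing, and the DP subscale loading)
#' on a large common-random-numbers batch, minimising squared deviation
#' from the utility targets (mean, SD, ceiling share) and, when the DP
#' loading is free, the Spearman(DP, utility) target. The follow-up
#' latent shift is then solved by bisection so the expected paired
#' utility change matches \code{change_target}. Results are cached
#' in-session and on disk, keyed by a hash of the config targets and
#' tariff.
#'
#' @param config a \code{\link{generator_config}}.
#' @param vs value set.
#' @param cache use the calibration cache (default TRUE).
#' @return list with elements \code{a}, \code{shift}, \code{gap_scale},
#'   \code{lambda} (full 5-vector), \code{thresholds} (5 x 4 matrix),
#'   \code{delta} (follow-up latent shift) and \code{achieved}
#'   (diagnostics from the calibration batch).
#' @export
calibrate_generator <- function(config, vs = load_value_set(),
                                cache = TRUE) {
  validate_generator_config(config)
  key <- cfg_cache_key(config, vs)
  if (cache && !is.null(.saqmap_cal_cache[[key]])) {
    return(.saqmap_cal_cache[[key]])
  }
  cache_dir <- tryCatch(tools::R_user_dir("saqmap", "cache"),
                        error = function(e) NULL)
  cache_file <- if (!is.null(cache_dir)) file.path(cache_dir,
                                                   paste0(key, ".json"))
  if (cache && !is.null(cache_file) && file.exists(cache_file)) {
    cal <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    cal$thresholds <- matrix(cal$thresholds, nrow = 5,
                             dimnames = list(eq5d_dimensions(), NULL))
    cal$lambda <- stats::setNames(cal$lambda, saq_subscales())
    .saqmap_cal_cache[[key]] <- cal
    return(cal)
  }

  nb <- config$calibration_n
  free_dp <- is.na(config$lambda["dp"])
  st <- config$subscale_targets
  dp_row <- match("dp", st$subscale)
  ut <- config$utility_targets

  # common random numbers, fixed internal stream: the calibration is a
  # deterministic function of the config
  batch <- with_seed(20230703L, {
    list(theta = stats::rnorm(nb),
         nu = matrix(stats::rnorm(nb * 5), ncol = 5),
         eps = matrix(stats::rnorm(nb * 5), ncol = 5,
                      dimnames = list(NULL, saq_subscales())))
  })
  w <- -batch$theta
  base <- dim_base_cuts()

  make_thresholds <- function(shift, gap_scale) {
    t1 <- base + shift
    outer(t1, rep(1, 4)) +
      outer(rep(1, 5), (0:3) * base_gap * gap_scale)
  }

  sim_stats <- function(a, shift, gap_scale, lambda_dp) {
    thr <- make_thresholds(shift, gap_scale)
    lv <- draw_levels(w, a, thr, batch$nu)
    u <- eq5d_utility(as.data.frame(lv), vs)
    out <- list(mean = mean(u), sd = stats::sd(u),
                ceiling = mean(rowSums(lv == 1L) == 5L))
    if (!is.na(lambda_dp)) {
      dp <- clamp(st$mean[dp_row] + st$sd[dp_row] *
                    (lambda_dp * batch$theta +
                       sqrt(1 - lambda_dp^2) * batch$eps[, "dp"]), 0, 100)
      out$spearman_dp <- stats::cor(dp, u, method = "spearman")
    }
    out
  }

  to_par <- function(a, shift, gap_scale, ldp) {
    c(stats::qlogis((a - 0.05) / 0.93),
      shift,
      log(gap_scale),
      if (free_dp) stats::qlogis((ldp - 0.3) / 0.68))
  }
  from_par <- function(p) {
    list(a = 0.05 + 0.93 * stats::plogis(p[1]),
         shift = p[2],
         gap_scale = exp(p[3]),
         ldp = if (free_dp) 0.3 + 0.68 * stats::plogis(p[4]) else
           config$lambda[["dp"]])
  }
  objective <- function(p) {
    pr <- from_par(p)
    s <- sim_stats(pr$a, pr$shift, pr$gap_scale,
                   if (free_dp) pr$ldp else NA)
    val <- 200 * (s$mean - ut$mean)^2 +
      50 * (s$sd - ut$sd)^2 +
      50 * (s$ceiling - ut$ceiling)^2
    if (free_dp) {
      val <- val + 50 * (s$spearman_dp - config$correlation_target$dp)^2
    }
    val
  }
  start <- to_par(0.75, 0.45, 1.0, if (free_dp) 0.88 else NA)
  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 1500, reltol = 1e-9))
  pr <- from_par(opt$par)
  lambda <- config$lambda
  if (free_dp) lambda["dp"] <- pr$ldp
  thr <- make_thresholds(pr$shift, pr$gap_scale)
  ach <- sim_stats(pr$a, pr$shift, pr$gap_scale, lambda[["dp"]])

  # remaining free loadings: solve each so Spearman(subscale, utility)
  # matches its configured target (monotone in lambda => bisection)
  lv_cal <- draw_levels(w, pr$a, thr, batch$nu)
  u_cal <- eq5d_utility(as.data.frame(lv_cal), vs)
  sp_at <- function(lam, j) {
    s <- clamp(st$mean[j] + st$sd[j] *
                 (lam * batch$theta +
                    sqrt(1 - lam^2) * batch$eps[, st$subscale[j]]),
               0, 100)
    stats::cor(s, u_cal, method = "spearman")
  }
  sp_targets <- config$correlation_target$subscales
  achieved_sp <- stats::setNames(rep(NA_real_, 5), st$subscale)
  for (j in seq_len(5)) {
    sub <- st$subscale[j]
    if (!is.na(lambda[[sub]]) || sub == "dp" ||
        is.null(sp_targets) || !sub %in% names(sp_targets)) next
    tgt <- sp_targets[[sub]]
    f <- function(l) sp_at(l, j) - tgt
    if (f(0.995) < 0) {
      stop_saqmap("correlation target ", tgt, " for subscale ", sub,
                  " is unreachable even at loading 0.995 (achieved ",
                  signif(sp_at(0.995, j), 4), ")",
                  class = "saqmap_calibration_error")
    }
    lambda[[sub]] <- stats::uniroot(f, lower = 0.02, upper = 0.995,
                                    tol = 1e-4)$root
  }
  if (anyNA(lambda)) {
    stop_saqmap("loadings remain uncalibrated for: ",
                paste(names(lambda)[is.na(lambda)], collapse = ", "),
                class = "saqmap_calibration_error")
  }
  for (j in seq_len(5)) achieved_sp[j] <- sp_at(lambda[[st$subscale[j]]], j)
  ach$spearman <- achieved_sp

  feasible <- abs(ach$mean - ut$mean) <= 0.02 &&
    abs(ach$sd - ut$sd) <= 0.03 &&
    abs(ach$ceiling - ut$ceiling) <= 0.05 &&
    (!free_dp ||
       abs(ach$spearman_dp - config$correlation_target$dp) <= 0.08)
  if (!feasible) {
    stop_saqmap(
      "generator calibration failed to reach the configured targets; ",
      "achieved mean=", signif(ach$mean, 4), " sd=", signif(ach$sd, 4),
      " ceiling=", signif(ach$ceiling, 4),
      if (!is.null(ach$spearman_dp)) {
        paste0(" spearman_dp=", signif(ach$spearman_dp, 4))
      } else "",
      class = "saqmap_calibration_error"
    )
  }

  # follow-up latent shift: solve E[u(theta + delta)] - E[u(theta)] =
  # change_target on the batch (fresh dimension noise for the second wave)
  nu2 <- with_seed(20230704L, matrix(stats::rnorm(nb * 5), ncol = 5))
  mean_u_shift <- function(delta) {
    lv2 <- draw_levels(-(batch$theta + delta), pr$a, thr, nu2)
    mean(eq5d_utility(as.data.frame(lv2), vs)) - ach$mean
  }
  delta <- tryCatch(
    stats::uniroot(function(d) mean_u_shift(d) - config$change_target,
                   lower = 0, upper = 6, extendInt = "no",
                   tol = 1e-4)$root,
    error = function(e) {
      stop_saqmap("follow-up shift calibration failed: change target ",
                  config$change_target, " unreachable",
                  class = "saqmap_calibration_error")
    }
  )

  cal <- list(a = pr$a, shift = pr$shift, gap_scale = pr$gap_scale,
              lambda = lambda, thresholds = thr, delta = delta,
              achieved = ach, objective = opt$value,
              converged = opt$convergence == 0)
  .saqmap_cal_cache[[key]] <- cal
  if (cache && !is.null(cache_file)) {
    dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({
      jsonlite::write_json(cal, cache_file, auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) FALSE)
  }
  cal
}

#' Generate a synthetic baseline cohort
#'
#' Draws \code{n} patients from the calibrated latent-factor model: one
#' standard-normal severity \code{theta} per patient drives the five SAQ
#' subscales and the five EQ-5D dimension levels; utilities are computed
#' from the generated states under \code{vs} (never stored free-
#' floating). Covariates (age, sex, disease type, illness duration) are
#' drawn independently of \code{theta}. Deterministic for a fixed seed.
#'
#' @param config a \code{\link{generator_config}}.
#' @param vs value set.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @param calibration optional precomputed \code{\link{calibrate_generator}}
#'   result (to skip the cache lookup).
#' @return data.frame with columns \code{pid, wave, theta, pl, as, af,
#'   ts, dp, mo, sc, ua, pd, ad, utility, age, sex, disease_type,
#'   duration}; \code{wave} is 1 throughout.
#' @export
generate_cohort <- function(config = generator_config(),
                            vs = load_value_set(),
                            seed = config$seed, calibration = NULL) {
  validate_generator_config(config)
  cal <- calibration %||% calibrate_generator(config, vs)
  n <- config$n
  st <- config$subscale_targets
  cov <- config$covariates
  with_seed(seed, {
    theta <- stats::rnorm(n)
    nu <- matrix(stats::rnorm(n * 5), ncol = 5)
    lv <- draw_levels(-theta, cal$a, cal$thresholds, nu)
    subs <- matrix(NA_real_, nrow = n, ncol = 5,
                   dimnames = list(NULL, saq_subscales()))
    for (j in seq_len(5)) {
      lam <- cal$lambda[[st$subscale[j]]]
      subs[, st$subscale[j]] <- clamp(
        st$mean[j] + st$sd[j] * (lam * theta +
                                   sqrt(1 - lam^2) * stats::rnorm(n)),
        0, 100)
    }
    states <- as.data.frame(lv)
    g <- cov$duration_sd^2 / cov$duration_mean
    k <- cov$duration_mean / g
    out <- data.frame(
      pid = seq_len(n), wave = 1L, theta = theta,
      subs, states,
      utility = eq5d_utility(states, vs),
      age = round(stats::rnorm(n, cov$age_mean, cov$age_sd), 1),
      sex = ifelse(stats::runif(n) < cov$male_share, "male", "female"),
      disease_type = sample(names(cov$disease_shares), n, replace = TRUE,
                            prob = cov$disease_shares),
      duration = round(stats::rgamma(n, shape = k, scale = g), 2),
      stringsAsFactors = FALSE
    )
    out
  })
}

#' Append a paired follow-up wave
#'
#' A random \code{followup_fraction} share of patients receives a second
#' wave: their latent severity is shifted by the calibrated improvement
#' \code{delta} (so the expected paired utility change matches the
#' configured target) and subscales, states and utility are redrawn from
#' the shifted latent. Pairing is preserved through \code{pid}.
#'
#' @param cohort baseline cohort from \code{\link{generate_cohort}}
#'   (must carry the \code{theta} column).
#' @param config a \code{\link{generator_config}}.
#' @param vs value set.
#' @param seed RNG seed; defaults to \code{config$seed + 500000}.
#' @param delta override for the latent shift (e.g. 0 for a
#'   no-improvement null).
#' @return the cohort with follow-up rows (\code{wave == 2}) appended.
#' @export
generate_followup <- function(cohort, config = generator_config(),
                              vs = load_value_set(),
                              seed = config$seed + 500000L,
                              delta = NULL) {
  if (!"theta" %in% names(cohort)) {
    stop_saqmap("cohort lacks the latent theta column",
                class = "saqmap_validation_error")
  }
  base <- cohort[cohort$wave == 1L, , drop = FALSE]
  m <- round(config$followup_fraction * nrow(base))
  if (m < 2) {
    stop_saqmap("followup_fraction * n must be at least 2",
                class = "saqmap_validation_error")
  }
  cal <- calibrate_generator(config, vs)
  delta <- delta %||% cal$delta
  st <- config$subscale_targets
  with_seed(seed, {
    pick <- sort(sample.int(nrow(base), m))
    fu <- base[pick, , drop = FALSE]
    fu$wave <- 2L
    fu$theta <- fu$theta + delta
    nu <- matrix(stats::rnorm(m * 5), ncol = 5)
    lv <- draw_levels(-fu$theta, cal$a, cal$thresholds, nu)
    for (j in seq_len(5)) {
      lam <- cal$lambda[[st$subscale[j]]]
      fu[[st$subscale[j]]] <- clamp(
        st$mean[j] + st$sd[j] * (lam * fu$theta +
                                   sqrt(1 - lam^2) * stats::rnorm(m)),
        0, 100)
    }
    fu[eq5d_dimensions()] <- as.data.frame(lv)
    fu$utility <- eq5d_utility(fu[eq5d_dimensions()], vs)
    rownames(fu) <- NULL
    rbind(cohort, fu)
  })
}
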