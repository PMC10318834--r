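#' Build the mapping design matrix
#'
#' The direct and indirect mapping models regress utilities (or dimension
#' levels) on the five SAQ subscale scores rescaled to \code{[0, 1]}
#' (score / 100), plus an intercept where applicable. Rescaling puts all
#' covariates on a common unit so coefficients are utility changes over
#' the full subscale range.
#'
#' @param data data.frame with subscale columns \code{pl, as, af, ts, dp}
#'   on the 0-100 scale.
#' @param intercept logical; prepend an intercept column (default TRUE).
#' @return numeric matrix with columns \code{(Intercept), pl, as, af, ts,
#'   dp} (intercept optional), no missing values allowed.
#' @export
build_design <- function(data, intercept = TRUE) {
  subs <- saq_subscales()
  missing_cols <- setdiff(subs, names(data))
  if (length(missing_cols)) {
    stop_saqmap("data is missing subscale column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "saqmap_validation_error")
  }
  X <- as.matrix(data[subs]) / 100
  if (anyNA(X)) {
    stop_saqmap("design has missing subscale values",
                class = "saqmap_validation_error")
  }
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  X
}

check_design <- function(X, y = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X)) {
    stop_saqmap("design contains missing values",
                class = "saqmap_validation_error")
  }
  if (!is.null(y) && length(y) != nrow(X)) {
    stop_saqmap("length(y) != nrow(X)", class = "saqmap_validation_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_saqmap("design is rank-deficient; collinear column(s): ",
                paste(dropped, collapse = ", "),
                class = "saqmap_validation_error")
  }
  X
}

new_direct_fit <- function(method, coefficients, sigma = NA_real_,
                           vcov = NULL, convergence = list(converged = TRUE),
                           extra = list()) {
  structure(
    c(list(method = method, coefficients = coefficients, sigma = sigma,
           vcov = vcov, convergence = convergence), extra),
    class = c(paste0("saq_fit_", method), "saq_direct_fit")
  )
}

#' @export
print.saq_direct_fit <- function(x, ...) {
  cat("Direct mapping model [", x$method, "]\n", sep = "")
  print(round(x$coefficients, 4))
  if (is.finite(x$sigma)) cat("sigma:", format(round(x$sigma, 4)), "\n")
  if (!isTRUE(x$convergence$converged)) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
coef.saq_direct_fit <- function(object, ...) object$coefficients

#' @export
vcov.saq_direct_fit <- function(object, ...) object$vcov

#' Ordinary least squares mapping model
#'
#' @param X design matrix from \code{\link{build_design}} (intercept
#'   included).
#' @param y numeric vector of observed EQ-5D-5L utilities.
#' @return A \code{saq_direct_fit} object with coefficients, residual
#'   scale and coefficient covariance.
#' @export
fit_ols <- function(X, y) {
  X <- check_design(X, y)
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  new_direct_fit("ols", fit$coefficients, sqrt(sigma2),
                 vcov = sigma2 * XtX_inv,
                 extra = list(fitted = drop(X %*% fit$coefficients)))
}

#' Tobit mapping model (right-censored at full health)
#'
#' Maximises the right-censored Gaussian likelihood: observations at the
#' censoring point contribute the upper-tail mass
#' \eqn{1 - \Phi((u - x'\beta)/\sigma)}, others the normal density.
#' Fitted through the censored Gaussian AFT machinery of
#' \code{survival::survreg}. Predictions are the latent index
#' \eqn{x'\beta} (not the censored expectation), matching common mapping
#' practice of reporting uncensored predictions.
#'
#' @inheritParams fit_ols
#' @param upper censoring point (default 1, full health).
#' @export
fit_tobit <- function(X, y, upper = 1) {
  X <- check_design(X, y)
  uncensored <- y < upper
  if (!any(uncensored)) {
    stop_saqmap("all observations censored at the upper bound",
                class = "saqmap_validation_error")
  }
  sv <- survival::Surv(y, event = uncensored, type = "right")
  fit <- survival::survreg(sv ~ X - 1, dist = "gaussian")
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  V <- fit$var
  p <- ncol(X)
  vcov <- V[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # survreg errors out (rather than flagging) when it fails to converge
  conv <- list(converged = TRUE, iterations = fit$iter,
               loglik = fit$loglik[2])
  new_direct_fit("tobit", beta, fit$scale, vcov = vcov, convergence = conv,
                 extra = list(upper = upper))
}

#' Log-link Gaussian GLM mapping model
#'
#' Gaussian family with a log link, fitted by iteratively reweighted
#' least squares; accommodates the left skew of utilities while keeping
#' predictions positive (\eqn{\hat y = \exp(x'\beta)}).
#'
#' @inheritParams fit_ols
#' @export
fit_glm_log <- function(X, y) {
  X <- check_design(X, y)
  fam <- stats::gaussian(link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, mustart = pmax(y, 0.05),
                   control = stats::glm.control(maxit = 100))
  )
  if (!fit$converged) {
    warning("log-link Gaussian GLM did not converge")
  }
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  mu <- fit$fitted.values
  n <- length(y)
  p <- ncol(X)
  dispersion <- sum((y - mu)^2) / (n - p)
  W <- mu^2  # (dmu/deta)^2 for the log link, unit gaussian variance
  XtWX <- crossprod(X * sqrt(W))
  vcov <- dispersion * solve(XtWX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  new_direct_fit("glm", beta, sqrt(dispersion), vcov = vcov,
                 convergence = list(converged = fit$converged,
                                    iterations = fit$iter,
                                    deviance = fit$deviance))
}

# L1 (median) regression: IRLS with a Nelder-Mead polish on the exact
# objective. quantile-regression LP solvers are deliberately avoided so
# the package has no dependency beyond base + recommended.
lad_fit <- function(X, y, beta0 = NULL, polish = TRUE) {
  n <- nrow(X)
  beta <- beta0 %||% stats::lm.fit(X, y)$coefficients
  eps <- 1e-6
  for (i in seq_len(200)) {
    r <- y - drop(X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    new_beta <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(new_beta - beta)) < 1e-9) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  if (polish && length(beta) <= 12) {
    obj <- function(b) sum(abs(y - drop(X %*% b)))
    opt <- stats::optim(beta, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (opt$value < obj(beta)) beta <- opt$par
  }
  names(beta) <- colnames(X)
  beta
}

#' Censored least absolute deviations (CLAD) mapping model
#'
#' Powell's estimator: minimises \eqn{\sum_i |y_i - \min(x_i'\beta, u)|}
#' by alternating (a) median (L1) regression on the active subsample with
#' fitted index below the censoring point and (b) recomputation of the
#' active set, until the active set stabilises. The best objective seen
#' is kept if the iteration cycles. Predictions are the uncensored index.
#'
#' @inheritParams fit_tobit
#' @param se \code{"boot"} for nonparametric bootstrap standard errors,
#'   \code{"none"} to skip (e.g. inside cross-validation).
#' @param B bootstrap resamples (default 199).
#' @param seed seed for the bootstrap resampling.
#' @export
fit_clad <- function(X, y, upper = 1, se = c("boot", "none"), B = 199,
                     seed = 1L) {
  se <- match.arg(se)
  X <- check_design(X, y)
  clad_obj <- function(b) sum(abs(y - pmin(drop(X %*% b), upper)))
  beta <- lad_fit(X, y)
  best <- beta
  best_obj <- clad_obj(beta)
  active_prev <- NULL
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(50)) {
    iters <- i
    active <- which(drop(X %*% beta) < upper)
    if (length(active) <= ncol(X)) break
    if (!is.null(active_prev) && identical(active, active_prev)) {
      converged <- TRUE
      break
    }
    active_prev <- active
    beta <- lad_fit(X[active, , drop = FALSE], y[active], beta0 = beta)
    o <- clad_obj(beta)
    if (o < best_obj) {
      best_obj <- o
      best <- beta
    }
  }
  vcov <- NULL
  if (se == "boot") {
    n <- nrow(X)
    boot <- with_seed(seed, {
      t(vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        fit_clad(X[idx, , drop = FALSE], y[idx], upper = upper,
                 se = "none")$coefficients
      }, numeric(ncol(X))))
    })
    vcov <- stats::cov(boot)
    dimnames(vcov) <- list(colnames(X), colnames(X))
  }
  new_direct_fit("clad", best, vcov = vcov,
                 convergence = list(converged = converged,
                                    iterations = iters,
                                    objective = best_obj),
                 extra = list(upper = upper))
}

#' Robust MM regression mapping model
#'
#' MM estimation: a high-breakdown S-estimate of scale (Tukey bisquare)
#' followed by an efficient bisquare M-step at 95% Gaussian efficiency
#' (tuning constant 4.685), via \code{MASS::rlm(method = "MM")}. The
#' S-step subsampling RNG is seeded for reproducibility.
#'
#' @inheritParams fit_ols
#' @param seed seed for the S-step subsampling.
#' @export
fit_rmm <- function(X, y, seed = 1L) {
  X <- check_design(X, y)
  fit <- with_seed(seed, MASS::rlm(X, y, method = "MM", maxit = 100))
  if (fit$s < 1e-8) {
    stop_saqmap("degenerate robust scale (exact fit)",
                class = "saqmap_validation_error")
  }
  sm <- summary(fit)
  vcov <- sm$cov.unscaled * sm$stddev^2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  new_direct_fit("rmm", beta, fit$s, vcov = vcov,
                 convergence = list(converged = fit$converged,
                                    iterations = length(fit$conv)))
}

#' Predict utilities from a direct mapping model
#'
#' @param object a \code{saq_direct_fit}.
#' @param X design matrix with the same columns as at fit time.
#' @param truncate clamp predictions to \code{[floor, 1]} (default FALSE;
#'   mapping studies conventionally report untruncated predictions).
#' @param floor lower clamp bound when \code{truncate} (default -0.391).
#' @param ... unused.
#' @return numeric vector of predicted utilities.
#' @export
predict.saq_direct_fit <- function(object, X, truncate = FALSE,
                                   floor = -0.391, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!identical(colnames(X), names(object$coefficients))) {
    stop_saqmap("design columns do not match the fitted model (",
                paste(names(object$coefficients), collapse = ", "),
                " expected)", class = "saqmap_validation_error")
  }
  eta <- drop(X %*% object$coefficients)
  pred <- if (object$method == "glm") exp(eta) else eta
  if (truncate) pred <- clamp(pred, floor, 1)
  pred
}
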