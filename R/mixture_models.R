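#' Adjusted limited dependent variable mixture model (ALDVMM)
#'
#' A K-component Gaussian mixture adapted to the distribution of EQ-5D
#' utilities: a probability mass at full health (1), a gap between 1 and
#' the largest feasible utility below 1 (\code{psi}), and an optional
#' mass at the tariff floor. Within component k, with latent index
#' \eqn{\mu_k = x'\beta_k}:
#' \itemize{
#'   \item \eqn{P(y = 1)     = 1 - \Phi((\psi - \mu_k)/\sigma_k)}
#'   \item \eqn{P(y = floor) = \Phi((floor - \mu_k)/\sigma_k)}
#'   \item density \eqn{\phi((y-\mu_k)/\sigma_k)/\sigma_k} for
#'     \eqn{floor < y \le \psi}.
#' }
#' Component membership is multinomial-logit with intercept-only
#' coefficients by default. The likelihood is maximised by quasi-Newton
#' iteration from multiple random starts; components are relabelled in
#' increasing order of intercept for identifiability.
#'
#' @param X design matrix (see \code{\link{build_design}}).
#' @param y utilities; must lie in \code{[floor, psi]} or equal 1 —
#'   values strictly inside the gap \code{(psi, 1)} are rejected.
#' @param K number of components (default 2).
#' @param psi largest feasible utility below 1. Default: computed from
#'   \code{vs} as 1 minus the smallest single-level decrement.
#' @param floor minimum feasible utility (default \code{vs$floor}).
#' @param vs value set used for the \code{psi}/\code{floor} defaults.
#' @param n_starts random starts (default 20).
#' @param seed master seed for the starts.
#' @return object of class \code{c("saq_aldvmm", "saq_mixture_fit")} with
#'   per-component coefficients \code{beta} (p x K), scales \code{sigma},
#'   membership probabilities \code{pi}, membership logits \code{delta},
#'   log-likelihood, vcov (observed-information inverse, when available)
#'   and convergence info.
#' @export
fit_aldvmm <- function(X, y, K = 2, psi = NULL, floor = NULL,
                       vs = load_value_set(), n_starts = 20, seed = 1L) {
  X <- check_design(X, y)
  psi <- psi %||% (1 - min(vs$decrements[, 2]))
  floor <- floor %||% vs$floor
  if (K < 1) stop_saqmap("K must be >= 1", class = "saqmap_validation_error")
  if (any(y > psi & y < 1)) {
    stop_saqmap("observations inside the gap (psi, 1) are infeasible ",
                "under the ALDVMM", class = "saqmap_validation_error")
  }
  if (any(y < floor - 1e-12) || any(y > 1 + 1e-12)) {
    stop_saqmap("utilities outside [floor, 1]",
                class = "saqmap_validation_error")
  }
  p <- ncol(X)
  npar <- K * p + K + (K - 1)

  unpack <- function(par) {
    beta <- matrix(par[seq_len(K * p)], nrow = p, ncol = K)
    sigma <- exp(par[K * p + seq_len(K)])
    delta <- if (K > 1) par[K * p + K + seq_len(K - 1)] else numeric(0)
    pi_k <- softmax_ref(delta, K)
    list(beta = beta, sigma = sigma, delta = delta, pi = pi_k)
  }

  at_one <- y >= 1 - 1e-12
  at_floor <- abs(y - floor) < 1e-12
  mid <- !at_one & !at_floor

  negll <- function(par) {
    pr <- unpack(par)
    ll_k <- matrix(NA_real_, nrow = length(y), ncol = K)
    for (k in seq_len(K)) {
      mu <- drop(X %*% pr$beta[, k])
      s <- pr$sigma[k]
      lk <- numeric(length(y))
      lk[at_one] <- stats::pnorm((psi - mu[at_one]) / s, lower.tail = FALSE,
                                 log.p = TRUE)
      if (any(at_floor)) {
        lk[at_floor] <- stats::pnorm((floor - mu[at_floor]) / s, log.p = TRUE)
      }
      lk[mid] <- stats::dnorm(y[mid], mu[mid], s, log = TRUE)
      ll_k[, k] <- lk + log(pr$pi[k])
    }
    m <- apply(ll_k, 1, max)
    ll <- m + log(rowSums(exp(ll_k - m)))
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }

  base <- stats::lm.fit(X, y)
  sd0 <- stats::sd(base$residuals)
  seeds <- derive_seeds(seed, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- with_seed(seeds[s], {
      b0 <- vapply(seq_len(K), function(k) {
        base$coefficients + stats::rnorm(p, 0, 0.25 * max(sd0, 0.05))
      }, numeric(p))
      c(as.numeric(b0),
        log(pmax(sd0, 0.02)) + stats::rnorm(K, 0, 0.4),
        if (K > 1) stats::rnorm(K - 1, 0, 0.5))
    })
    opt <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    stop_saqmap("ALDVMM optimisation failed from every start",
                class = "saqmap_fit_error")
  }
  pr <- unpack(best$par)
  ord <- order(pr$beta[1, ])
  beta <- pr$beta[, ord, drop = FALSE]
  sigma <- pr$sigma[ord]
  pi_k <- pr$pi[ord]
  delta <- if (K > 1) log(pi_k[-1] / pi_k[1]) else numeric(0)
  rownames(beta) <- colnames(X)
  colnames(beta) <- paste0("comp", seq_len(K))
  vcov <- tryCatch({
    H <- stats::optimHess(best$par, negll)
    V <- solve(H)
    V
  }, error = function(e) NULL)
  structure(
    list(method = "aldvmm", K = K, beta = beta, sigma = sigma, pi = pi_k,
         delta = delta, psi = psi, floor = floor,
         loglik = -best$value, vcov = vcov,
         convergence = list(converged = best$convergence == 0,
                            starts = n_starts, value = -best$value)),
    class = c("saq_aldvmm", "saq_mixture_fit")
  )
}

softmax_ref <- function(delta, K) {
  e <- exp(c(0, delta))
  e / sum(e)
}

#' One-inflated beta mixture mapping model
#'
#' Two-part model for bounded, skewed, ceiling-inflated utilities. Part
#' one is a logistic regression for the probability mass at full health
#' (\eqn{y = 1}). Part two, conditional on \eqn{y < 1}, rescales
#' utilities to \eqn{y^* = (y - L)/(U - L)} and fits a C-component beta
#' mixture with logit-linked component means \eqn{\mu_c(x)} and constant
#' precisions \eqn{\phi_c}. Rescaled values of exactly 0 are nudged to
#' \code{0.5/n} (standard beta-regression practice); \eqn{y = 1} is
#' handled entirely by the logistic part.
#'
#' @inheritParams fit_aldvmm
#' @param C number of beta components (default 1).
#' @param bounds rescaling bounds \code{c(L, U)}; default the tariff
#'   range \code{c(vs$floor, 1)}.
#' @return object of class \code{c("saq_betamix", "saq_mixture_fit")}
#'   with \code{gamma} (ceiling logit coefficients), \code{delta} (p x C
#'   mean-link coefficients), \code{phi} (precisions), \code{weights}
#'   (mixture weights), bounds, log-likelihood and convergence info.
#' @export
fit_betamix <- function(X, y, C = 1, bounds = NULL, vs = load_value_set(),
                        n_starts = 20, seed = 1L) {
  X <- check_design(X, y)
  bounds <- bounds %||% c(vs$floor, 1)
  L <- bounds[1]; U <- bounds[2]
  if (any(y < L - 1e-12) || any(y > U + 1e-12)) {
    stop_saqmap("utilities outside [", format(L), ", ", format(U), "]",
                class = "saqmap_validation_error")
  }
  at_one <- y >= 1 - 1e-12
  # Part 1: ceiling mass (exact MLE; separable from the continuous part)
  gfit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(at_one),
                   family = stats::binomial(link = "logit"))
  )
  gamma <- gfit$coefficients
  names(gamma) <- colnames(X)

  Xc <- X[!at_one, , drop = FALSE]
  yc <- y[!at_one]
  n_c <- length(yc)
  ystar <- (yc - L) / (U - L)
  eps <- 0.5 / n_c
  ystar[ystar <= 0] <- eps
  ystar <- pmin(ystar, 1 - 1e-10)
  p <- ncol(X)

  unpack <- function(par) {
    delta <- matrix(par[seq_len(C * p)], nrow = p, ncol = C)
    phi <- exp(par[C * p + seq_len(C)])
    wl <- if (C > 1) par[C * p + C + seq_len(C - 1)] else numeric(0)
    list(delta = delta, phi = phi, w = softmax_ref(wl, C))
  }

  negll <- function(par) {
    pr <- unpack(par)
    if (any(pr$phi > 1e7)) return(1e10)
    dens <- matrix(NA_real_, nrow = n_c, ncol = C)
    for (cc in seq_len(C)) {
      mu <- logistic(drop(Xc %*% pr$delta[, cc]))
      mu <- clamp(mu, 1e-8, 1 - 1e-8)
      dens[, cc] <- log(pr$w[cc]) +
        stats::dbeta(ystar, mu * pr$phi[cc], (1 - mu) * pr$phi[cc],
                     log = TRUE)
    }
    m <- apply(dens, 1, max)
    ll <- m + log(rowSums(exp(dens - m)))
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }

  # moment-based start for the mean link
  start_delta <- stats::lm.fit(Xc, stats::qlogis(ystar))$coefficients
  seeds <- derive_seeds(seed + 1L, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- with_seed(seeds[s], {
      d0 <- vapply(seq_len(C), function(cc) {
        start_delta + stats::rnorm(p, 0, 0.3)
      }, numeric(p))
      c(as.numeric(d0), log(10) + stats::rnorm(C, 0, 0.7),
        if (C > 1) stats::rnorm(C - 1, 0, 0.5))
    })
    opt <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    stop_saqmap("beta mixture optimisation failed from every start",
                class = "saqmap_fit_error")
  }
  pr <- unpack(best$par)
  ord <- order(pr$delta[1, ])
  delta <- pr$delta[, ord, drop = FALSE]
  phi <- pr$phi[ord]
  w <- pr$w[ord]
  rownames(delta) <- colnames(X)
  colnames(delta) <- paste0("comp", seq_len(C))
  # joint log-likelihood on the utility scale (adds the ceiling part and
  # the 1/(U-L) change-of-variable jacobian for the continuous part)
  ll_gamma <- sum(ifelse(at_one, stats::plogis(drop(X %*% gamma), log.p = TRUE),
                         stats::plogis(drop(X %*% gamma), lower.tail = FALSE,
                                       log.p = TRUE)))
  loglik <- ll_gamma - best$value - n_c * log(U - L)
  structure(
    list(method = "bm", C = C, gamma = gamma, delta = delta, phi = phi,
         weights = w, bounds = c(L = L, U = U), loglik = loglik,
         convergence = list(converged = best$convergence == 0,
                            starts = n_starts,
                            beta_part_nll = best$value)),
    class = c("saq_betamix", "saq_mixture_fit")
  )
}

#' @export
print.saq_mixture_fit <- function(x, ...) {
  cat("Mixture mapping model [", x$method, "]\n", sep = "")
  if (x$method == "aldvmm") {
    print(round(x$beta, 4))
    cat("sigma:", paste(round(x$sigma, 4), collapse = ", "),
        " pi:", paste(round(x$pi, 3), collapse = ", "), "\n")
  } else {
    cat("ceiling logit (PM_ub):\n"); print(round(x$gamma, 4))
    cat("beta mean link:\n"); print(round(x$delta, 4))
    cat("phi:", paste(round(x$phi, 3), collapse = ", "), "\n")
  }
  cat("log-likelihood:", format(round(x$loglik, 3)), "\n")
  invisible(x)
}

# mean of a normal(mu, sigma) truncated to (a, b)
truncnorm_mean <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  Z <- stats::pnorm(beta) - stats::pnorm(alpha)
  out <- mu + sigma * (stats::dnorm(alpha) - stats::dnorm(beta)) / Z
  # when the window carries essentially no mass, fall back to the nearer bound
  out[Z < 1e-12] <- ifelse(mu[Z < 1e-12] > b, b, a)
  out
}

#' Predict expected utilities from a mixture mapping model
#'
#' Expected value under the fitted generative model. For the ALDVMM:
#' \deqn{E[Y|x] = \sum_k \pi_k [P_1 \cdot 1 + P_{floor} \cdot floor +
#'   (1 - P_1 - P_{floor}) E(\mathrm{trunc.normal}(floor, \psi))].}
#' For the beta mixture:
#' \deqn{E[Y|x] = p_1(x) + (1 - p_1(x)) (L + (U-L) \sum_c w_c \mu_c(x)).}
#' Predictions therefore always lie in \code{[floor, 1]}.
#'
#' @param object a fitted \code{saq_aldvmm} or \code{saq_betamix}.
#' @param X design matrix matching the training columns.
#' @param ... unused.
#' @export
predict.saq_aldvmm <- function(object, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!identical(colnames(X), rownames(object$beta))) {
    stop_saqmap("design columns do not match the fitted model",
                class = "saqmap_validation_error")
  }
  out <- numeric(nrow(X))
  for (k in seq_len(object$K)) {
    mu <- drop(X %*% object$beta[, k])
    s <- object$sigma[k]
    p1 <- stats::pnorm((object$psi - mu) / s, lower.tail = FALSE)
    pf <- stats::pnorm((object$floor - mu) / s)
    pm <- pmax(1 - p1 - pf, 0)
    etr <- truncnorm_mean(mu, s, object$floor, object$psi)
    out <- out + object$pi[k] * (p1 * 1 + pf * object$floor + pm * etr)
  }
  out
}

#' @rdname predict.saq_aldvmm
#' @export
predict.saq_betamix <- function(object, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!identical(colnames(X), rownames(object$delta))) {
    stop_saqmap("design columns do not match the fitted model",
                class = "saqmap_validation_error")
  }
  p1 <- logistic(drop(X %*% object$gamma))
  mu_mix <- numeric(nrow(X))
  for (cc in seq_len(object$C)) {
    mu_mix <- mu_mix +
      object$weights[cc] * logistic(drop(X %*% object$delta[, cc]))
  }
  L <- object$bounds["L"]; U <- object$bounds["U"]
  unname(p1 + (1 - p1) * (L + (U - L) * mu_mix))
}

#' Mixture model log-likelihood on new data
#'
#' Evaluates the exact mixture log-likelihood of a fitted ALDVMM or beta
#' mixture on (possibly new) data. For the beta mixture this is the joint
#' likelihood of both parts on the utility scale (including the
#' change-of-variable jacobian of the rescaling).
#'
#' @param model fitted mixture model.
#' @param X design matrix.
#' @param y utilities, feasible under the model.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(model, X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (inherits(model, "saq_aldvmm")) {
    if (any(y > model$psi & y < 1)) {
      stop_saqmap("y inside the infeasible gap (psi, 1)",
                  class = "saqmap_validation_error")
    }
    at_one <- y >= 1 - 1e-12
    at_floor <- abs(y - model$floor) < 1e-12
    mid <- !at_one & !at_floor
    ll_k <- matrix(NA_real_, nrow = length(y), ncol = model$K)
    for (k in seq_len(model$K)) {
      mu <- drop(X %*% model$beta[, k])
      s <- model$sigma[k]
      lk <- numeric(length(y))
      lk[at_one] <- stats::pnorm((model$psi - mu[at_one]) / s,
                                 lower.tail = FALSE, log.p = TRUE)
      if (any(at_floor)) {
        lk[at_floor] <- stats::pnorm((model$floor - mu[at_floor]) / s,
                                     log.p = TRUE)
      }
      lk[mid] <- stats::dnorm(y[mid], mu[mid], s, log = TRUE)
      ll_k[, k] <- lk + log(model$pi[k])
    }
    m <- apply(ll_k, 1, max)
    return(sum(m + log(rowSums(exp(ll_k - m)))))
  }
  if (inherits(model, "saq_betamix")) {
    L <- model$bounds["L"]; U <- model$bounds["U"]
    if (any(y < L - 1e-12) || any(y > U + 1e-12)) {
      stop_saqmap("y outside the model bounds",
                  class = "saqmap_validation_error")
    }
    at_one <- y >= 1 - 1e-12
    eta1 <- drop(X %*% model$gamma)
    ll <- ifelse(at_one, stats::plogis(eta1, log.p = TRUE),
                 stats::plogis(eta1, lower.tail = FALSE, log.p = TRUE))
    if (any(!at_one)) {
      Xc <- X[!at_one, , drop = FALSE]
      ystar <- (y[!at_one] - L) / (U - L)
      ystar <- clamp(ystar, 0.5 / sum(!at_one), 1 - 1e-10)
      dens <- matrix(NA_real_, nrow = sum(!at_one), ncol = model$C)
      for (cc in seq_len(model$C)) {
        mu <- clamp(logistic(drop(Xc %*% model$delta[, cc])),
                    1e-8, 1 - 1e-8)
        dens[, cc] <- log(model$weights[cc]) +
          stats::dbeta(ystar, mu * model$phi[cc],
                       (1 - mu) * model$phi[cc], log = TRUE)
      }
      m <- apply(dens, 1, max)
      ll[!at_one] <- ll[!at_one] + m + log(rowSums(exp(dens - m))) -
        log(U - L)
    }
    return(sum(ll))
  }
  stop_saqmap("unsupported model class", class = "saqmap_validation_error")
}
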