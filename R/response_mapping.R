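#' Fit per-dimension response models (indirect mapping)
#'
#' For each EQ-5D-5L dimension, fits a proportional-odds (ordered logit)
#' model of the dimension level on the five SAQ subscales:
#' \deqn{P(Y \le j \mid x) = \mathrm{logistic}(c_j - x'\beta),}
#' with no separate intercept (the cut points \eqn{c_j} play that role).
#' Categories are the distinct levels observed in the training data;
#' unobserved levels are collapsed away and later carry predicted
#' probability zero. A multinomial-logit variant is available for
#' sensitivity analysis.
#'
#' @param X design matrix over the subscales \emph{without} an intercept
#'   column (see \code{build_design(data, intercept = FALSE)}); an
#'   intercept column, if present, is dropped.
#' @param states data.frame of EQ-5D levels with columns
#'   \code{mo, sc, ua, pd, ad}.
#' @param type \code{"ordered"} (default, proportional odds) or
#'   \code{"multinomial"}.
#' @return object of class \code{saq_response_fit}: a list of five
#'   per-dimension models, each with \code{beta}, \code{cuts} (ordered
#'   logit only), \code{category_levels} (fitted category -> EQ-5D
#'   level), \code{vcov} and a convergence/separation flag.
#' @export
fit_response_models <- function(X, states, type = c("ordered",
                                                    "multinomial")) {
  type <- match.arg(type)
  if (!is.matrix(X)) X <- as.matrix(X)
  if ("(Intercept)" %in% colnames(X)) {
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  }
  st <- check_states(states)
  models <- list()
  for (d in eq5d_dimensions()) {
    lev <- sort(unique(st[, d]))
    if (length(lev) < 2) {
      stop_saqmap("dimension ", d, " has a single observed category",
                  class = "saqmap_validation_error")
    }
    yf <- factor(st[, d], levels = lev, ordered = TRUE)
    if (type == "ordered" && length(lev) == 2) {
      # two observed categories: the proportional-odds model reduces to
      # logistic regression; P(Y = high) = logistic(x'beta - cut)
      gfit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), as.numeric(st[, d] == lev[2]),
                       family = stats::binomial())
      )
      a <- gfit$coefficients[1]
      beta <- gfit$coefficients[-1]
      names(beta) <- colnames(X)
      separation <- any(abs(c(a, beta)) > 50)
      models[[d]] <- list(
        dimension = d, type = "ordered",
        beta = beta, cuts = unname(-a), category_levels = lev,
        vcov = NULL,
        convergence = list(converged = gfit$converged,
                           separation = separation)
      )
      next
    }
    if (type == "ordered") {
      dat <- data.frame(.y = yf, X, check.names = FALSE)
      fml <- stats::as.formula(paste(
        ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
      fit <- tryCatch(
        MASS::polr(fml, data = dat, method = "logistic", Hess = TRUE),
        error = function(e) {
          stop_saqmap("ordered logit failed for dimension ", d, ": ",
                      conditionMessage(e), class = "saqmap_fit_error")
        }
      )
      beta <- stats::coef(fit)
      names(beta) <- colnames(X)
      separation <- any(abs(beta) > 50) || any(abs(fit$zeta) > 50)
      if (separation) {
        warning("possible separation in dimension ", d,
                " (very large coefficients)")
      }
      vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      models[[d]] <- list(
        dimension = d, type = "ordered",
        # polr parameterises logit P(Y<=j) = zeta_j - eta, matching ours
        beta = beta, cuts = unname(fit$zeta), category_levels = lev,
        vcov = vc,
        convergence = list(converged = fit$convergence == 0,
                           separation = separation)
      )
    } else {
      dat <- data.frame(.y = factor(st[, d], levels = lev), X,
                        check.names = FALSE)
      fml <- stats::as.formula(paste(
        ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
      fit <- nnet_multinom_quietly(fml, dat)
      models[[d]] <- list(dimension = d, type = "multinomial",
                          fit = fit, category_levels = lev,
                          convergence = list(converged = TRUE,
                                             separation = FALSE))
    }
  }
  structure(list(models = models, columns = colnames(X), type = type),
            class = "saq_response_fit")
}

nnet_multinom_quietly <- function(fml, dat) {
  if (!requireNamespace("nnet", quietly = TRUE)) {
    stop_saqmap("the multinomial variant needs the 'nnet' package",
                class = "saqmap_validation_error")
  }
  out <- utils::capture.output(
    fit <- nnet::multinom(fml, data = dat, trace = FALSE)
  )
  fit
}

#' Predict EQ-5D level probabilities per dimension
#'
#' @param object a \code{saq_response_fit}.
#' @param X design matrix with the training subscale columns (intercept
#'   dropped if present).
#' @param ... unused.
#' @return object of class \code{saq_dim_probs}: named list (one element
#'   per dimension) of n x 5 probability matrices over EQ-5D levels 1-5;
#'   levels unobserved at training time have probability 0, rows sum
#'   to 1.
#' @export
predict.saq_response_fit <- function(object, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if ("(Intercept)" %in% colnames(X)) {
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  }
  if (!identical(colnames(X), object$columns)) {
    stop_saqmap("design columns do not match the fitted response models",
                class = "saqmap_validation_error")
  }
  out <- list()
  for (d in eq5d_dimensions()) {
    m <- object$models[[d]]
    probs <- matrix(0, nrow = nrow(X), ncol = 5,
                    dimnames = list(NULL, paste0("L", 1:5)))
    if (m$type == "ordered") {
      cat_probs <- ordered_probs(m$beta, m$cuts, X)
    } else {
      cat_probs <- stats::predict(m$fit,
                                  newdata = data.frame(X,
                                                       check.names = FALSE),
                                  type = "probs")
      if (is.null(dim(cat_probs))) cat_probs <- rbind(cat_probs)
    }
    probs[, m$category_levels] <- cat_probs
    out[[d]] <- probs
  }
  structure(out, class = "saq_dim_probs")
}

# category probabilities under logit P(Y<=j) = cut_j - x'beta
ordered_probs <- function(beta, cuts, X) {
  eta <- drop(X %*% beta)
  cum <- vapply(cuts, function(cj) logistic(cj - eta),
                numeric(length(eta)))
  if (is.null(dim(cum))) cum <- rbind(cum)
  cum <- cbind(cum, 1)
  out <- cbind(cum[, 1, drop = FALSE],
               cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Expected utility from dimension-level probabilities
#'
#' Converts predicted per-dimension level probabilities to a utility.
#' The default \code{"expected-decrement"} method computes
#' \deqn{EU = 1 - \sum_d \sum_l p_d(l)\,\delta_d(l),}
#' which is the exact expectation under an additive tariff when
#' dimensions are drawn independently. \code{"monte-carlo"} samples
#' states from independent per-dimension draws and averages tariff
#' values; \code{"modal"} scores the per-dimension argmax state.
#'
#' @param probs a \code{saq_dim_probs} (or a plain named list of n x 5
#'   matrices over the five dimensions).
#' @param vs value set.
#' @param method computation method; see Details.
#' @param draws Monte-Carlo draws per row (default 10000).
#' @param seed Monte-Carlo seed.
#' @return numeric vector of expected utilities, one per row.
#' @export
expected_utility <- function(probs, vs = load_value_set(),
                             method = c("expected-decrement",
                                        "monte-carlo", "modal"),
                             draws = 10000, seed = 1L) {
  method <- match.arg(method)
  dims <- eq5d_dimensions()
  if (!all(dims %in% names(probs))) {
    stop_saqmap("probs must contain all five dimensions",
                class = "saqmap_validation_error")
  }
  n <- nrow(probs[[dims[1]]])
  for (d in dims) {
    pm <- probs[[d]]
    if (any(pm < -1e-12) || any(abs(rowSums(pm) - 1) > 1e-6)) {
      stop_saqmap("probabilities for dimension ", d,
                  " are negative or do not sum to 1",
                  class = "saqmap_validation_error")
    }
  }
  if (method == "expected-decrement") {
    eu <- rep(1, n)
    for (d in dims) {
      eu <- eu - drop(probs[[d]] %*% vs$decrements[d, ])
    }
    return(eu)
  }
  if (method == "modal") {
    state <- as.data.frame(lapply(dims, function(d) {
      max.col(probs[[d]], ties.method = "first")
    }))
    names(state) <- dims
    return(eq5d_utility(state, vs))
  }
  # monte-carlo
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      lv <- vapply(dims, function(d) {
        sample.int(5, draws, replace = TRUE, prob = probs[[d]][i, ])
      }, integer(draws))
      dec <- numeric(draws)
      for (j in seq_along(dims)) {
        dec <- dec + vs$decrements[dims[j], ][lv[, j]]
      }
      mean(1 - dec)
    }, numeric(1))
  })
}
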