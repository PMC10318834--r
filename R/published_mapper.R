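#' Published mapping coefficient tables
#'
#' Loads the bundled published coefficient sets: the direct-approach
#' regression columns (OLS, Tobit, log-link GLM, CLAD, RMM), the mixture
#' columns (beta-mixture mean link \code{c1_mu} and ceiling-inflation
#' logit \code{pm_ub}; ALDVMM components \code{com1}/\code{com2}) and
#' the indirect-approach ordered-logit coefficients (per-dimension
#' subscale betas and three cut points). Values are stored exactly as
#' printed (4 decimal places); covariates are subscale scores divided by
#' 100, in the order PL, AS, AF, TS, DP.
#'
#' @return nested list mirroring the bundled JSON document.
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.json",
                      package = "saqmap", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

check_scores <- function(scores) {
  subs <- saq_subscales()
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- as.data.frame(as.list(scores))
  }
  missing_cols <- setdiff(subs, names(scores))
  if (length(missing_cols)) {
    stop_saqmap("scores are missing subscale(s): ",
                paste(missing_cols, collapse = ", "),
                class = "saqmap_validation_error")
  }
  sm <- as.matrix(scores[subs])
  if (anyNA(sm) || any(sm < 0) || any(sm > 100)) {
    stop_saqmap("subscale scores must lie in [0, 100] with no missing ",
                "values", class = "saqmap_validation_error")
  }
  sm / 100
}

linear_index <- function(coefs, x01) {
  drop(coefs[["constant"]] +
         x01 %*% unlist(coefs[saq_subscales()]))
}

#' Map SAQ subscale scores to utilities with published direct equations
#'
#' Applies a printed direct-approach coefficient column:
#' \code{utility = constant + beta . (scores/100)} (exponentiated for the
#' log-link GLM).
#'
#' @param scores data.frame (or named numeric vector) with subscale
#'   columns \code{pl, as, af, ts, dp} on the 0-100 scale.
#' @param method one of \code{"ols", "tobit", "glm", "clad", "rmm"}.
#' @param clamp clamp the result to \code{[-0.391, 1]} (default FALSE;
#'   published equations can exceed 1 for very healthy profiles).
#' @return numeric vector of utilities.
#' @examples
#' map_direct(data.frame(pl = 70.83, as = 36.18, af = 64.55,
#'                       ts = 67.69, dp = 51.80), "ols")
#' @export
map_direct <- function(scores, method = c("ols", "tobit", "glm", "clad",
                                          "rmm"),
                       clamp = FALSE) {
  method <- match.arg(method)
  x01 <- check_scores(scores)
  coefs <- published_coefficients()$direct[[method]]
  eta <- linear_index(coefs, x01)
  out <- if (method == "glm") exp(eta) else eta
  if (clamp) out <- clamp(out, -0.391, 1)
  out
}

#' Map SAQ scores with the published mixture-model columns
#'
#' The published mixture columns omit several quantities needed for a
#' full expected-value prediction (mixture weights, component scales,
#' beta precision, the gap boundary). The beta mixture needs only the
#' rescaling bounds, which default to the tariff range; the ALDVMM needs
#' explicit \code{sigma}, \code{pi} and \code{psi} assumptions and
#' refuses to invent them.
#'
#' @param scores as in \code{\link{map_direct}}.
#' @param method \code{"bm"} or \code{"aldvmm"}.
#' @param assumptions list of unprinted quantities. For \code{"bm"}:
#'   \code{bounds = c(L, U)} (default \code{c(-0.391, 1)}). For
#'   \code{"aldvmm"}: \code{sigma} (length-2), \code{pi} (length-2,
#'   summing to 1), \code{psi}, and optionally \code{floor} (default
#'   -0.391) — all required, no silent defaults.
#' @return numeric vector of expected utilities (always <= 1).
#' @export
map_direct_mixture <- function(scores, method = c("bm", "aldvmm"),
                               assumptions = list()) {
  method <- match.arg(method)
  x01 <- check_scores(scores)
  pub <- published_coefficients()$mixture[[method]]
  if (method == "bm") {
    bounds <- assumptions$bounds %||% c(-0.391, 1)
    L <- bounds[1]; U <- bounds[2]
    p1 <- logistic(linear_index(pub$pm_ub, x01))
    mu <- logistic(linear_index(pub$c1_mu, x01))
    return(p1 + (1 - p1) * (L + (U - L) * mu))
  }
  need <- c("sigma", "pi", "psi")
  absent <- need[!need %in% names(assumptions)]
  if (length(absent)) {
    stop_saqmap("the published ALDVMM column omits ",
                paste(absent, collapse = ", "),
                "; supply them via `assumptions` (no defaults are ",
                "assumed for unprinted parameters)",
                class = "saqmap_validation_error")
  }
  sigma <- assumptions$sigma
  pi_k <- assumptions$pi
  psi <- assumptions$psi
  floor_u <- assumptions$floor %||% -0.391
  if (length(sigma) != 2 || length(pi_k) != 2 ||
      abs(sum(pi_k) - 1) > 1e-8) {
    stop_saqmap("aldvmm assumptions need length-2 sigma and pi ",
                "(pi summing to 1)", class = "saqmap_validation_error")
  }
  mu <- cbind(linear_index(pub$com1, x01), linear_index(pub$com2, x01))
  out <- numeric(nrow(x01))
  for (k in 1:2) {
    p1 <- stats::pnorm((psi - mu[, k]) / sigma[k], lower.tail = FALSE)
    pf <- stats::pnorm((floor_u - mu[, k]) / sigma[k])
    pm <- pmax(1 - p1 - pf, 0)
    etr <- truncnorm_mean(mu[, k], sigma[k], floor_u, psi)
    out <- out + pi_k[k] * (p1 + pf * floor_u + pm * etr)
  }
  out
}

#' Map SAQ scores to dimension probabilities and utility (indirect)
#'
#' Applies the published per-dimension ordered-logit coefficients:
#' category probabilities from \eqn{P(Y \le j) =
#' \mathrm{logistic}(c_j - x'\beta)} with \eqn{x} = scores/100, then the
#' expected-decrement utility under the bundled tariff. The published
#' tables report three cuts (four categories) per dimension without
#' stating which EQ-5D levels were merged; \code{level_map} supplies the
#' category-to-level assumption and defaults to levels 1-4. Treat
#' predictions under the default map as carrying that documented
#' assumption.
#'
#' @param scores as in \code{\link{map_direct}}.
#' @param level_map integer vector mapping fitted categories to EQ-5D
#'   levels; must be strictly increasing within 1-5 (default
#'   \code{1:4}). Either one vector for all dimensions or a named list
#'   per dimension.
#' @param vs value set for the expected-decrement step.
#' @return list with \code{probabilities} (a \code{saq_dim_probs}) and
#'   \code{utility} (numeric vector).
#' @export
map_indirect <- function(scores, level_map = 1:4, vs = load_value_set()) {
  x01 <- check_scores(scores)
  pub <- published_coefficients()$indirect
  dims <- eq5d_dimensions()
  if (!is.list(level_map)) {
    level_map <- stats::setNames(rep(list(level_map), 5), dims)
  }
  probs <- list()
  for (d in dims) {
    lm_d <- level_map[[d]]
    ncat <- length(pub[[d]]$cuts) + 1
    if (length(lm_d) != ncat || any(duplicated(lm_d)) ||
        !all(lm_d %in% 1:5) || is.unsorted(lm_d)) {
      stop_saqmap("level_map for ", d, " must be ", ncat,
                  " strictly increasing levels within 1-5",
                  class = "saqmap_validation_error")
    }
    beta <- unlist(pub[[d]]$beta[saq_subscales()])
    cat_probs <- ordered_probs(beta, pub[[d]]$cuts, x01)
    pm <- matrix(0, nrow = nrow(x01), ncol = 5,
                 dimnames = list(NULL, paste0("L", 1:5)))
    pm[, lm_d] <- cat_probs
    probs[[d]] <- pm
  }
  probs <- structure(probs, class = "saq_dim_probs")
  list(probabilities = probs,
       utility = expected_utility(probs, vs))
}
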