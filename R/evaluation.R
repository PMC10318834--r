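#' Goodness-of-fit metrics for utility predictions
#'
#' Computes the four indicators used to judge mapping models: mean
#' absolute error, root mean squared error, Pearson correlation and
#' Lin's concordance correlation coefficient
#' \deqn{CCC = \frac{2\,\mathrm{cov}(o,p)}
#'   {\mathrm{var}(o) + \mathrm{var}(p) + (\bar o - \bar p)^2},}
#' with population (1/n) moments by default (Lin's original estimator);
#' set \code{moments = "sample"} for the 1/(n-1) variant.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @param moments \code{"population"} (default) or \code{"sample"}.
#' @return one-row data.frame with columns \code{mae, rmse, rho, ccc}.
#'   \code{rho}/\code{ccc} are \code{NA} (with a warning) when either
#'   vector has zero variance.
#' @examples
#' compute_metrics(c(0.2, 0.5, 0.9), c(0.3, 0.5, 0.8))
#' @export
compute_metrics <- function(observed, predicted,
                            moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop_saqmap("observed and predicted must have equal length >= 2",
                class = "saqmap_validation_error")
  }
  err <- observed - predicted
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  n <- length(observed)
  denom <- if (moments == "population") n else n - 1
  vo <- sum((observed - mean(observed))^2) / denom
  vp <- sum((predicted - mean(predicted))^2) / denom
  if (vo < 1e-300 || vp < 1e-300) {
    warning("zero variance: rho and CCC are undefined")
    rho <- NA_real_
    ccc <- NA_real_
  } else {
    cv <- sum((observed - mean(observed)) *
                (predicted - mean(predicted))) / denom
    rho <- cv / sqrt(vo * vp)
    ccc <- 2 * cv / (vo + vp + (mean(observed) - mean(predicted))^2)
  }
  data.frame(mae = mae, rmse = rmse, rho = rho, ccc = ccc)
}

#' Summarise predictions and paired change
#'
#' Table-style summary of a prediction vector: mean, minimum, maximum,
#' and — when the cohort carries paired waves — the mean within-patient
#' change (follow-up minus baseline) over patients with both waves.
#'
#' @param pred numeric predictions aligned with \code{cohort} rows.
#' @param cohort data.frame with at least \code{pid} and \code{wave}
#'   columns (\code{wave} 1 = baseline, 2 = follow-up).
#' @return one-row data.frame \code{mean, min, max, mean_change}
#'   (\code{mean_change} is \code{NA}, with a warning, when no pids have
#'   both waves).
#' @export
summarize_predictions <- function(pred, cohort) {
  if (length(pred) != nrow(cohort)) {
    stop_saqmap("pred length does not match cohort rows",
                class = "saqmap_validation_error")
  }
  out <- data.frame(mean = mean(pred), min = min(pred), max = max(pred),
                    mean_change = NA_real_)
  if (all(c("pid", "wave") %in% names(cohort))) {
    b <- cohort$wave == 1
    f <- cohort$wave == 2
    paired <- intersect(cohort$pid[b], cohort$pid[f])
    if (length(paired)) {
      pb <- pred[b][match(paired, cohort$pid[b])]
      pf <- pred[f][match(paired, cohort$pid[f])]
      out$mean_change <- mean(pf - pb)
    } else {
      warning("no paired pids: mean_change is NA")
    }
  } else {
    warning("cohort lacks pid/wave columns: mean_change is NA")
  }
  out
}

#' Assign k-fold cross-validation folds
#'
#' Random partition into k folds whose sizes differ by at most one;
#' deterministic for a fixed seed. With \code{group_by_pid}, all rows of
#' a patient land in the same fold.
#'
#' @param cohort data.frame of records.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param group_by_pid keep each patient's rows together (default FALSE,
#'   mirroring a row-level split).
#' @return integer vector of fold indices (1..k), one per row.
#' @export
assign_folds <- function(cohort, k = 5, seed = 1L, group_by_pid = FALSE) {
  n <- nrow(cohort)
  if (n < k) {
    stop_saqmap("need at least k records", class = "saqmap_validation_error")
  }
  with_seed(seed, {
    if (group_by_pid && "pid" %in% names(cohort)) {
      pids <- unique(cohort$pid)
      fp <- rep(seq_len(k), length.out = length(pids))[sample.int(length(pids))]
      fp[match(cohort$pid, pids)]
    } else {
      rep(seq_len(k), length.out = n)[sample.int(n)]
    }
  })
}

# registry: fit on training rows, predict on validation rows.
# each entry returns a numeric prediction vector for `valid`.
method_registry <- function(vs, n_starts = 10, seed = 1L) {
  direct <- function(fitter, ...) {
    args <- list(...)
    function(train, valid) {
      Xt <- build_design(train)
      Xv <- build_design(valid)
      fit <- do.call(fitter, c(list(Xt, train$utility), args))
      predict(fit, Xv)
    }
  }
  list(
    ols = direct(fit_ols),
    tobit = direct(fit_tobit),
    glm = direct(fit_glm_log),
    clad = direct(fit_clad, se = "none"),
    rmm = direct(fit_rmm, seed = seed),
    bm = direct(fit_betamix, vs = vs, n_starts = n_starts, seed = seed),
    aldvmm = direct(fit_aldvmm, vs = vs, n_starts = n_starts, seed = seed),
    indirect = function(train, valid) {
      Xt <- build_design(train, intercept = FALSE)
      Xv <- build_design(valid, intercept = FALSE)
      fit <- fit_response_models(Xt, train[eq5d_dimensions()])
      expected_utility(predict(fit, Xv), vs)
    }
  )
}

#' k-fold cross-validation of mapping models
#'
#' For each fold, trains every requested method on the remaining folds
#' and predicts the held-out fold. Metrics are reported pooled over all
#' held-out predictions (primary) and per fold; both are returned since
#' either convention is used in the mapping literature. A method that
#' fails on a fold is flagged and the others continue.
#'
#' @param cohort cohort data.frame with subscales \code{pl..dp}, EQ-5D
#'   state columns, and \code{utility}.
#' @param methods character vector among \code{ols, tobit, glm, clad,
#'   rmm, bm, aldvmm, indirect}.
#' @param k folds (default 5).
#' @param seed seed for the fold assignment and any stochastic fitter.
#' @param group_by_pid see \code{\link{assign_folds}}.
#' @param vs value set (used by the mixture/indirect methods).
#' @param n_starts random starts for the mixture fitters inside CV.
#' @return object of class \code{saq_cv_report}: list with
#'   \code{folds} (assignment), \code{pooled} (data.frame, one row per
#'   method), \code{per_fold}, \code{predictions} (held-out predictions
#'   per method) and \code{failures}.
#' @export
crossvalidate <- function(cohort, methods = c("ols", "tobit", "glm", "clad",
                                              "rmm", "bm", "aldvmm",
                                              "indirect"),
                          k = 5, seed = 1L, group_by_pid = FALSE,
                          vs = load_value_set(), n_starts = 10) {
  registry <- method_registry(vs, n_starts = n_starts, seed = seed)
  unknown <- setdiff(methods, names(registry))
  if (length(unknown)) {
    stop_saqmap("unknown method(s): ", paste(unknown, collapse = ", "),
                class = "saqmap_validation_error")
  }
  folds <- assign_folds(cohort, k = k, seed = seed,
                        group_by_pid = group_by_pid)
  n <- nrow(cohort)
  preds <- matrix(NA_real_, nrow = n, ncol = length(methods),
                  dimnames = list(NULL, methods))
  failures <- list()
  for (fold in seq_len(k)) {
    hold <- folds == fold
    train <- cohort[!hold, , drop = FALSE]
    valid <- cohort[hold, , drop = FALSE]
    for (m in methods) {
      res <- tryCatch(registry[[m]](train, valid), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(method = m, fold = fold, message = conditionMessage(res))
      } else {
        preds[hold, m] <- res
      }
    }
  }
  pooled <- do.call(rbind, lapply(methods, function(m) {
    ok <- !is.na(preds[, m])
    if (sum(ok) < 2) {
      return(data.frame(model = m, mae = NA_real_, rmse = NA_real_,
                        rho = NA_real_, ccc = NA_real_))
    }
    cbind(model = m, compute_metrics(cohort$utility[ok], preds[ok, m]))
  }))
  per_fold <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(seq_len(k), function(fold) {
      ok <- folds == fold & !is.na(preds[, m])
      if (sum(ok) < 2) return(NULL)
      cbind(model = m, fold = fold,
            n = sum(ok), compute_metrics(cohort$utility[ok], preds[ok, m]))
    }))
  }))
  structure(list(folds = folds, pooled = pooled, per_fold = per_fold,
                 predictions = preds, failures = failures, k = k,
                 seed = seed),
            class = "saq_cv_report")
}

#' @export
print.saq_cv_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  df <- x$pooled
  df[-1] <- lapply(df[-1], function(v) round(v, 4))
  print(df, row.names = FALSE)
  if (length(x$failures)) {
    cat("failures:", length(x$failures), "fold-model fits\n")
  }
  invisible(x)
}
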