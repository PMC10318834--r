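#' Run the full mapping analysis pipeline on a cohort
#'
#' Reproduces the structure of a complete SAQ-to-EQ-5D-5L mapping study
#' on one cohort: fits all seven direct models (OLS, Tobit, log-link
#' GLM, CLAD, RMM, beta mixture, ALDVMM) and the indirect ordered-logit
#' model on the full sample, producing
#' \itemize{
#'   \item a full-sample report (per model: prediction mean/min/max,
#'     mean paired baseline-to-follow-up change, MAE, RMSE, Pearson rho,
#'     Lin's CCC),
#'   \item a k-fold cross-validation report,
#'   \item coefficient tables for the direct and indirect equations, and
#'   \item observed-vs-predicted scatter data.
#' }
#' A model that fails to fit is recorded and the run continues. When
#' \code{out_dir} is given, all reports are written as CSV plus a JSON
#' run log (package version, seeds, value set).
#'
#' @param cohort cohort data.frame (see \code{\link{read_cohort}} /
#'   \code{\link{generate_cohort}}).
#' @param out_dir optional output directory.
#' @param k cross-validation folds (default 5).
#' @param seed seed for fold assignment and stochastic fitters.
#' @param vs value set.
#' @param methods model set (default all eight).
#' @param n_starts random starts for the mixture fitters.
#' @return list with \code{full_sample}, \code{cv} (a
#'   \code{saq_cv_report}), \code{models}, \code{coefficients},
#'   \code{scatter} and \code{failures}.
#' @export
run_mapping_pipeline <- function(cohort, out_dir = NULL, k = 5, seed = 1L,
                                 vs = load_value_set(),
                                 methods = c("ols", "tobit", "glm", "clad",
                                             "rmm", "bm", "aldvmm",
                                             "indirect"),
                                 n_starts = 10) {
  registry <- method_registry(vs, n_starts = n_starts, seed = seed)
  X <- build_design(cohort)
  Xr <- build_design(cohort, intercept = FALSE)
  y <- cohort$utility
  models <- list()
  failures <- list()
  preds <- list()
  for (m in methods) {
    res <- tryCatch({
      fit <- switch(m,
        ols = fit_ols(X, y),
        tobit = fit_tobit(X, y),
        glm = fit_glm_log(X, y),
        clad = fit_clad(X, y, se = "none"),
        rmm = fit_rmm(X, y, seed = seed),
        bm = fit_betamix(X, y, vs = vs, n_starts = n_starts, seed = seed),
        aldvmm = fit_aldvmm(X, y, vs = vs, n_starts = n_starts,
                            seed = seed),
        indirect = fit_response_models(Xr, cohort[eq5d_dimensions()])
      )
      pred <- if (m == "indirect") {
        expected_utility(predict(fit, Xr), vs)
      } else {
        predict(fit, X)
      }
      list(fit = fit, pred = pred)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[m]] <- conditionMessage(res)
    } else {
      models[[m]] <- res$fit
      preds[[m]] <- res$pred
    }
  }

  observed_row <- cbind(model = "observed",
                        summarize_predictions(y, cohort),
                        mae = NA_real_, rmse = NA_real_,
                        rho = NA_real_, ccc = NA_real_)
  full <- do.call(rbind, c(list(observed_row), lapply(names(preds),
    function(m) {
      cbind(model = m, summarize_predictions(preds[[m]], cohort),
            compute_metrics(y, preds[[m]]))
    })))
  rownames(full) <- NULL

  cv <- crossvalidate(cohort, methods = intersect(methods, names(preds)),
                      k = k, seed = seed, vs = vs, n_starts = n_starts)

  coef_direct <- do.call(rbind, lapply(names(models), function(m) {
    f <- models[[m]]
    if (inherits(f, "saq_direct_fit")) {
      data.frame(model = m, term = names(f$coefficients),
                 estimate = unname(f$coefficients))
    }
  }))
  coef_indirect <- NULL
  if (!is.null(models$indirect)) {
    coef_indirect <- do.call(rbind, lapply(models$indirect$models,
      function(mm) {
        rbind(data.frame(dimension = mm$dimension, term = names(mm$beta),
                         estimate = unname(mm$beta)),
              data.frame(dimension = mm$dimension,
                         term = paste0("cut", seq_along(mm$cuts)),
                         estimate = mm$cuts))
      }))
    rownames(coef_indirect) <- NULL
  }
  scatter <- data.frame(pid = cohort$pid, wave = cohort$wave,
                        observed = y, preds)

  out <- list(full_sample = full, cv = cv, models = models,
              coefficients = list(direct = coef_direct,
                                  indirect = coef_indirect),
              scatter = scatter, failures = failures)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(full, file.path(out_dir, "full_sample_report.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$pooled, file.path(out_dir, "cv_pooled.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$per_fold, file.path(out_dir, "cv_per_fold.csv"),
                     row.names = FALSE)
    if (!is.null(coef_direct)) {
      utils::write.csv(coef_direct,
                       file.path(out_dir, "coefficients_direct.csv"),
                       row.names = FALSE)
    }
    if (!is.null(coef_indirect)) {
      utils::write.csv(coef_indirect,
                       file.path(out_dir, "coefficients_indirect.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(scatter,
                     file.path(out_dir, "observed_vs_predicted.csv"),
                     row.names = FALSE)
    log <- list(package_version =
                  as.character(utils::packageVersion("saqmap")),
                seed = seed, k = k, value_set = vs$name,
                methods = methods, n = nrow(cohort),
                failures = failures)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
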