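#' Read and write cohort CSV files
#'
#' The cohort CSV schema has one row per patient-wave: \code{pid, wave},
#' either raw items \code{saq_q1..saq_q19} or subscales
#' \code{pl, as, af, ts, dp}, EQ-5D levels \code{mo, sc, ua, pd, ad},
#' and optional covariates. Header required, UTF-8, missing cells empty.
#' \code{read_cohort} scores raw items to subscales when subscale
#' columns are absent, recomputes \code{utility} from the state columns
#' when present (utilities are never trusted free-floating), and
#' validates levels.
#'
#' @param path CSV path.
#' @param vs value set used to (re)compute utilities.
#' @param item_map item map for scoring raw items if needed.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path, vs = load_value_set(),
                        item_map = saq_item_map()) {
  if (!file.exists(path)) {
    stop_saqmap("cohort file not found: ", path, class = "saqmap_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_saqmap("malformed cohort CSV (", path, "): ",
                                    conditionMessage(e),
                                    class = "saqmap_parse_error")
  )
  subs <- saq_subscales()
  if (!all(subs %in% names(df))) {
    if (all(item_map$item %in% names(df))) {
      df <- cbind(df, score_saq(df[item_map$item], item_map))
    } else {
      stop_saqmap("cohort CSV needs either subscale columns (",
                  paste(subs, collapse = ", "), ") or all 19 item columns",
                  class = "saqmap_validation_error")
    }
  }
  if (all(eq5d_dimensions() %in% names(df))) {
    df$utility <- eq5d_utility(df[eq5d_dimensions()], vs)
  }
  df
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Generates a baseline cohort plus paired follow-up wave and writes the
#' cohort CSV with a JSON sidecar recording the seed, config hash and
#' package version, so any run can be reproduced exactly.
#'
#' @param config a \code{\link{generator_config}}.
#' @param path output CSV path (sidecar written to \code{<path>.meta.json}).
#' @param vs value set.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return the cohort data.frame, invisibly.
#' @export
simulate_cohort <- function(config = generator_config(), path,
                            vs = load_value_set(), seed = config$seed) {
  validate_generator_config(config)
  cohort <- generate_cohort(config, vs, seed = seed)
  if (config$followup_fraction * config$n >= 2) {
    cohort <- generate_followup(cohort, config, vs,
                                seed = seed + 500000L)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, path)
  meta <- list(seed = seed, config_hash = cfg_cache_key(config, vs),
               n_rows = nrow(cohort),
               package_version = as.character(utils::packageVersion("saqmap")),
               value_set = vs$name)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(cohort)
}

#' Save or load a fitted mapping model as JSON
#'
#' Serialises the coefficient content of a fitted model (method tag,
#' coefficient names/values, scales, vcov, convergence block and package
#' version) to a human-inspectable JSON document.
#'
#' @param model a fitted \code{saq_direct_fit} or \code{saq_mixture_fit}.
#' @param path JSON path.
#' @export
save_model_json <- function(model, path) {
  doc <- unclass(model)
  if (!is.null(doc$coefficients)) {
    doc$coefficients <- as.list(doc$coefficients)  # keep names in JSON
  }
  doc$package_version <- as.character(utils::packageVersion("saqmap"))
  doc$class <- class(model)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- doc$class
  doc$class <- NULL
  p <- length(doc$coefficients %||% doc$beta)
  if (!is.null(doc$vcov) && is.numeric(doc$vcov)) {
    k <- as.integer(sqrt(length(doc$vcov)))
    doc$vcov <- matrix(doc$vcov, k, k)
  }
  if (!is.null(doc$beta) && !is.null(doc$K) && is.numeric(doc$beta)) {
    doc$beta <- matrix(doc$beta, ncol = doc$K)
  }
  if (!is.null(doc$delta) && !is.null(doc$C) && is.numeric(doc$delta) &&
      length(doc$delta) > doc$C - 1) {
    doc$delta <- matrix(doc$delta, ncol = doc$C)
  }
  structure(doc, class = cls)
}

#' Map a CSV of SAQ data to utilities with the published equations
#'
#' Reads a CSV of SAQ subscale scores (or raw items, which are scored
#' first), appends one utility column per requested method using the
#' published coefficient tables, and optionally writes the result.
#'
#' @param input input CSV path.
#' @param output optional output CSV path.
#' @param methods direct methods and/or \code{"indirect"} (default
#'   \code{c("ols", "indirect")}).
#' @param clamp clamp predictions to \code{[-0.391, 1]}.
#' @param vs value set for the indirect step.
#' @param item_map item map for raw-item inputs.
#' @return the augmented data.frame, invisibly when \code{output} given.
#' @export
map_saq_file <- function(input, output = NULL,
                         methods = c("ols", "indirect"), clamp = FALSE,
                         vs = load_value_set(), item_map = saq_item_map()) {
  df <- tryCatch(
    utils::read.csv(input, stringsAsFactors = FALSE),
    error = function(e) stop_saqmap("malformed CSV (", input, "): ",
                                    conditionMessage(e),
                                    class = "saqmap_parse_error")
  )
  subs <- saq_subscales()
  if (!all(subs %in% names(df))) {
    if (all(item_map$item %in% names(df))) {
      df <- cbind(df, score_saq(df[item_map$item], item_map))
    } else {
      missing_cols <- setdiff(subs, names(df))
      stop_saqmap("input is missing subscale column(s): ",
                  paste(missing_cols, collapse = ", "),
                  class = "saqmap_validation_error")
    }
  }
  for (m in methods) {
    col <- paste0("utility_", m)
    if (m == "indirect") {
      u <- map_indirect(df[subs], vs = vs)$utility
      if (clamp) u <- clamp(u, vs$floor, 1)
      df[[col]] <- u
    } else {
      df[[col]] <- map_direct(df[subs], m, clamp = clamp)
    }
  }
  if (!is.null(output)) {
    utils::write.csv(df, output, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
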