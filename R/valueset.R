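#' EQ-5D-5L dimensions
#'
#' Column names used throughout the package for the five EQ-5D-5L
#' dimensions: mobility (\code{mo}), self-care (\code{sc}), usual
#' activities (\code{ua}), pain/discomfort (\code{pd}) and
#' anxiety/depression (\code{ad}).
#'
#' @export
eq5d_dimensions <- function() c("mo", "sc", "ua", "pd", "ad")

#' Load an EQ-5D-5L value set (tariff)
#'
#' A value set maps each of the 3,125 EQ-5D-5L health states to a utility
#' through additive per-dimension, per-level decrements:
#' \deqn{U(s) = 1 - \sum_d \delta_d(\mathrm{level}_d),}
#' with \eqn{\delta_d(1) = 0}. The bundled \code{"china-5L"} tariff spans
#' utilities from -0.391 (state 55555) to 1 (full health, state 11111).
#'
#' @param source either the name of a bundled tariff (currently
#'   \code{"china-5L"}) or a path to a CSV constants file with columns
#'   \code{dimension, level, decrement} (dimension in
#'   \code{eq5d_dimensions()}, level 1-5; level-1 rows may be omitted and
#'   are taken as decrement 0).
#' @param name optional display name; defaults to the bundled name or the
#'   file name.
#'
#' @return An object of class \code{eq5d_value_set}: a list with elements
#'   \code{name}, \code{decrements} (5 x 5 matrix, dimensions x levels),
#'   \code{floor} (utility of state 55555) and \code{ceiling} (1).
#'
#' @details Integrity checks enforced on load: decrements are non-negative
#'   and non-decreasing in level within each dimension, the level-1
#'   decrement is zero, \code{utility(11111) == 1}, and for the bundled
#'   Chinese tariff \code{utility(55555) == -0.391}.
#'
#' @examples
#' vs <- load_value_set("china-5L")
#' eq5d_utility(data.frame(mo = 1, sc = 1, ua = 1, pd = 1, ad = 1), vs)
#' @export
load_value_set <- function(source = "china-5L", name = NULL) {
  bundled <- c("china-5L" = "china_5l_tariff.csv")
  expected_floor <- NA_real_
  if (source %in% names(bundled)) {
    path <- system.file("extdata", bundled[[source]], package = "saqmap",
                        mustWork = TRUE)
    name <- name %||% source
    if (source == "china-5L") expected_floor <- -0.391
  } else {
    if (!file.exists(source)) {
      stop_saqmap("value set source not found: ", source,
                  class = "saqmap_io_error")
    }
    path <- source
    name <- name %||% basename(source)
  }
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_saqmap("malformed value-set constants file: ",
                                    conditionMessage(e),
                                    class = "saqmap_parse_error")
  )
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tab))) {
    stop_saqmap("value-set constants file must have columns ",
                paste(need, collapse = ", "), class = "saqmap_parse_error")
  }
  dims <- eq5d_dimensions()
  dec <- matrix(NA_real_, nrow = 5, ncol = 5,
                dimnames = list(dims, paste0("L", 1:5)))
  tab$dimension <- tolower(tab$dimension)
  if (!all(tab$dimension %in% dims) || !all(tab$level %in% 1:5)) {
    stop_saqmap("value-set rows must use dimensions ",
                paste(dims, collapse = "/"), " and levels 1-5",
                class = "saqmap_parse_error")
  }
  dec[cbind(match(tab$dimension, dims), tab$level)] <- tab$decrement
  dec[, 1][is.na(dec[, 1])] <- 0
  if (anyNA(dec)) {
    stop_saqmap("value-set constants file is missing dimension/level rows",
                class = "saqmap_parse_error")
  }
  vs <- structure(
    list(name = name, decrements = dec,
         floor = 1 - sum(dec[, 5]), ceiling = 1),
    class = "eq5d_value_set"
  )
  validate_value_set(vs, expected_floor = expected_floor)
  vs
}

validate_value_set <- function(vs, expected_floor = NA_real_) {
  dec <- vs$decrements
  if (any(dec < 0)) {
    stop_saqmap("value-set integrity error: negative decrement",
                class = "saqmap_integrity_error")
  }
  if (any(dec[, 1] != 0)) {
    stop_saqmap("value-set integrity error: level-1 decrement must be 0",
                class = "saqmap_integrity_error")
  }
  if (any(apply(dec, 1, diff) < 0)) {
    stop_saqmap("value-set integrity error: decrements must be ",
                "non-decreasing in level", class = "saqmap_integrity_error")
  }
  if (!is.na(expected_floor) &&
      abs(vs$floor - expected_floor) > 1e-9) {
    stop_saqmap("value-set integrity error: floor ", format(vs$floor),
                " does not match expected ", format(expected_floor),
                class = "saqmap_integrity_error")
  }
  invisible(vs)
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-5L value set:", x$name, "\n")
  cat("  utility range: [", format(x$floor), ", ", format(x$ceiling),
      "]\n", sep = "")
  print(round(x$decrements, 4))
  invisible(x)
}

check_states <- function(states) {
  dims <- eq5d_dimensions()
  if (is.matrix(states)) states <- as.data.frame(states)
  if (!all(dims %in% names(states))) {
    stop_saqmap("states must have columns ", paste(dims, collapse = ", "),
                class = "saqmap_validation_error")
  }
  st <- as.matrix(states[dims])
  if (anyNA(st) || !all(st %in% 1:5)) {
    bad <- which(!(st %in% 1:5) | is.na(st))
    stop_saqmap("EQ-5D levels must be integers 1-5 (", length(bad),
                " offending cell(s))", class = "saqmap_validation_error")
  }
  st
}

#' Score EQ-5D-5L states to utilities
#'
#' Applies an additive tariff to one or more EQ-5D-5L states.
#'
#' @param states a data.frame (or matrix) with integer columns
#'   \code{mo, sc, ua, pd, ad}, each level in 1-5.
#' @param vs an \code{eq5d_value_set}, e.g. \code{load_value_set()}.
#' @return Numeric vector of utilities in \code{[vs$floor, 1]}.
#' @examples
#' vs <- load_value_set()
#' eq5d_utility(data.frame(mo = 2, sc = 1, ua = 1, pd = 1, ad = 1), vs)
#' @export
eq5d_utility <- function(states, vs = load_value_set()) {
  st <- check_states(states)
  dec <- vs$decrements
  total <- numeric(nrow(st))
  for (d in seq_len(5)) total <- total + dec[d, st[, d]]
  unname(1 - total)
}

#' Enumerate all 3,125 EQ-5D-5L states with their utilities
#'
#' @param vs an \code{eq5d_value_set}.
#' @return data.frame with columns \code{mo, sc, ua, pd, ad, utility},
#'   one row per health state.
#' @export
utility_table <- function(vs = load_value_set()) {
  grid <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(names(grid))]
  grid$utility <- eq5d_utility(grid, vs)
  grid
}
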