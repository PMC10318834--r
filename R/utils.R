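# Internal helpers shared across modules.

logistic <- function(x) {
  # plogis handles +/-Inf correctly (1 and 0)
  stats::plogis(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_saqmap <- function(..., class = "saqmap_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
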