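#' Default SAQ item map
#'
#' The Seattle Angina Questionnaire has 19 items in five subscales:
#' physical limitation (PL, 9 items scored 1-6), anginal stability
#' (AS, 1 item, 1-5), anginal frequency (AF, 2 items, 1-6), treatment
#' satisfaction (TS, 4 items, 1-5) and disease perception (DP, 3 items,
#' 1-5). Items are identified as \code{saq_q1 .. saq_q19} in instrument
#' order. The map is a plain data.frame so alternative scorings can be
#' supplied to \code{\link{score_saq}}.
#'
#' @return data.frame with columns \code{item, subscale, min, max}.
#' @export
saq_item_map <- function() {
  map <- data.frame(
    item = paste0("saq_q", 1:19),
    subscale = rep(c("pl", "as", "af", "ts", "dp"), c(9, 1, 2, 4, 3)),
    min = 1L,
    max = rep(c(6L, 5L, 6L, 5L, 5L), c(9, 1, 2, 4, 3)),
    stringsAsFactors = FALSE
  )
  map
}

saq_subscales <- function() c("pl", "as", "af", "ts", "dp")

validate_item_map <- function(item_map) {
  need <- c("item", "subscale", "min", "max")
  if (!all(need %in% names(item_map))) {
    stop_saqmap("item map must have columns ", paste(need, collapse = ", "),
                class = "saqmap_validation_error")
  }
  if (anyDuplicated(item_map$item)) {
    stop_saqmap("duplicate items in item map",
                class = "saqmap_validation_error")
  }
  if (any(item_map$min >= item_map$max)) {
    stop_saqmap("item map has min >= max", class = "saqmap_validation_error")
  }
  invisible(item_map)
}

#' Score SAQ item responses to 0-100 subscale scores
#'
#' Each subscale is scored by summing its item responses, subtracting the
#' lowest possible sum, dividing by the subscale range and multiplying by
#' 100, so 0 is the worst and 100 the best attainable score.
#'
#' @param responses data.frame of item responses, one row per respondent,
#'   with columns named as in \code{item_map$item}. Missing responses as
#'   \code{NA}.
#' @param item_map item-to-subscale map; see \code{\link{saq_item_map}}.
#' @param missing \code{"impute"} (default): when at least half of a
#'   subscale's items are answered, missing items are imputed with the
#'   within-respondent mean of the answered items of that subscale;
#'   otherwise the subscale score is \code{NA}. \code{"strict"}: any
#'   missing item makes the subscale \code{NA}.
#'
#' @return data.frame with numeric columns \code{pl, as, af, ts, dp},
#'   each in \code{[0, 100]} (or \code{NA} when unscorable).
#' @examples
#' resp <- as.data.frame(as.list(setNames(rep(1, 19), paste0("saq_q", 1:19))))
#' score_saq(resp)  # all subscales 0
#' @export
score_saq <- function(responses, item_map = saq_item_map(),
                      missing = c("impute", "strict")) {
  missing <- match.arg(missing)
  validate_item_map(item_map)
  absent <- setdiff(item_map$item, names(responses))
  if (length(absent)) {
    stop_saqmap("responses are missing item column(s): ",
                paste(absent, collapse = ", "),
                class = "saqmap_validation_error")
  }
  resp <- as.matrix(responses[item_map$item])
  storage.mode(resp) <- "double"
  for (j in seq_len(ncol(resp))) {
    bad <- which(!is.na(resp[, j]) &
                   (resp[, j] < item_map$min[j] | resp[, j] > item_map$max[j] |
                      resp[, j] != round(resp[, j])))
    if (length(bad)) {
      stop_saqmap("response out of range for item ", item_map$item[j],
                  " (row ", bad[1], "): allowed ", item_map$min[j], "-",
                  item_map$max[j], class = "saqmap_validation_error")
    }
  }
  out <- matrix(NA_real_, nrow = nrow(resp), ncol = 5,
                dimnames = list(NULL, saq_subscales()))
  for (sub in saq_subscales()) {
    idx <- which(item_map$subscale == sub)
    block <- resp[, idx, drop = FALSE]
    lo <- sum(item_map$min[idx])
    hi <- sum(item_map$max[idx])
    answered <- rowSums(!is.na(block))
    k <- length(idx)
    sums <- rowSums(block, na.rm = TRUE)
    if (missing == "impute") {
      # impute unanswered items with the respondent's mean answered item
      ok <- answered >= ceiling(k / 2) & answered > 0
      mean_answered <- ifelse(answered > 0, sums / answered, NA_real_)
      sums <- sums + (k - answered) * mean_answered
    } else {
      ok <- answered == k
    }
    score <- (sums - lo) / (hi - lo) * 100
    score[!ok] <- NA_real_
    out[, sub] <- score
  }
  as.data.frame(out)
}
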