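# Composite scoring of the OQ and RFL item blocks.
#
# OQ items 13, 24 and 31 are positively worded ("I am a happy person", ...)
# and printed with a reversed answer scale, so their answer position p is
# scored 4 - p; items 3 and 8 are distress-worded and scored as-is. Item 8
# ("I think about taking my life") stays a standalone variable.

OQ_REVERSED <- c(13L, 24L, 31L)

#' Score the OQ item block
#'
#' Reverse-keys items 13, 24 and 31 (score = 4 - answer position), averages
#' the four non-screening items (3, 13, 24, 31) into `oq_mean`, and passes
#' item 8 through unchanged as the suicidal-ideation screen `oq8`. Higher
#' scores always mean more distress.
#'
#' @param oq_items Named numeric vector or one-row data frame with entries
#'   `oq_3`, `oq_8`, `oq_13`, `oq_24`, `oq_31`, each an answer position 0..4.
#' @param reversed Integer item ids to reverse-key; the default is the
#'   instrument's printed keying.
#' @return A list with `oq_mean` (real in \[0, 4\]) and `oq8` (integer 0..4).
#' @export
#' @examples
#' score_oq(c(oq_3 = 2, oq_8 = 1, oq_13 = 1, oq_24 = 3, oq_31 = 4))
score_oq <- function(oq_items, reversed = OQ_REVERSED) {
  ids <- c(3L, 8L, 13L, 24L, 31L)
  x <- .item_vector(oq_items, "oq", ids, 0, 4)
  scored <- x
  rev_cols <- paste0("oq_", intersect(ids, reversed))
  scored[rev_cols] <- 4 - scored[rev_cols]
  mean_items <- paste0("oq_", setdiff(ids, 8L))
  list(oq_mean = mean(scored[mean_items]), oq8 = as.integer(x[["oq_8"]]))
}

#' Score the RFL item block
#'
#' Averages the 13 reasons-for-living items excluding item 25 into
#' `rfl_mean` and passes item 25 ("I'm too stable to kill myself") through
#' unchanged as `rfl25`. All RFL items share the protective direction, so no
#' reversal is applied; higher scores mean stronger reasons to live.
#'
#' @param rfl_items Named numeric vector or one-row data frame with entries
#'   `rfl_2` .. `rfl_50`, each 1..6.
#' @return A list with `rfl_mean` (real in \[1, 6\]) and `rfl25`
#'   (integer 1..6).
#' @export
score_rfl <- function(rfl_items) {
  ids <- c(2L, 5L, 10L, 12L, 14L, 17L, 19L, 20L, 22L, 24L, 25L, 40L, 45L, 50L)
  x <- .item_vector(rfl_items, "rfl", ids, 1, 6)
  mean_items <- paste0("rfl_", setdiff(ids, 25L))
  list(rfl_mean = mean(x[mean_items]), rfl25 = as.integer(x[["rfl_25"]]))
}

# Coerce a named vector / one-row data frame into a validated named vector.
.item_vector <- function(items, prefix, ids, lo, hi) {
  if (is.data.frame(items)) {
    stopifnot(nrow(items) == 1)
    items <- unlist(items[, paste0(prefix, "_", ids), drop = FALSE])
  }
  nm <- paste0(prefix, "_", ids)
  missing <- setdiff(nm, names(items))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing item(s): ", paste(missing, collapse = ", ")),
                 class = "pvq_scoring_error")
  }
  x <- as.numeric(items[nm])
  names(x) <- nm
  bad <- nm[is.na(x) | x < lo | x > hi | x != round(x)]
  if (length(bad) > 0) {
    rlang::abort(paste0("item(s) out of range ", lo, "..", hi, ": ",
                        paste(bad, collapse = ", ")),
                 class = "pvq_scoring_error")
  }
  x
}
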