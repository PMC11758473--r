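#' Canonical daily emotion items
#'
#' The daily diary asks how well each of 16 feeling words described the day,
#' rated 0 ("None of the time") to 4 ("All of the time"). Seven items are
#' negatively valenced and nine positively valenced; the two sets are scored
#' separately throughout the package (composites, emodiversity, reliability).
#'
#' @param valence `"negative"`, `"positive"`, or `"all"` (default).
#'
#' @return A character vector of item names. `emotion_items()` returns all 16
#'   in canonical order (negative items first).
#' @examples
#' emotion_items("negative")
#' length(emotion_items())
#' @export
emotion_items <- function(valence = c("all", "negative", "positive")) {
  valence <- match.arg(valence)
  switch(valence,
    negative = NEGATIVE_ITEMS,
    positive = POSITIVE_ITEMS,
    all = c(NEGATIVE_ITEMS, POSITIVE_ITEMS)
  )
}

NEGATIVE_ITEMS <- c(
  "anxious", "sad", "angry", "frustrated", "disgusted", "lonely", "ashamed"
)

POSITIVE_ITEMS <- c(
  "enthusiastic", "happy", "satisfied", "confident", "calm",
  "like_you_belong", "close_to_others", "proud", "full_of_life"
)

#' @rdname emotion_items
#' @export
item_valence <- function() {
  stats::setNames(
    rep(c("negative", "positive"), c(length(NEGATIVE_ITEMS), length(POSITIVE_ITEMS))),
    c(NEGATIVE_ITEMS, POSITIVE_ITEMS)
  )
}

RATING_MIN <- 0L
RATING_MAX <- 4L

DYAD_ROLES <- c("adolescent", "caregiver")

GENDER_GROUPS <- c("boy", "girl", "other", "unreported")
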