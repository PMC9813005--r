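# Flag-type extractors: interaction/mediation/moderation and test
# direction.

# Sentences about interactions of organisms rather than variables are
# removed before keyword matching.
interaction_exclusion <- paste0(
  "\\bsocial\\b|child|mother|baby|babies|\\bcell|infant|peer|famil|",
  "animal|parent|teacher|friend|spouse|partner[s]?\\b|sibling|dyad"
)

#' Detect interaction, mediation and moderation analyses
#'
#' Searches the lower-cased methods/results text for keyword families of
#' interaction, mediator and moderator effects. Sentences about the
#' interaction of organisms (mother-infant interaction, peer interaction,
#' cell interactions, ...) are removed before matching so they cannot
#' produce false alarms.
#'
#' @param text Character vector.
#' @return An `interaction_flags` object: logicals `interaction`,
#'   `mediator`, `moderator` and the derived `any`.
#' @examples
#' detect_interaction("The A × B interaction was significant.")
#' detect_interaction("Mother-infant interaction was coded.")
#' @export
detect_interaction <- function(text) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  sents <- sents[!grepl(interaction_exclusion, sents, perl = TRUE)]
  interaction <- any(grepl("interact(ion|ed|ing)?", sents, perl = TRUE))
  mediator <- any(grepl("(?<!im)mediat(or|ion|ing|ed|es)", sents, perl = TRUE))
  moderator <- any(grepl("moderat(or|ion|ing|ed)", sents, perl = TRUE))
  structure(
    list(
      interaction = interaction, mediator = mediator, moderator = moderator,
      any = interaction || mediator || moderator
    ),
    class = "interaction_flags"
  )
}

#' @export
print.interaction_flags <- function(x, ...) {
  on <- c("interaction", "mediator", "moderator")[
    c(x$interaction, x$mediator, x$moderator)
  ]
  cat("<interaction_flags>", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

# Reference words whose sentences are excluded to avoid false one-sided
# hits ("one-sided aggression", "see page 3", signalling pathways, ...).
direction_exclusion <- "\\bpaper\\b|\\bpage\\b|pathway|aggress|one side of|on (the|one|two) sides?"

#' Extract the reported test direction
#'
#' Restricts attention to sentences containing a test/hypothesis trigger
#' term, removes sentences with known false-alarm contexts (paper, page,
#' pathway, ...), and maps synonym families of one-sided (one-tailed,
#' directed, directional) and two-sided (two-tailed, undirected,
#' non-directional) testing onto an enum. In default mode "two tails" is
#' not an inclusion pattern; `extended_patterns` adds it.
#'
#' @param text Character vector.
#' @param extended_patterns Also accept the "two tails"/"one tail"
#'   phrasings.
#' @return One of `"none"`, `"one_sided"`, `"two_sided"`, `"both"`.
#' @examples
#' extract_test_direction("All tests were two-tailed.")
#' @export
extract_test_direction <- function(text, extended_patterns = FALSE) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  sents <- sents[grepl("test|hypothes|tail|sided|direct", sents, perl = TRUE)]
  sents <- sents[!grepl(direction_exclusion, sents, perl = TRUE)]
  one_pat <- "one[- ](sided|tailed)|1[- ]tailed|(?<!un)(?<!non-)(?<!non )directed (test|hypothes)|(?<!un)(?<!non-)(?<!non )directional (test|hypothes)"
  two_pat <- "two[- ](sided|tailed)|2[- ]tailed|undirected|non-?directional"
  if (extended_patterns) {
    one_pat <- paste0(one_pat, "|one[- ]tail\\b")
    two_pat <- paste0(two_pat, "|two[- ]tails\\b")
  }
  one <- any(grepl(one_pat, sents, perl = TRUE))
  two <- any(grepl(two_pat, sents, perl = TRUE))
  if (one && two) "both" else if (one) "one_sided" else if (two) "two_sided" else "none"
}
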