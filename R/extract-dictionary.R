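# Dictionary-driven extractors: multiple-testing corrections, statistical
# assumptions and analysis software.

#' Extract multiple-testing correction methods
#'
#' Two-stage search: only sentences containing one of the trigger terms
#' "adjust", "correct", "post-hoc" or "multiple" are inspected for the
#' author names and procedure names of the correction dictionary. A
#' "Bonferroni test" mentioned without any indication that something was
#' corrected or adjusted with it is therefore not reported. Common
#' misspellings (e.g. "Bonfferoni") are detected but returned under the
#' canonical spelling.
#'
#' @param text Character vector (methods/results/captions surface).
#' @param dictionary Correction dictionary, see [correction_terms()].
#' @return A `correction_result` with canonical `authors` and
#'   `procedures`, each sorted.
#' @examples
#' extract_multiple_comparison("P-values were Bonfferoni corrected.")
#' @export
extract_multiple_comparison <- function(text, dictionary = correction_terms()) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  sents <- sents[grepl("adjust|correct|post-? ?hoc|multiple", sents, perl = TRUE)]
  hit <- function(pattern) any(grepl(pattern, sents, perl = TRUE))
  found <- vapply(dictionary$pattern, hit, logical(1))
  authors <- sort(unique(dictionary$canonical[found & dictionary$type == "author"]))
  procedures <- sort(unique(dictionary$canonical[found & dictionary$type == "procedure"]))
  structure(list(authors = authors, procedures = procedures),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> authors:",
      if (length(x$authors)) paste(x$authors, collapse = ", ") else "none", "\n")
  if (length(x$procedures)) {
    cat("  procedures:", paste(x$procedures, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract mentioned statistical assumptions
#'
#' Dictionary search over the methods/results surface against the 20-entry
#' assumption gazetteer. Matching is longest-label-first with matched text
#' consumed, so "missing completely at random" does not additionally emit
#' "missing at random". Assumption phrases outside the dictionary yield no
#' hit.
#'
#' @param text Character vector.
#' @param dictionary Assumption dictionary, see [assumption_dictionary()].
#' @return An `assumption_hits` object with the sorted label set
#'   `assumptions`.
#' @examples
#' extract_assumptions("The assumption of sphericity was tested.")
#' @export
extract_assumptions <- function(text, dictionary = assumption_dictionary()) {
  s <- tolower(letter_convert(collapse_text(text)))
  ord <- order(nchar(dictionary$label), decreasing = TRUE)
  dictionary <- dictionary[ord, ]
  hits <- character()
  for (i in seq_len(nrow(dictionary))) {
    p <- dictionary$pattern[i]
    if (grepl(p, s, perl = TRUE)) {
      hits <- c(hits, dictionary$label[i])
      s <- gsub(p, " ", s, perl = TRUE)
    }
  }
  structure(list(assumptions = sort(hits)), class = "assumption_hits")
}

#' @export
print.assumption_hits <- function(x, ...) {
  cat("<assumption_hits>",
      if (length(x$assumptions)) paste(x$assumptions, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Extract mentioned analysis software
#'
#' Fine-grained dictionary search of 55 software names and their empirical
#' representation in text (case conventions, version suffixes, spelling
#' variants). Data-acquisition tools are not part of the default
#' dictionary but additional terms can be passed through `add`; those are
#' matched as literal strings and reported separately.
#'
#' @param text Character vector.
#' @param add Character vector of user-defined additional terms.
#' @param dictionary Software dictionary, see [software_dictionary()].
#' @return A `software_hits` object with canonical `software` names and
#'   `user_added` matches, each sorted.
#' @examples
#' extract_software("Analyses were run in SPSS version 25.")
#' extract_software("ConQuest 2.0 was used.", add = "ConQuest 2.0")
#' @export
extract_software <- function(text, add = character(),
                             dictionary = software_dictionary()) {
  s <- letter_convert(collapse_text(text))
  found <- vapply(dictionary$pattern, function(p) {
    grepl(p, s, perl = TRUE)
  }, logical(1))
  user <- vapply(add, function(term) {
    grepl(term, s, fixed = TRUE)
  }, logical(1))
  structure(
    list(
      software = sort(unique(dictionary$name[found])),
      user_added = sort(unique(add[user]))
    ),
    class = "software_hits"
  )
}

#' @export
print.software_hits <- function(x, ...) {
  all <- c(x$software, x$user_added)
  cat("<software_hits>",
      if (length(all)) paste(all, collapse = ", ") else "none", "\n")
  invisible(x)
}
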