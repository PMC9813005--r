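# Harvesting of statistical-method mentions.

#' Extract statistical method mentions
#'
#' Detects sentences containing one of the identifier terms that commonly
#' used procedures share as their last word (test, correlation,
#' regression, ANOVA, method, theorem, interval, algorithm, analysis,
#' model, estimator) and harvests, per hit, up to seven preceding words
#' with the identifier at the end. Harvested phrases are lower-cased,
#' clipped at clause boundaries, cleaned with a curated list of redundant
#' leading words and de-duplicated. Phrases consisting of the bare
#' identifier are discarded, so simple descriptive measures (mean,
#' standard deviation, proportion) are never returned as stand-alone
#' methods. New, still unknown procedures are picked up as long as their
#' name ends with an identifier term; `add` extends the identifier list.
#'
#' @param text Character vector.
#' @param add Additional identifier terms (single lower-case words).
#' @return A `method_mentions` object with the sorted set `methods` of
#'   lower-cased phrases (hyphens normalized to spaces).
#' @examples
#' extract_methods("We applied the quickfit algorithm.")
#' extract_methods("A repeated measures anova was conducted.")
#' @export
extract_methods <- function(text, add = character()) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  id_pat <- method_identifier_pattern
  if (length(add) > 0) {
    add <- tolower(trimws(add))
    id_pat <- paste(c(id_pat, paste0("^(", add, ")$")), collapse = "|")
  }
  phrases <- character()
  for (s in sents) {
    # clause boundaries stop the preceding-word window
    for (chunk in strsplit(s, "[,;:()\\[\\]]+")[[1]]) {
      toks <- strsplit(trimws(chunk), "\\s+")[[1]]
      toks <- gsub("^[\"'’‘]+|[\"'’‘.!?]+$", "", toks)
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0) next
      # an identifier may be the last word of a hyphenated compound
      last_word <- vapply(strsplit(gsub("-", " ", toks), " "), function(w) {
        w[length(w)]
      }, character(1))
      for (i in which(grepl(id_pat, last_word, perl = TRUE))) {
        window <- toks[max(1, i - method_window_words):i]
        # strip redundant words and number tokens from the left edge
        while (length(window) > 1 &&
               (window[1] %in% method_redundant_words ||
                grepl("^[0-9.%<>=±+-]+$", window[1]))) {
          window <- window[-1]
        }
        if (length(window) <= 1) next # bare identifier: not a method name
        phrases <- c(phrases, gsub("-", " ", paste(window, collapse = " ")))
      }
    }
  }
  structure(list(methods = sort(unique(phrases))), class = "method_mentions")
}

#' @export
print.method_mentions <- function(x, ...) {
  cat("<method_mentions>\n")
  if (length(x$methods) == 0) {
    cat("  none\n")
  } else {
    cat(paste0("  - ", x$methods, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Count the number of reported studies
#'
#' Identifies enumerated studies or experiments in the section titles and
#' the abstract ("Study 1", "Experiment 6", "Study One", "three
#' experiments") and returns the highest value; `1` when no numbering is
#' identified. Word numbers are converted before taking the maximum.
#'
#' @param section_titles Character vector of section titles.
#' @param abstract Abstract text (optional).
#' @return A positive integer count of reported studies.
#' @examples
#' count_studies(c("Study 1", "Study 2", "General Discussion"))
#' count_studies(c("Methods", "Results"))
#' @export
count_studies <- function(section_titles, abstract = "") {
  titles <- text2num(letter_convert(section_titles), percentages = FALSE,
                     fractions = FALSE)
  abs_txt <- text2num(letter_convert(collapse_text(abstract)),
                      percentages = FALSE, fractions = FALSE)
  n <- integer()
  pat <- "(?i)(?:stud(?:y|ies)|experiments?)\\s*([0-9]+)"
  for (s in c(titles, abs_txt)) {
    for (m in regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]) {
      n <- c(n, as.integer(sub(pat, "\\1", m, perl = TRUE)))
    }
  }
  rev_pat <- "(?i)\\b([0-9]+)\\s+(?:sub-?)?(?:studies|experiments)\\b"
  for (m in regmatches(abs_txt, gregexpr(rev_pat, abs_txt, perl = TRUE))[[1]]) {
    n <- c(n, as.integer(sub(rev_pat, "\\1", m, perl = TRUE)))
  }
  n <- n[n >= 1 & n <= 100]
  if (length(n) == 0) 1L else max(n)
}
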