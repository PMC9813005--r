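# Shipped gazetteers: correction authors/procedures, statistical
# assumptions, analysis software and the method-category taxonomy. Each is
# a plain CSV under extdata so users can supply an amended copy through the
# `dictionary`/`file` arguments of the corresponding extractor.

read_dictionary <- function(file) {
  stopifnot(file.exists(file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
  tibble::as_tibble(df)
}

dict_path <- function(name) {
  system.file("extdata", name, package = "studychar", mustWork = TRUE)
}

#' Dictionary of multiple-testing correction terms
#'
#' Twelve author names associated with correction procedures (matched with
#' misspelling-tolerant patterns but always returned under their canonical
#' spelling) and four named procedures such as the family-wise error rate
#' and the false discovery rate.
#'
#' @param file Optional path to a replacement CSV with columns
#'   `type` (`author`/`procedure`), `canonical` and `pattern`.
#' @return A tibble with columns `type`, `canonical`, `pattern`.
#' @export
correction_terms <- function(file = NULL) {
  read_dictionary(file %||% dict_path("correction_terms.csv"))
}

#' Dictionary of statistical assumptions
#'
#' Twenty common assumptions covering model adequacy, covariate structure
#' and missing/sampling mechanisms. Matching is longest-label-first so that
#' e.g. "missing completely at random" does not additionally emit
#' "missing at random".
#'
#' @param file Optional path to a replacement CSV with columns `label`,
#'   `pattern`.
#' @return A tibble with columns `label`, `pattern`.
#' @export
assumption_dictionary <- function(file = NULL) {
  read_dictionary(file %||% dict_path("assumptions.csv"))
}

#' Dictionary of analysis software
#'
#' Fifty-five software solutions with patterns tuned to their empirical
#' representation in article text. The entry for the R language requires a
#' version number, "R Core Team" or an "the R environment/language/..."
#' context so the bare letter never matches.
#'
#' @param file Optional path to a replacement CSV with columns `name`,
#'   `pattern`.
#' @return A tibble with columns `name`, `pattern`.
#' @export
software_dictionary <- function(file = NULL) {
  read_dictionary(file %||% dict_path("software.csv"))
}

#' Method-category taxonomy
#'
#' Category labels with the search expression used to map raw method
#' mentions onto categorized statistical methods (e.g. `"Logistic
#' regression"`, `"ANOVA"`). One mention may match several categories; a
#' generic `"regression"` mention and a `"multilevel regression"` mention
#' both count towards "Regression analysis".
#'
#' @param file Optional path to a replacement CSV with columns `label`,
#'   `pattern`.
#' @return A tibble with columns `label`, `pattern`.
#' @export
method_categories <- function(file = NULL) {
  df <- read_dictionary(file %||% dict_path("method_categories.csv"))
  if (anyDuplicated(df$label)) {
    stop("method category labels must be unique", call. = FALSE)
  }
  ok <- vapply(df$pattern, function(p) {
    !inherits(try(grepl(p, "", perl = TRUE), silent = TRUE), "try-error")
  }, logical(1))
  if (!all(ok)) {
    stop("invalid category pattern(s): ",
         paste(df$label[!ok], collapse = ", "), call. = FALSE)
  }
  df
}

# Search terms that identify a statistical-method phrase by its last word.
method_identifier_pattern <- paste0(
  "^(tests?|correlations?|regressions?|anovas?|ancovas?|manovas?|",
  "mancovas?|methods?|theorems?|intervals?|algorithms?|analys[ei]s|",
  "models?|estimators?)$"
)

# Number of words preceding the identifier that are harvested.
method_window_words <- 7L

# Iteratively curated redundant words stripped from the left edge of a
# harvested method phrase.
method_redundant_words <- c(
  "a", "an", "the", "this", "that", "these", "those", "was", "were", "is",
  "are", "be", "been", "being", "we", "our", "they", "their", "it", "its",
  "all", "each", "both", "and", "or", "as", "of", "in", "on", "for", "to",
  "with", "by", "from", "at", "using", "used", "use", "apply", "applied",
  "applying", "conduct", "conducted", "conducting", "perform", "performed",
  "performing", "compute", "computed", "calculate", "calculated", "ran",
  "run", "fit", "fitted", "fitting", "report", "reported", "reporting",
  "show", "showed", "shown", "present", "presented", "obtain", "obtained",
  "include", "included", "via", "then", "also", "first",
  "second", "third", "further", "additionally", "subsequently", "finally",
  "initial", "final", "same", "separate", "respective", "corresponding",
  "following", "several", "main", "additional", "new", "subsequent",
  "prior", "preliminary", "one", "two", "three", "significant"
)
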