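# Mapping raw method mentions onto categorized statistical methods and
# tabulating article counts per category.

#' Categorize method mentions
#'
#' Assigns a method category whenever any mention matches the category's
#' search expression. One mention may hit several categories: a
#' "logistic regression" mention counts towards both "Logistic
#' regression" and the generic "Regression analysis".
#'
#' @param mentions A `method_mentions` object or a character vector of
#'   lower-cased method phrases.
#' @param categories Category table from [method_categories()].
#' @return Character vector of matched category labels (alphabetical).
#' @examples
#' categorize_methods("logistic regression")
#' @export
categorize_methods <- function(mentions, categories = method_categories()) {
  if (inherits(mentions, "method_mentions")) mentions <- mentions$methods
  mentions <- tolower(mentions)
  if (length(mentions) == 0) return(character())
  hit <- vapply(categories$pattern, function(p) {
    any(grepl(p, mentions, perl = TRUE))
  }, logical(1))
  sort(categories$label[hit])
}

#' Tabulate method categories over a corpus
#'
#' Counts, per category, the number of articles with at least one matching
#' method mention. Duplicate mentions within one article never inflate the
#' count.
#'
#' @param records List of `study_character` records.
#' @param categories Category table from [method_categories()].
#' @return A tibble with columns `category` and `n_articles`, in the
#'   category-table order.
#' @export
tabulate_methods <- function(records, categories = method_categories()) {
  counts <- stats::setNames(integer(nrow(categories)), categories$label)
  for (r in records) {
    if (!inherits(r, "study_character")) next
    hits <- categorize_methods(r$methods, categories)
    counts[hits] <- counts[hits] + 1L
  }
  tibble::tibble(category = categories$label,
                 n_articles = as.integer(counts[categories$label]))
}
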