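# Article-level evaluation of extractions against a gold standard:
# multi-value confusion counting and the sensitivity / specificity /
# accuracy summary measures.

#' Score one article's extraction for one feature
#'
#' Article-level multi-value counting: every gold value that was extracted
#' is a correct positive, every gold value that was missed a false
#' negative, every extracted value outside the gold coding a false
#' positive. An article that does not contain the feature and for which
#' nothing was detected contributes one correct negative. With gold
#' \{0.05, 0.10\} and extraction \{0.05, 0.01\} the result is therefore
#' CP = 1, FN = 1, FP = 1.
#'
#' @param gold Character (or coercible) vector of manually coded values.
#' @param extracted Character (or coercible) vector of extracted values.
#' @return A `confusion_counts` object: named numeric with `CP`, `CN`,
#'   `FP`, `FN`.
#' @examples
#' score_article(c("0.05", "0.1"), c("0.05", "0.01"))
#' @export
score_article <- function(gold, extracted) {
  gold <- unique(canon_value(gold[!is.na(gold) & nzchar(trimws(gold))]))
  extracted <- unique(canon_value(extracted[!is.na(extracted) & nzchar(trimws(extracted))]))
  cp <- length(intersect(gold, extracted))
  fn <- length(setdiff(gold, extracted))
  fp <- length(setdiff(extracted, gold))
  cn <- as.integer(length(gold) == 0 && length(extracted) == 0)
  structure(c(CP = cp, CN = cn, FP = fp, FN = fn), class = "confusion_counts")
}

#' Sum confusion counts component-wise
#'
#' @param counts A list of `confusion_counts` (an empty list yields all
#'   zeros).
#' @return A `confusion_counts` with the component-wise sums.
#' @export
aggregate_counts <- function(counts) {
  out <- c(CP = 0, CN = 0, FP = 0, FN = 0)
  for (x in counts) out <- out + x[names(out)]
  structure(out, class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' sensitivity = CP/(CP+FN), specificity = CN/(CN+FP),
#' accuracy = (CP+CN)/(CP+FN+CN+FP). A measure whose denominator is zero
#' is undefined and returned as `NA` (a feature that always outputs a
#' value has no specificity).
#'
#' @param counts A `confusion_counts` (or named vector/list with `CP`,
#'   `CN`, `FP`, `FN`).
#' @param digits Round half-up to this many decimals; `NULL` for raw
#'   proportions.
#' @return A one-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' extraction_metrics(c(CP = 105, CN = 169, FP = 0, FN = 21))
#' @export
extraction_metrics <- function(counts, digits = 2) {
  counts <- unlist(counts)[c("CP", "CN", "FP", "FN")]
  ratio <- function(num, den) {
    if (den == 0) NA_real_ else unname(num / den)
  }
  m <- tibble::tibble(
    sensitivity = ratio(counts["CP"], counts["CP"] + counts["FN"]),
    specificity = ratio(counts["CN"], counts["CN"] + counts["FP"]),
    accuracy = ratio(counts["CP"] + counts["CN"], sum(counts))
  )
  if (!is.null(digits)) {
    m <- dplyr::mutate(m, dplyr::across(dplyr::everything(),
                                        ~ round_half_up(.x, digits)))
  }
  m
}

#' Read a gold-standard coding table
#'
#' The gold standard is a CSV with columns `article_id`, `feature`,
#' `value`: one row per manually coded value; a row with an empty value
#' marks the feature as explicitly absent for that article.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the three columns, values canonicalized.
#' @export
read_gold <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  stopifnot(all(c("article_id", "feature", "value") %in% names(df)))
  df$value <- ifelse(nzchar(trimws(df$value)), canon_value(df$value), "")
  tibble::as_tibble(df)
}

#' Evaluate extracted records against a gold standard
#'
#' For every feature and article, scores the extracted value set against
#' the gold coding with the multi-value counting of [score_article()],
#' aggregates the per-article counts and computes sensitivity,
#' specificity and accuracy per feature. Because articles can carry
#' several values of one feature, the total number of decisions may
#' exceed the number of articles.
#'
#' @param records List of `study_character` records, or a long tibble
#'   with columns `article_id`, `feature`, `value` (e.g. rebuilt from a
#'   JSONL record file).
#' @param gold Gold tibble from [read_gold()] (or a path to the CSV).
#' @param features Features to evaluate; defaults to every feature
#'   occurring in the gold standard or the records.
#' @param digits Rounding for the reported metrics (half-up).
#' @return An object of class `studychar_eval`: a tibble with one row per
#'   feature (`feature`, `CP`, `CN`, `FP`, `FN`, `total`, `sensitivity`,
#'   `specificity`, `accuracy`).
#' @export
evaluate_extractions <- function(records, gold, features = NULL, digits = 2) {
  if (is.character(gold)) gold <- read_gold(gold)
  extracted <- if (is.data.frame(records)) {
    tibble::as_tibble(records)
  } else {
    dplyr::bind_rows(lapply(records, function(r) {
      if (inherits(r, "study_character")) return(generics::tidy(r))
      NULL
    }))
  }
  if (nrow(extracted) == 0) {
    extracted <- tibble::tibble(article_id = character(),
                                feature = character(), value = character())
  }
  extracted$value <- canon_value(extracted$value)
  ids <- sort(unique(c(gold$article_id, extracted$article_id)))
  if (is.null(features)) {
    features <- sort(unique(c(gold$feature, extracted$feature)))
  }
  rows <- lapply(features, function(f) {
    per_article <- lapply(ids, function(id) {
      g <- gold$value[gold$feature == f & gold$article_id == id]
      g <- g[nzchar(g)]
      e <- extracted$value[extracted$feature == f & extracted$article_id == id]
      score_article(g, e)
    })
    counts <- aggregate_counts(per_article)
    m <- extraction_metrics(counts, digits = digits)
    tibble::tibble(
      feature = f, CP = counts[["CP"]], CN = counts[["CN"]],
      FP = counts[["FP"]], FN = counts[["FN"]], total = sum(counts),
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("studychar_eval", class(out))
  out
}

#' Plot an evaluation report
#'
#' Bar chart of sensitivity, specificity and accuracy per feature.
#'
#' @param object A `studychar_eval` from [evaluate_extractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
autoplot.studychar_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("feature", "sensitivity", "specificity", "accuracy")],
    cols = -"feature", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
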