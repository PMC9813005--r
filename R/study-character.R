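# Orchestration: run every extractor on its designated surface and
# aggregate the results into one article-level record.

#' Extraction configuration
#'
#' Bundles the user-adjustable settings of [study_character()]. The
#' defaults match the standard extraction mode: p-value thresholds count
#' as alpha-levels, captions are part of the default surface, table cell
#' content is parsed but not processed, and the outlier result space is
#' [1, 10] standard deviations.
#'
#' @param p2alpha Convert significance-threshold p-value statements into
#'   alpha-levels.
#' @param include_captions Include figure/table captions in the default
#'   extraction surface.
#' @param include_tables Include table cell content in the surface.
#' @param outlier_range Accepted SD range for outlier definitions.
#' @param add_software Additional software terms (matched verbatim).
#' @param add_methods Additional method identifier terms.
#' @param extended_patterns Enable additional test-direction phrasings
#'   ("two tails").
#' @param dictionaries Optional named list of replacement dictionary file
#'   paths (`corrections`, `assumptions`, `software`).
#' @return A list of class `sc_config`.
#' @export
sc_config <- function(p2alpha = TRUE, include_captions = TRUE,
                      include_tables = FALSE, outlier_range = c(1, 10),
                      add_software = character(), add_methods = character(),
                      extended_patterns = FALSE, dictionaries = list()) {
  stopifnot(length(outlier_range) == 2, outlier_range[1] <= outlier_range[2])
  structure(
    list(
      p2alpha = isTRUE(p2alpha),
      include_captions = isTRUE(include_captions),
      include_tables = isTRUE(include_tables),
      outlier_range = as.numeric(outlier_range),
      add_software = as.character(add_software),
      add_methods = as.character(add_methods),
      extended_patterns = isTRUE(extended_patterns),
      dictionaries = dictionaries
    ),
    class = "sc_config"
  )
}

#' Extract all methodological study characteristics of an article
#'
#' Runs every extractor on its designated text surface: the methods and
#' results sections (plus captions for the alpha-level, correction and
#' outlier extractors when enabled) for most features, the full document
#' text for test power, and the section titles plus abstract for the
#' study count. A failure inside one extractor is recorded under `errors`
#' for that feature and never aborts the remaining extractions.
#'
#' @param article A `jats_article` from [read_jats()] (or a path/XML
#'   string, which is parsed first).
#' @param config An [sc_config()].
#' @return A `study_character` record: `id` plus one component per
#'   feature (`methods`, `alpha`, `power`, `correction`, `interaction`,
#'   `direction`, `outlier`, `assumptions`, `software`, `n_studies`) and
#'   an `errors` list.
#' @examples
#' xml <- system.file("extdata", "example-article.xml", package = "studychar")
#' sc <- study_character(read_jats(xml))
#' sc$alpha$nominal
#' @export
study_character <- function(article, config = sc_config()) {
  if (is.character(article)) article <- read_jats(article)
  stopifnot(inherits(article, "jats_article"), inherits(config, "sc_config"))
  st <- classify_sections(article)

  mrc <- extraction_surface(st, include_captions = config$include_captions,
                            include_tables = config$include_tables)
  mr <- extraction_surface(st, include_captions = FALSE,
                           include_tables = config$include_tables)
  full_text <- collapse_text(c(
    st$abstract, st$introduction, st$methods, st$results, st$discussion,
    st$unclassified, st$captions
  ))

  dict <- config$dictionaries
  corr_dict <- if (!is.null(dict$corrections)) {
    correction_terms(dict$corrections)
  } else {
    correction_terms()
  }
  assum_dict <- if (!is.null(dict$assumptions)) {
    assumption_dictionary(dict$assumptions)
  } else {
    assumption_dictionary()
  }
  soft_dict <- if (!is.null(dict$software)) {
    software_dictionary(dict$software)
  } else {
    software_dictionary()
  }

  errors <- list()
  run <- function(feature, expr, empty) {
    tryCatch(expr, error = function(e) {
      errors[[feature]] <<- conditionMessage(e)
      empty
    })
  }

  res <- list(
    id = article$id,
    methods = run("methods", extract_methods(mr, add = config$add_methods),
                  structure(list(methods = character()), class = "method_mentions")),
    alpha = run("alpha", extract_alpha(mrc, p2alpha = config$p2alpha),
                new_alpha_result()),
    power = run("power", extract_power(full_text),
                structure(list(values = numeric(), beta_converted = numeric()),
                          class = "power_result")),
    correction = run("correction",
                     extract_multiple_comparison(mrc, dictionary = corr_dict),
                     structure(list(authors = character(), procedures = character()),
                               class = "correction_result")),
    interaction = run("interaction", detect_interaction(mr),
                      structure(list(interaction = FALSE, mediator = FALSE,
                                     moderator = FALSE, any = FALSE),
                                class = "interaction_flags")),
    direction = run("direction",
                    extract_test_direction(mr, extended_patterns = config$extended_patterns),
                    "none"),
    outlier = run("outlier",
                  extract_outlier_def(mrc, lo = config$outlier_range[1],
                                      hi = config$outlier_range[2]),
                  structure(list(sd_values = numeric(),
                                 lo = config$outlier_range[1],
                                 hi = config$outlier_range[2]),
                            class = "outlier_defs")),
    assumptions = run("assumptions",
                      extract_assumptions(mr, dictionary = assum_dict),
                      structure(list(assumptions = character()),
                                class = "assumption_hits")),
    software = run("software",
                   extract_software(mr, add = config$add_software,
                                    dictionary = soft_dict),
                   structure(list(software = character(), user_added = character()),
                             class = "software_hits")),
    n_studies = run("n_studies",
                    count_studies(st$section_titles, st$abstract), 1L),
    errors = errors
  )
  structure(res, class = "study_character")
}

#' @export
print.study_character <- function(x, ...) {
  cat("<study_character> ", x$id, "\n", sep = "")
  df <- generics::tidy(x)
  if (nrow(df) == 0) {
    cat("  no features detected\n")
  } else {
    for (f in unique(df$feature)) {
      cat(sprintf("  %-12s %s\n", f,
                  paste(df$value[df$feature == f], collapse = ", ")))
    }
  }
  if (length(x$errors)) {
    cat("  errors in:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Canonical value set of one feature of a record
#'
#' Returns the detected values of a feature as the canonical character
#' set used for serialization and gold-standard comparison (numbers as
#' plain decimal strings, names under their canonical spelling, flags as
#' labels).
#'
#' @param sc A `study_character` record.
#' @param feature One of `"alpha"`, `"power"`, `"correction"`,
#'   `"interaction"`, `"direction"`, `"outlier_sd"`, `"assumptions"`,
#'   `"software"`, `"methods"`, `"n_studies"`.
#' @return Character vector (possibly empty), sorted.
#' @export
feature_values <- function(sc, feature) {
  stopifnot(inherits(sc, "study_character"))
  out <- switch(
    feature,
    alpha = fmt_num(unique(c(sc$alpha$nominal, sc$alpha$corrected,
                             sc$alpha$from_ci))),
    power = fmt_num(sc$power$values),
    correction = c(sc$correction$authors, sc$correction$procedures),
    interaction = c("interaction", "mediator", "moderator")[
      c(sc$interaction$interaction, sc$interaction$mediator,
        sc$interaction$moderator)
    ],
    direction = if (identical(sc$direction, "both")) {
      c("one_sided", "two_sided")
    } else if (sc$direction %in% c("one_sided", "two_sided")) {
      sc$direction
    } else {
      character()
    },
    outlier_sd = fmt_num(sc$outlier$sd_values),
    assumptions = sc$assumptions$assumptions,
    software = c(sc$software$software, sc$software$user_added),
    methods = sc$methods$methods,
    n_studies = as.character(sc$n_studies),
    stop("unknown feature: ", feature, call. = FALSE)
  )
  sort(unique(out))
}

sc_features <- c(
  "methods", "alpha", "power", "correction", "interaction", "direction",
  "outlier_sd", "assumptions", "software", "n_studies"
)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a study-character record into a long tibble
#'
#' @param x A `study_character`.
#' @param ... Unused.
#' @return A tibble with columns `article_id`, `feature`, `value`, one row
#'   per detected value.
#' @export
tidy.study_character <- function(x, ...) {
  rows <- lapply(sc_features, function(f) {
    v <- feature_values(x, f)
    if (length(v) == 0) return(NULL)
    tibble::tibble(article_id = x$id, feature = f, value = v)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a study-character record
#'
#' @param x A `study_character`.
#' @param ... Unused.
#' @return A one-row tibble with per-feature detection counts.
#' @export
glance.study_character <- function(x, ...) {
  counts <- vapply(sc_features, function(f) length(feature_values(x, f)),
                   integer(1))
  tibble::as_tibble(c(list(article_id = x$id), as.list(counts)))
}

#' Convert a record to its serializable form
#'
#' @param sc A `study_character`.
#' @return A plain list with the article id, the raw per-feature results
#'   and the canonical value sets, suitable for JSON output.
#' @export
as_record <- function(sc) {
  stopifnot(inherits(sc, "study_character"))
  values <- lapply(sc_features, function(f) as.list(feature_values(sc, f)))
  names(values) <- sc_features
  list(
    id = sc$id,
    features = list(
      methods = sc$methods$methods,
      alpha = list(nominal = sc$alpha$nominal, corrected = sc$alpha$corrected,
                   from_ci = sc$alpha$from_ci,
                   max_alpha = sc$alpha$max_alpha,
                   min_alpha = sc$alpha$min_alpha),
      power = list(values = sc$power$values,
                   beta_converted = sc$power$beta_converted),
      correction = list(authors = sc$correction$authors,
                        procedures = sc$correction$procedures),
      interaction = list(interaction = sc$interaction$interaction,
                         mediator = sc$interaction$mediator,
                         moderator = sc$interaction$moderator,
                         any = sc$interaction$any),
      direction = sc$direction,
      outlier_sd = sc$outlier$sd_values,
      assumptions = sc$assumptions$assumptions,
      software = list(software = sc$software$software,
                      user_added = sc$software$user_added),
      n_studies = sc$n_studies
    ),
    values = values,
    errors = sc$errors
  )
}

#' Extract study characteristics for a batch of articles
#'
#' @param paths Character vector of JATS XML file paths.
#' @param config An [sc_config()].
#' @return A list of `study_character` records; per-file parse errors are
#'   returned as records with an `errors$parse` entry instead of aborting
#'   the batch.
#' @export
study_character_batch <- function(paths, config = sc_config()) {
  lapply(paths, function(p) {
    tryCatch(
      study_character(read_jats(p), config),
      error = function(e) {
        structure(
          list(id = basename(p), errors = list(parse = conditionMessage(e))),
          class = c("study_character_error", "list")
        )
      }
    )
  })
}

#' Write records as JSON Lines
#'
#' @param records List of `study_character` records (or error records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    obj <- if (inherits(r, "study_character")) {
      as_record(r)
    } else {
      list(id = r$id, errors = r$errors)
    }
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-Lines record file
#'
#' @param path Path to a file written by [write_records()].
#' @return List of plain record lists.
#' @export
read_records <- function(path) {
  lapply(readLines(path, warn = FALSE, encoding = "UTF-8"), function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE)
  })
}
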