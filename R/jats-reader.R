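#' Parse a NISO-JATS article
#'
#' Reads a NISO-JATS 1.x XML document (a file path or an XML string) into a
#' structured article: title, abstract, the body as an ordered list of
#' titled sections with their paragraphs, figure and table captions, table
#' cell content and the reference list. All character content is passed
#' through [letter_convert()]; the reference list is isolated so it can
#' never leak into the extraction surfaces.
#'
#' @param x Path to a JATS XML file, or a string containing JATS XML.
#' @param id Article identifier; defaults to the `article-id` element or
#'   the file name.
#' @return An object of class `jats_article` with fields `id`, `title`,
#'   `abstract`, `sections` (each a list with `title`, `path` of ancestor
#'   titles, and `paragraphs`), `captions`, `table_text` and
#'   `reference_list`.
#' @examples
#' xml <- "<article><front><article-meta><title-group>
#'   <article-title>T</article-title></title-group></article-meta></front>
#'   <body><sec><title>Methods</title><p>We did things.</p></sec></body>
#'   </article>"
#' art <- read_jats(xml)
#' art$sections[[1]]$title
#' @export
read_jats <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) == 1)
  is_doc <- grepl("^\\s*<", x)
  if (!is_doc && !file.exists(x)) {
    stop("file not found: ", x, call. = FALSE)
  }
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stop("malformed XML in ",
           if (is_doc) "input string" else x, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (xml2::xml_name(doc) != "article") {
    stop("unsupported format: expected a NISO-JATS <article> root, got <",
         xml2::xml_name(doc), ">", call. = FALSE)
  }

  lc <- function(v) letter_convert(v)
  txt <- function(nodes) lc(trimws(xml2::xml_text(nodes)))

  if (is.null(id)) {
    id_node <- xml2::xml_find_first(doc, ".//front//article-id")
    id <- if (!inherits(id_node, "xml_missing")) {
      trimws(xml2::xml_text(id_node))
    } else if (!is_doc) {
      basename(x)
    } else {
      "article"
    }
  }

  title_node <- xml2::xml_find_first(doc, ".//front//article-title")
  title <- if (inherits(title_node, "xml_missing")) "" else
    lc(trimws(xml2::xml_text(title_node)))

  abstract_ps <- xml2::xml_find_all(doc, ".//front//abstract//p")
  abstract <- collapse_text(txt(abstract_ps))

  body <- xml2::xml_find_first(doc, ".//body")
  sections <- list()
  walk_sec <- function(node, path) {
    title_n <- xml2::xml_find_first(node, "./title")
    sec_title <- if (inherits(title_n, "xml_missing")) "" else
      lc(trimws(xml2::xml_text(title_n)))
    paras <- txt(xml2::xml_find_all(node, "./p"))
    paras <- paras[nzchar(paras)]
    sections[[length(sections) + 1]] <<- list(
      title = sec_title, path = path, paragraphs = paras
    )
    for (child in xml2::xml_find_all(node, "./sec")) {
      walk_sec(child, c(path, sec_title))
    }
  }
  if (!inherits(body, "xml_missing")) {
    loose <- txt(xml2::xml_find_all(body, "./p"))
    loose <- loose[nzchar(loose)]
    if (length(loose) > 0) {
      sections[[length(sections) + 1]] <- list(
        title = "", path = character(), paragraphs = loose
      )
    }
    for (sec in xml2::xml_find_all(body, "./sec")) {
      walk_sec(sec, character())
    }
  }

  captions <- txt(xml2::xml_find_all(
    doc, ".//body//fig//caption | .//body//table-wrap//caption"
  ))
  captions <- captions[nzchar(captions)]
  table_text <- txt(xml2::xml_find_all(doc, ".//body//table-wrap//td | .//body//table-wrap//th"))
  table_text <- table_text[nzchar(table_text)]
  refs <- txt(xml2::xml_find_all(doc, ".//back//ref-list//ref"))
  refs <- refs[nzchar(refs)]

  structure(
    list(
      id = id, title = title, abstract = abstract, sections = sections,
      captions = captions, table_text = table_text, reference_list = refs
    ),
    class = "jats_article"
  )
}

#' @export
print.jats_article <- function(x, ...) {
  cat("<jats_article> ", x$id, "\n", sep = "")
  cat("  title:    ", substr(x$title, 1, 60), "\n", sep = "")
  cat("  sections: ", length(x$sections),
      " | captions: ", length(x$captions),
      " | references: ", length(x$reference_list), "\n", sep = "")
  invisible(x)
}

#' Section titles of a parsed article, in document order
#' @param article A `jats_article`.
#' @return Character vector of section titles (empty titles included).
#' @export
section_titles <- function(article) {
  vapply(article$sections, function(s) s$title, character(1))
}

# Title keyword sets for the four canonical buckets. Matching is
# case-insensitive substring; the first matching bucket in this fixed
# order wins.
section_keywords <- list(
  methods = c("method", "material", "procedure", "participant", "sample",
              "measure", "design", "apparatus", "analysis plan"),
  results = c("result", "finding", "analys"),
  discussion = c("discussion", "conclusion", "limitation", "implication"),
  introduction = c("introduction", "background", "theory")
)

classify_title <- function(title) {
  t <- tolower(title)
  if (!nzchar(trimws(t))) return(NA_character_)
  for (bucket in names(section_keywords)) {
    if (any(vapply(section_keywords[[bucket]], function(k) {
      grepl(k, t, fixed = TRUE)
    }, logical(1)))) {
      return(bucket)
    }
  }
  NA_character_
}

#' Classify article sections into the four canonical buckets
#'
#' Assigns every body section to introduction, methods, results or
#' discussion by keyword rules on its title; a section whose title matches
#' no bucket inherits the bucket of its nearest classified ancestor, and
#' remains unclassified otherwise. Every body paragraph ends up in exactly
#' one bucket. Captions, table text, the abstract and the section titles
#' are carried along separately.
#'
#' @param article A `jats_article` from [read_jats()].
#' @return An object of class `sectioned_text` with text fields
#'   `introduction`, `methods`, `results`, `discussion`, `unclassified`,
#'   `captions`, `tables`, `abstract` and the vector `section_titles`.
#' @export
classify_sections <- function(article) {
  stopifnot(inherits(article, "jats_article"))
  buckets <- list(
    introduction = character(), methods = character(),
    results = character(), discussion = character(),
    unclassified = character()
  )
  for (sec in article$sections) {
    bucket <- classify_title(sec$title)
    if (is.na(bucket)) {
      # nearest classified ancestor
      for (anc in rev(sec$path)) {
        anc_bucket <- classify_title(anc)
        if (!is.na(anc_bucket)) {
          bucket <- anc_bucket
          break
        }
      }
    }
    if (is.na(bucket)) bucket <- "unclassified"
    buckets[[bucket]] <- c(buckets[[bucket]], sec$paragraphs)
  }
  structure(
    list(
      introduction = collapse_text(buckets$introduction),
      methods = collapse_text(buckets$methods),
      results = collapse_text(buckets$results),
      discussion = collapse_text(buckets$discussion),
      unclassified = collapse_text(buckets$unclassified),
      captions = collapse_text(article$captions),
      tables = collapse_text(article$table_text),
      abstract = article$abstract,
      section_titles = section_titles(article)
    ),
    class = "sectioned_text"
  )
}

#' @export
print.sectioned_text <- function(x, ...) {
  cat("<sectioned_text>\n")
  for (f in c("introduction", "methods", "results", "discussion",
              "unclassified", "captions")) {
    cat(sprintf("  %-12s %d chars\n", f, nchar(x[[f]])))
  }
  invisible(x)
}

#' Build the selective text surface the extractors read
#'
#' Returns the methods and results text (plus captions when requested),
#' the default surface for most study-characteristic extractors.
#' Introductions, discussions and the reference list are deliberately
#' excluded because they describe other work and would inflate false
#' positives. When both the methods and the results bucket are empty (as
#' happens for PDF-converted files that lost their section titles), the
#' unclassified body text is used instead so degraded files are still
#' processed.
#'
#' @param st A `sectioned_text` from [classify_sections()].
#' @param include_captions Append figure/table captions to the surface.
#' @param include_tables Append table cell content (off by default; table
#'   content is parsed but not processed unless requested).
#' @return A single text string.
#' @export
extraction_surface <- function(st, include_captions = TRUE,
                               include_tables = FALSE) {
  stopifnot(inherits(st, "sectioned_text"))
  core <- c(st$methods, st$results)
  if (!has_text(core)) core <- st$unclassified
  out <- core
  if (include_captions) out <- c(out, st$captions)
  if (include_tables) out <- c(out, st$tables)
  trimws(collapse_text(out))
}

#' Serialize a parsed article to JSON
#'
#' @param article A `jats_article`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string (UTF-8, stable key order).
#' @export
article_json <- function(article, pretty = FALSE) {
  stopifnot(inherits(article, "jats_article"))
  jsonlite::toJSON(unclass(article), auto_unbox = TRUE, pretty = pretty)
}
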