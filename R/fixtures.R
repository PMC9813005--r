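# Synthetic JATS article generator: declaratively planted study
# characteristics rendered through templated sentences, with optional
# PDF-conversion-style corruption, plus the matching gold-standard rows so
# the extraction-evaluation loop can be closed without any external data.

fixture_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- jsonlite::fromJSON(
        system.file("extdata", "templates.json", package = "studychar",
                    mustWork = TRUE),
        simplifyVector = TRUE
      )
    }
    cache
  }
})

# Software names the generator can plant, with their empirical in-text
# representation.
fixture_software_mentions <- c(
  "SPSS" = "SPSS (version 25)", "Mplus" = "Mplus 8.4",
  "MATLAB" = "MATLAB R2019b", "Stata" = "Stata 16", "SAS" = "SAS 9.4",
  "R" = "R version 4.0.2", "JASP" = "JASP", "Excel" = "Microsoft Excel",
  "LISREL" = "LISREL 8.8", "Python" = "Python 3.8", "Praat" = "Praat",
  "G*Power" = "G*Power 3.1", "Minitab" = "Minitab 19", "jamovi" = "jamovi",
  "Mathematica" = "Mathematica 12"
)

# Method phrases the generator can plant (already in the canonical
# lower-case, hyphen-free form the extractor returns).
fixture_method_phrases <- c(
  "repeated measures anova", "logistic regression", "multilevel regression",
  "confirmatory factor analysis", "independent t test",
  "mann whitney u test", "cluster analysis", "growth curve model",
  "structural equation model", "spearman rank correlation"
)

# Misspelling variants used when a correction author is planted misspelled.
fixture_misspellings <- c(
  "Bonferroni" = "Bonfferoni", "Tukey" = "Tuckey", "Scheffé" = "Scheffe",
  "Sidak" = "Sidack", "Dunnett" = "Dunnet"
)

fixture_corruption_classes <- c(
  "drop_section_titles", "strip_operators", "break_greek",
  "insert_invisible_spaces"
)

#' Declare a synthetic article's planted features
#'
#' A `fixture_spec` describes exactly which study characteristics a
#' generated article reports and in which reporting style; the same spec
#' also determines the article's gold-standard rows, so generation and
#' evaluation always agree. Planted values must respect each extractor's
#' valid range. With a fixed `seed`, [generate_article()] is
#' byte-for-byte deterministic.
#'
#' @param id Article identifier.
#' @param n_studies Number of enumerated studies (section structure).
#' @param alpha Optional alpha-level in (0, 1).
#' @param alpha_style One of `"explicit"`, `"p_threshold"`, `"ci"`,
#'   `"fraction"`.
#' @param alpha_divisor Divisor for the `"fraction"` style (the corrected
#'   level is `alpha / alpha_divisor`).
#' @param power Optional power value(s) in \[0, 1\] (two values for the
#'   `"interval"` style).
#' @param power_style One of `"direct"`, `"beta"`, `"interval"`.
#' @param correction Optional correction author (canonical name from
#'   [correction_terms()]).
#' @param misspell_correction Plant the author under a common misspelling
#'   (extraction must still return the canonical name).
#' @param interaction Character subset of
#'   `c("interaction", "mediator", "moderator")`.
#' @param direction `"none"`, `"one_sided"`, `"two_sided"` or `"both"`.
#' @param outlier_sd Optional SD threshold(s) in \[1, 10\].
#' @param assumptions Labels from [assumption_dictionary()].
#' @param software Names from `names(studychar:::fixture_software_mentions)`.
#' @param methods Phrases from the plantable method pool.
#' @param corruption Subset of `r paste(fixture_corruption_classes, collapse = ", ")`.
#' @param seed Integer seed fixing the generated bytes.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(id = "art-001", n_studies = 1L,
                         alpha = NULL, alpha_style = "explicit",
                         alpha_divisor = 4,
                         power = NULL, power_style = "direct",
                         correction = NULL, misspell_correction = FALSE,
                         interaction = character(),
                         direction = "none",
                         outlier_sd = NULL,
                         assumptions = character(),
                         software = character(),
                         methods = character(),
                         corruption = character(),
                         seed = 1L) {
  stopifnot(n_studies >= 1)
  alpha_style <- match.arg(alpha_style,
                           c("explicit", "p_threshold", "ci", "fraction"))
  power_style <- match.arg(power_style, c("direct", "beta", "interval"))
  direction <- match.arg(direction,
                         c("none", "one_sided", "two_sided", "both"))
  if (!is.null(alpha) && any(alpha <= 0 | alpha >= 1)) {
    stop("planted alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(power)) {
    if (any(power < 0 | power > 1)) {
      stop("planted power must lie in [0, 1]", call. = FALSE)
    }
    if (power_style == "interval" && length(power) != 2) {
      stop("interval power style needs exactly two values", call. = FALSE)
    }
  }
  if (!is.null(outlier_sd) && any(outlier_sd < 1 | outlier_sd > 10)) {
    stop("planted outlier SD must lie in [1, 10]", call. = FALSE)
  }
  if (!all(interaction %in% c("interaction", "mediator", "moderator"))) {
    stop("unknown interaction flag", call. = FALSE)
  }
  if (!all(corruption %in% fixture_corruption_classes)) {
    stop("unknown corruption class: ",
         paste(setdiff(corruption, fixture_corruption_classes), collapse = ", "),
         call. = FALSE)
  }
  if (!all(software %in% names(fixture_software_mentions))) {
    stop("software not in the plantable pool: ",
         paste(setdiff(software, names(fixture_software_mentions)), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      id = id, n_studies = as.integer(n_studies),
      alpha = alpha, alpha_style = alpha_style,
      alpha_divisor = alpha_divisor,
      power = power, power_style = power_style,
      correction = correction, misspell_correction = isTRUE(misspell_correction),
      interaction = interaction, direction = direction,
      outlier_sd = outlier_sd, assumptions = assumptions,
      software = software, methods = methods,
      corruption = corruption, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

fill_template <- function(tpl, ...) {
  subs <- list(...)
  for (nm in names(subs)) {
    tpl <- gsub(paste0("{", nm, "}"), subs[[nm]], tpl, fixed = TRUE)
  }
  tpl
}

indef_article <- function(phrase) {
  if (grepl("^[aeiou]", phrase)) "an" else "a"
}

# Sentences realizing the planted features, split into the methods-type
# and results-type pools.
fixture_sentences <- function(spec) {
  tpl <- fixture_templates()
  pick <- function(x) x[[sample.int(length(x), 1)]]
  methods_s <- character()
  results_s <- character()

  if (!is.null(spec$alpha)) {
    if (spec$alpha_style == "ci") {
      pct <- fmt_num(100 * (1 - spec$alpha))
      results_s <- c(results_s, fill_template(pick(tpl$alpha$ci), pct = pct))
    } else if (spec$alpha_style == "fraction") {
      methods_s <- c(methods_s, fill_template(
        pick(tpl$alpha$fraction),
        v = fmt_num(spec$alpha), k = fmt_num(spec$alpha_divisor)
      ))
    } else {
      methods_s <- c(methods_s, fill_template(
        pick(tpl$alpha[[spec$alpha_style]]), v = fmt_num(spec$alpha)
      ))
    }
  }
  if (!is.null(spec$power)) {
    if (spec$power_style == "beta") {
      methods_s <- c(methods_s, fill_template(
        pick(tpl$power$beta), b = fmt_num(round(1 - spec$power[1], 6))
      ))
    } else if (spec$power_style == "interval") {
      methods_s <- c(methods_s, fill_template(
        pick(tpl$power$interval),
        v = fmt_num(spec$power[1]), v2 = fmt_num(spec$power[2])
      ))
    } else {
      methods_s <- c(methods_s, fill_template(
        pick(tpl$power$direct), v = fmt_num(spec$power[1])
      ))
    }
  }
  if (!is.null(spec$correction)) {
    name <- spec$correction
    if (spec$misspell_correction && name %in% names(fixture_misspellings)) {
      name <- fixture_misspellings[[name]]
    }
    methods_s <- c(methods_s, fill_template(pick(tpl$correction), author = name))
  }
  for (flag in spec$interaction) {
    results_s <- c(results_s, pick(tpl$interaction[[flag]]))
  }
  dirs <- switch(spec$direction,
                 none = character(), both = c("one_sided", "two_sided"),
                 spec$direction)
  for (d in dirs) {
    methods_s <- c(methods_s, pick(tpl$direction[[d]]))
  }
  for (v in spec$outlier_sd %||% numeric()) {
    methods_s <- c(methods_s, fill_template(pick(tpl$outlier), v = fmt_num(v)))
  }
  for (lab in spec$assumptions) {
    methods_s <- c(methods_s, fill_template(pick(tpl$assumption), label = lab))
  }
  for (sw in spec$software) {
    methods_s <- c(methods_s, fill_template(
      pick(tpl$software), mention = fixture_software_mentions[[sw]]
    ))
  }
  for (ph in spec$methods) {
    rendered <- gsub("t test", "t-test", ph, fixed = TRUE)
    art <- indef_article(rendered)
    methods_s <- c(methods_s, fill_template(
      pick(tpl$method), phrase = rendered, art = art,
      Art = paste0(toupper(substr(art, 1, 1)), substr(art, 2, nchar(art)))
    ))
  }
  list(methods = methods_s, results = results_s)
}

add_filler <- function(sentences, n_filler) {
  tpl <- fixture_templates()
  filler <- sample(tpl$filler, n_filler)
  out <- c(sentences, filler)
  sample(out, length(out))
}

#' Generate a synthetic NISO-JATS article
#'
#' Renders the planted features of a [fixture_spec()] into templated
#' sentences inside a well-formed JATS article (title, abstract, sectioned
#' body, one figure caption, a reference list), then applies the requested
#' corruption classes: `drop_section_titles` removes every body section
#' title (emulating PDF conversion that loses sectioning),
#' `strip_operators` deletes comparison operators between statistic
#' symbols and numbers, `break_greek` degrades Greek letters
#' (alpha to "a", beta to "b", chi-square to "v2"), and
#' `insert_invisible_spaces` seeds zero-width spaces into body text. The
#' same spec and seed always produce identical bytes.
#'
#' @param spec A [fixture_spec()].
#' @return A single string of JATS XML.
#' @export
generate_article <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    tpl <- fixture_templates()
    feats <- fixture_sentences(spec)
    methods_s <- add_filler(feats$methods, sample(2:3, 1))
    results_s <- add_filler(feats$results, sample(1:2, 1))
    abstract <- sample(tpl$abstract, 1)
    intro_s <- add_filler(character(), 2)
    disc_s <- add_filler(character(), 2)

    doc <- xml2::xml_new_root("article", "dtd-version" = "1.1")
    front <- xml2::xml_add_child(doc, "front")
    meta <- xml2::xml_add_child(front, "article-meta")
    aid <- xml2::xml_add_child(meta, "article-id")
    xml2::xml_text(aid) <- spec$id
    tg <- xml2::xml_add_child(meta, "title-group")
    at <- xml2::xml_add_child(tg, "article-title")
    xml2::xml_text(at) <- "Attention and evaluative judgment under varying context"
    ab <- xml2::xml_add_child(meta, "abstract")
    abp <- xml2::xml_add_child(ab, "p")
    xml2::xml_text(abp) <- abstract

    body <- xml2::xml_add_child(doc, "body")
    add_sec <- function(parent, title, paragraphs) {
      sec <- xml2::xml_add_child(parent, "sec")
      tt <- xml2::xml_add_child(sec, "title")
      xml2::xml_text(tt) <- title
      for (p in paragraphs) {
        pn <- xml2::xml_add_child(sec, "p")
        xml2::xml_text(pn) <- p
      }
      sec
    }
    add_sec(body, "Introduction", paste(intro_s, collapse = " "))
    if (spec$n_studies == 1L) {
      add_sec(body, "Methods", paste(methods_s, collapse = " "))
      add_sec(body, "Results",
              paste(c(results_s, "Group differences are summarized below."),
                    collapse = " "))
    } else {
      for (i in seq_len(spec$n_studies)) {
        study <- add_sec(body, paste("Study", i), character())
        if (i == 1L) {
          add_sec(study, "Methods", paste(methods_s, collapse = " "))
          add_sec(study, "Results",
                  paste(c(results_s, "Group differences are summarized below."),
                        collapse = " "))
        } else {
          add_sec(study, "Methods", paste(add_filler(character(), 2), collapse = " "))
          add_sec(study, "Results", "The earlier pattern was replicated.")
        }
      }
    }
    add_sec(body, if (spec$n_studies > 1) "General Discussion" else "Discussion",
            paste(disc_s, collapse = " "))
    fig <- xml2::xml_add_child(body, "fig")
    cap <- xml2::xml_add_child(fig, "caption")
    capp <- xml2::xml_add_child(cap, "p")
    xml2::xml_text(capp) <- "Figure 1. Average responses by condition and group."

    back <- xml2::xml_add_child(doc, "back")
    rl <- xml2::xml_add_child(back, "ref-list")
    for (ref in c(
      "Author, A. (2017). A treatise on measurement. Journal of Things, 1, 1-10.",
      "Writer, B. (2016). Judgments in context. Annual Review of Matters, 2, 11-20."
    )) {
      rn <- xml2::xml_add_child(rl, "ref")
      xml2::xml_text(rn) <- ref
    }

    apply_corruption(doc, spec$corruption)
    as.character(doc)
  })
}

apply_corruption <- function(doc, classes) {
  body_texts <- function() xml2::xml_find_all(doc, ".//body//text()")
  if ("drop_section_titles" %in% classes) {
    xml2::xml_remove(xml2::xml_find_all(doc, ".//body//sec/title"))
  }
  if ("strip_operators" %in% classes) {
    for (nd in body_texts()) {
      t <- xml2::xml_text(nd)
      t <- gsub("(p-?values?|[αβ]|\\bp)\\s*[=<>]+\\s*(?=[0-9.])", "\\1 ",
                t, perl = TRUE)
      xml2::xml_text(nd) <- t
    }
  }
  if ("break_greek" %in% classes) {
    for (nd in body_texts()) {
      t <- xml2::xml_text(nd)
      t <- gsub("α", "a", t, fixed = TRUE)
      t <- gsub("β", "b", t, fixed = TRUE)
      t <- gsub("χ2", "v2", t, fixed = TRUE)
      xml2::xml_text(nd) <- t
    }
  }
  if ("insert_invisible_spaces" %in% classes) {
    for (nd in body_texts()) {
      t <- xml2::xml_text(nd)
      words <- strsplit(t, " ", fixed = TRUE)[[1]]
      hit <- seq_along(words) %% 5 == 0
      words[hit] <- vapply(words[hit], function(w) {
        if (nchar(w) < 4) return(w)
        paste0(substr(w, 1, 2), "\u200b", substr(w, 3, nchar(w)))
      }, character(1), USE.NAMES = FALSE)
      xml2::xml_text(nd) <- paste(words, collapse = " ")
    }
  }
  invisible(doc)
}

#' Gold-standard rows implied by a fixture spec
#'
#' @param spec A [fixture_spec()].
#' @return A tibble with columns `article_id`, `feature`, `value` listing
#'   every value a perfect extraction of the uncorrupted article returns
#'   (template-induced mentions such as "confidence intervals" for the CI
#'   alpha style included).
#' @export
fixture_gold <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rows <- list()
  add <- function(feature, values) {
    if (length(values) == 0) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      article_id = spec$id, feature = feature, value = as.character(values)
    )
  }
  if (!is.null(spec$alpha)) {
    if (spec$alpha_style == "fraction") {
      add("alpha", fmt_num(c(spec$alpha, round(spec$alpha / spec$alpha_divisor, 6))))
    } else {
      add("alpha", fmt_num(spec$alpha))
    }
  }
  if (!is.null(spec$power)) add("power", fmt_num(spec$power))
  if (!is.null(spec$correction)) add("correction", spec$correction)
  add("interaction", spec$interaction)
  add("direction", switch(spec$direction,
                          none = character(),
                          both = c("one_sided", "two_sided"),
                          spec$direction))
  add("outlier_sd", fmt_num(spec$outlier_sd %||% numeric()))
  add("assumptions", spec$assumptions)
  add("software", spec$software)
  induced <- if (!is.null(spec$alpha) && spec$alpha_style == "ci") {
    "confidence intervals"
  } else {
    character()
  }
  add("methods", sort(unique(c(spec$methods, induced))))
  add("n_studies", as.character(spec$n_studies))
  dplyr::bind_rows(rows)
}

# Presence probabilities and value pools mirroring the empirical frequency
# profile of psychology articles (most articles mention at least one
# method and a software package; explicit alpha, power, outlier rules and
# test direction are comparatively rare; single-study articles dominate).
random_fixture_spec <- function(id, seed, corruption_pool = character()) {
  withr::with_seed(seed, {
    has <- function(p) stats::runif(1) < p
    alpha <- NULL
    alpha_style <- "explicit"
    if (has(0.5)) {
      alpha_style <- sample(c("explicit", "p_threshold", "ci", "fraction"),
                            1, prob = c(0.25, 0.20, 0.40, 0.15))
      alpha <- if (alpha_style == "ci") {
        sample(c(0.1, 0.05, 0.01), 1, prob = c(0.15, 0.75, 0.10))
      } else {
        sample(c(0.05, 0.01, 0.1), 1, prob = c(0.8, 0.1, 0.1))
      }
    }
    power <- NULL
    power_style <- "direct"
    if (has(0.16)) {
      power_style <- sample(c("direct", "beta", "interval"), 1,
                            prob = c(0.7, 0.2, 0.1))
      power <- if (power_style == "interval") {
        c(0.8, 0.9)
      } else {
        sample(c(0.8, 0.85, 0.9, 0.95), 1)
      }
    }
    correction <- NULL
    misspell <- FALSE
    if (has(0.22)) {
      correction <- sample(correction_terms()$canonical[
        correction_terms()$type == "author"
      ], 1)
      misspell <- has(0.1) && correction %in% names(fixture_misspellings)
    }
    interaction <- character()
    if (has(0.69)) {
      flags <- c("interaction", "mediator", "moderator")
      interaction <- flags[stats::runif(3) < c(0.76, 0.35, 0.17)]
      if (length(interaction) == 0) interaction <- "interaction"
    }
    direction <- "none"
    if (has(0.12)) {
      direction <- sample(c("two_sided", "one_sided", "both"), 1,
                          prob = c(0.76, 0.18, 0.06))
    }
    outlier_sd <- if (has(0.09)) {
      sample(c(2, 2.5, 3), 1, prob = c(5, 8, 12))
    }
    assumptions <- if (has(0.22)) {
      sample(assumption_dictionary()$label, sample(1:2, 1))
    } else {
      character()
    }
    software <- if (has(0.63)) {
      sample(names(fixture_software_mentions), sample(1:2, 1))
    } else {
      character()
    }
    methods <- sample(fixture_method_phrases, sample(1:3, 1))
    n_studies <- sample(1:6, 1, prob = c(202, 37, 26, 15, 6, 1))
    corruption <- if (length(corruption_pool) > 0) {
      sample(corruption_pool,
             min(length(corruption_pool), sample(1:2, 1)))
    } else {
      character()
    }
    fixture_spec(
      id = id, n_studies = n_studies, alpha = alpha,
      alpha_style = alpha_style, alpha_divisor = sample(c(2, 4, 5), 1),
      power = power, power_style = power_style,
      correction = correction, misspell_correction = misspell,
      interaction = interaction, direction = direction,
      outlier_sd = outlier_sd, assumptions = assumptions,
      software = software, methods = methods,
      corruption = unique(corruption), seed = seed + 1L
    )
  })
}

#' Generate a synthetic corpus with its gold standard
#'
#' @param n Number of articles (ignored when `specs` is given).
#' @param seed Master seed; article-level seeds are derived from it.
#' @param specs Optional list of [fixture_spec()]s to realize instead of
#'   random ones.
#' @param corruption_pool Corruption classes to sample from (1-2 classes
#'   per article); empty for a clean corpus.
#' @return A list with `articles` (named character vector of XML
#'   strings), `gold` (tibble of gold rows for all articles) and `specs`.
#' @export
generate_corpus <- function(n = 10, seed = 1L, specs = NULL,
                            corruption_pool = character()) {
  if (is.null(specs)) {
    if (n == 0) {
      return(list(articles = stats::setNames(character(), character()),
                  gold = tibble::tibble(article_id = character(),
                                        feature = character(),
                                        value = character()),
                  specs = list()))
    }
    seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 10L, n))
    specs <- lapply(seq_len(n), function(i) {
      random_fixture_spec(sprintf("art-%04d", i), seeds[i], corruption_pool)
    })
  }
  articles <- vapply(specs, generate_article, character(1))
  names(articles) <- vapply(specs, function(s) s$id, character(1))
  gold <- dplyr::bind_rows(lapply(specs, fixture_gold))
  list(articles = articles, gold = gold, specs = specs)
}

#' Write a generated corpus to disk
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the XML files written; the gold rows go
#'   to `gold.csv` in the same directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (id in names(corpus$articles)) {
    p <- file.path(dir, paste0(id, ".xml"))
    writeLines(corpus$articles[[id]], p, useBytes = TRUE)
    paths <- c(paths, p)
  }
  utils::write.csv(corpus$gold, file.path(dir, "gold.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(paths)
}
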