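#' Unify character encodings and repair PDF-conversion artefacts
#'
#' Decodes HTML and hexadecimal character entities to Unicode, maps every
#' space-like code point (the Unicode `Zs` category) to a plain space,
#' removes invisible characters such as zero-width spaces (U+200B), repairs
#' characteristic PDF-conversion damage to Greek letters in statistical
#' contexts (e.g. a chi-square statistic compiled as `v2`), and inserts a
#' `<=>` placeholder operator between a statistic symbol and an adjacent
#' bare number where the comparison operator was lost in conversion
#' (`"t 1.2"` becomes `"t <=> 1.2"`). The function is idempotent: applying
#' it to already-clean text changes nothing.
#'
#' @param x Character vector.
#' @param greek Repair mis-compiled Greek letters in statistical contexts.
#' @param fix_operators Insert the `<=>` placeholder for missing operators.
#' @return Character vector of the same length.
#' @examples
#' letter_convert("t 1.2, p 0.05")
#' letter_convert("a\u200bb")
#' @export
letter_convert <- function(x, greek = TRUE, fix_operators = TRUE) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- decode_entities(s)
    # all space-like code points to a plain space; invisible characters out
    s <- gsub("\\p{Zs}", " ", s, perl = TRUE)
    s <- gsub("[\u200b\u200c\u200d\u2060\ufeff\u00ad]", "", s)
    # unify operator glyphs
    s <- gsub("≤", "<=", s, fixed = TRUE)
    s <- gsub("≥", ">=", s, fixed = TRUE)
    s <- gsub("[−–]", "-", s)
    if (greek) {
      # chi-square statistics compiled as 'v2' by PDF extraction
      s <- gsub("\\bv2(?=\\s*[(=<>]|\\s*test)", "χ2", s, perl = TRUE)
    }
    if (fix_operators) {
      s <- gsub(
        "(?<![[:alnum:]<>=])((?:χ2|β|OR|HR|[tFrzpdb]))[ ]+((?:\\d+\\.?\\d*|\\.\\d+))",
        "\\1 <=> \\2", s, perl = TRUE
      )
    }
    s <- gsub(" {2,}", " ", s)
    s
  }, character(1), USE.NAMES = FALSE)
  out
}

# Named + numeric HTML entity decoding. Covers the entities that occur in
# JATS article text; numeric forms (&#x3b1; / &#945;) are decoded generally.
decode_entities <- function(s) {
  if (!grepl("&", s, fixed = TRUE)) return(s)
  # numeric entities, hex then decimal
  s <- gsub_fn(s, "&#x([0-9a-fA-F]{1,6});", function(m) {
    intToUtf8(strtoi(sub("&#x([0-9a-fA-F]+);", "\\1", m), 16L))
  })
  s <- gsub_fn(s, "&#([0-9]{1,7});", function(m) {
    intToUtf8(strtoi(sub("&#([0-9]+);", "\\1", m), 10L))
  })
  named <- c(
    lt = "<", gt = ">", quot = "\"", apos = "'", nbsp = " ",
    ndash = "-", mdash = "—", hellip = "…", times = "×",
    plusmn = "±", le = "<=", ge = ">=", minus = "-", middot = "·",
    deg = "°", micro = "µ", sect = "§",
    alpha = "α", beta = "β", gamma = "γ", delta = "δ",
    epsilon = "ε", eta = "η", theta = "θ", kappa = "κ",
    lambda = "λ", mu = "μ", nu = "ν", xi = "ξ",
    pi = "π", rho = "ρ", sigma = "σ", tau = "τ",
    phi = "φ", chi = "χ", psi = "ψ", omega = "ω",
    lsquo = "‘", rsquo = "’", ldquo = "“", rdquo = "”"
  )
  for (nm in names(named)) {
    s <- gsub(paste0("&", nm, ";"), named[[nm]], s, fixed = TRUE)
  }
  # ampersand last so double-encoded text decodes one level per call
  s <- gsub("&amp;", "&", s, fixed = TRUE)
  s
}

# Abbreviations after which a period never ends a sentence.
sentence_abbrev <- c(
  "et al", "e\\.g", "i\\.e", "vs", "cf", "ca", "approx", "resp",
  "Fig", "Figs", "Eq", "Eqs", "Ref", "Refs", "Tab", "No", "no",
  "Dr", "Prof", "Mr", "Mrs", "Ms", "St"
)

#' Split text into sentences
#'
#' Splits on sentence-final punctuation followed by whitespace and an
#' upper-case letter, digit or opening quote/bracket. Periods inside
#' decimals (`p = .05`), after common abbreviations (`et al.`, `e.g.`,
#' `Fig.`) and after single-letter initials do not split. Concatenating the
#' returned sentences reproduces the non-whitespace character sequence of
#' the input.
#'
#' @param x A character string (or vector, processed element-wise and
#'   flattened).
#' @param abbreviations Additional abbreviations (without the period) to
#'   protect from splitting.
#' @return Character vector of sentences, trimmed and non-empty.
#' @examples
#' text2sentences("A was done. B was found.")
#' text2sentences("p = .05 was used. Next step.")
#' @export
text2sentences <- function(x, abbreviations = character()) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(character())
  abbr <- c(sentence_abbrev, gsub("\\.", "\\\\.", abbreviations))
  out <- lapply(x, function(s) {
    if (!nzchar(trimws(s))) return(character())
    ph <- "\u0001"
    # protect abbreviation periods and single-initial periods
    for (a in abbr) {
      s <- gsub(paste0("\\b(", a, ")\\."), paste0("\\1", ph), s, perl = TRUE)
    }
    s <- gsub("\\b([A-Z])\\.(?=\\s+[A-Z])", paste0("\\1", ph), s, perl = TRUE)
    parts <- strsplit(s, "(?<=[.!?])\\s+(?=[\"'(\\[]?[A-Z0-9])", perl = TRUE)[[1]]
    parts <- gsub(ph, ".", parts, fixed = TRUE)
    parts <- trimws(parts)
    parts[nzchar(parts)]
  })
  unlist(out, use.names = FALSE)
}

word_number_map <- local({
  units <- c(
    one = 1, two = 2, three = 3, four = 4, five = 5, six = 6, seven = 7,
    eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12, thirteen = 13,
    fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17, eighteen = 18,
    nineteen = 19, twenty = 20
  )
  tens <- c(
    thirty = 30, forty = 40, fifty = 50, sixty = 60, seventy = 70,
    eighty = 80, ninety = 90
  )
  c(units, tens)
})

#' Rewrite textual number representations as decimals
#'
#' Number words (`"five"`), percentages (`"5%"`, `"five percent"`), simple
#' fractions (`"0.05/5"`), powers of ten (`"3 x 10^-2"`) and e-notation
#' (`"3e-2"`) are replaced by plain decimal digit strings; all other text
#' is preserved verbatim. Hyphenated composites (`"twenty-nine"`) are
#' resolved; number words fused to a following word by a hyphen
#' (`"one-sided"`) are left alone. A fraction with denominator zero is left
#' unchanged.
#'
#' @param x Character vector.
#' @param words,percentages,fractions,exponents Toggle the individual
#'   rewriting steps.
#' @return Character vector with numbers rewritten.
#' @examples
#' text2num("five percent")  # "0.05"
#' text2num("0.05/5")        # "0.01"
#' @export
text2num <- function(x, words = TRUE, percentages = TRUE, fractions = TRUE,
                     exponents = TRUE) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (words) {
      wm <- word_number_map
      # tens-units composites first ("twenty-nine", "twenty nine")
      tens_alt <- "twenty|thirty|forty|fifty|sixty|seventy|eighty|ninety"
      unit_alt <- "one|two|three|four|five|six|seven|eight|nine"
      s <- gsub_fn(
        s,
        paste0("(?i)\\b(", tens_alt, ")[- ](", unit_alt, ")\\b(?!-[A-Za-z])"),
        function(m) {
          parts <- strsplit(tolower(m), "[- ]")[[1]]
          fmt_num(wm[[parts[1]]] + wm[[parts[2]]])
        }
      )
      for (w in names(wm)) {
        s <- gsub(
          paste0("(?i)(?<![-[:alpha:]])", w, "(?![-[:alpha:]])"),
          fmt_num(wm[[w]]), s, perl = TRUE
        )
      }
    }
    if (exponents) {
      s <- gsub_fn(
        s, "(\\d+(?:\\.\\d+)?)\\s*[x×*]\\s*10\\s*\\^?\\s*\\(?([+-]?\\d+)\\)?",
        function(m) {
          g <- regmatches(m, regexec(
            "(\\d+(?:\\.\\d+)?)\\s*[x×*]\\s*10\\s*\\^?\\s*\\(?([+-]?\\d+)\\)?", m
          ))[[1]]
          fmt_num(as.numeric(g[2]) * 10^as.numeric(g[3]))
        }
      )
      s <- gsub_fn(s, "(?<![.\\d])10\\^\\(?([+-]?\\d+)\\)?", function(m) {
        g <- regmatches(m, regexec("10\\^\\(?([+-]?\\d+)\\)?", m))[[1]]
        fmt_num(10^as.numeric(g[2]))
      })
      s <- gsub_fn(s, "\\b(\\d+(?:\\.\\d+)?)[eE]([+-]\\d+)\\b", function(m) {
        g <- regmatches(m, regexec("(\\d+(?:\\.\\d+)?)[eE]([+-]\\d+)", m))[[1]]
        fmt_num(as.numeric(g[2]) * 10^as.numeric(g[3]))
      })
    }
    if (percentages) {
      s <- gsub_fn(s, "(\\d+(?:\\.\\d+)?)\\s*(?:%|(?i:percent)\\b)", function(m) {
        v <- as.numeric(sub("^(\\d+(?:\\.\\d+)?).*$", "\\1", m))
        fmt_num(v / 100)
      })
    }
    if (fractions) {
      s <- gsub_fn(s, "(\\d+(?:\\.\\d+)?)\\s*/\\s*(\\d+(?:\\.\\d+)?)", function(m) {
        g <- regmatches(m, regexec(
          "(\\d+(?:\\.\\d+)?)\\s*/\\s*(\\d+(?:\\.\\d+)?)", m
        ))[[1]]
        den <- as.numeric(g[3])
        if (den == 0) return(m)
        fmt_num(as.numeric(g[2]) / den)
      })
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Extract word windows around pattern matches
#'
#' For every whitespace-delimited token matching `pattern`, returns the
#' token together with up to `n_before` preceding and `n_after` following
#' tokens of the same sentence (fewer at sentence boundaries).
#'
#' @param sentences Character vector of sentences.
#' @param pattern Regular expression matched against individual tokens.
#' @param n_before,n_after Number of tokens to include on each side.
#' @return Character vector of windows; empty when nothing matches.
#' @examples
#' ngram("a b c d", "c", n_before = 2)
#' @export
ngram <- function(sentences, pattern, n_before = 0, n_after = 0) {
  stopifnot(n_before >= 0, n_after >= 0)
  out <- lapply(sentences, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    if (length(toks) == 0) return(character())
    idx <- which(grepl(pattern, toks, perl = TRUE))
    vapply(idx, function(i) {
      paste(toks[max(1, i - n_before):min(length(toks), i + n_after)],
            collapse = " ")
    }, character(1))
  })
  unlist(out, use.names = FALSE)
}

#' Check a text for multiple search patterns at once
#'
#' @param x Character vector of text to search.
#' @param patterns Non-empty character vector of regular expressions.
#' @param value If `TRUE`, return the patterns that were detected instead
#'   of the binary hit vector.
#' @return Named integer vector of 0/1 flags in pattern order, or the
#'   detected patterns when `value = TRUE`.
#' @examples
#' which_term("anova was run", c("anova", "manova"))
#' @export
which_term <- function(x, patterns, value = FALSE) {
  stopifnot(length(patterns) > 0)
  hits <- vapply(patterns, function(p) {
    as.integer(any(grepl(p, x, perl = TRUE)))
  }, integer(1))
  names(hits) <- patterns
  if (value) return(names(hits)[hits == 1L])
  hits
}

#' Filter texts matching all patterns (logical AND)
#'
#' @param x Character vector of texts.
#' @param patterns Character vector of regular expressions; an empty vector
#'   is the empty conjunction and returns `x` unchanged.
#' @param value Return matching texts (`TRUE`) or their indices.
#' @return The elements of `x` (or indices) matching every pattern.
#' @examples
#' grep_and(c("a b", "a", "b"), c("a", "b"))
#' @export
grep_and <- function(x, patterns, value = TRUE) {
  if (length(patterns) == 0) return(if (value) x else seq_along(x))
  keep <- Reduce(`&`, lapply(patterns, function(p) grepl(p, x, perl = TRUE)))
  if (value) x[keep] else which(keep)
}

#' Split a string while preserving the search pattern
#'
#' Unlike [strsplit()], the matched pattern is kept in the output: with
#' `side = "before"` each match starts a new piece, with `side = "after"`
#' each match ends one. Concatenating the pieces always reproduces the
#' input exactly.
#'
#' @param x A single character string.
#' @param pattern Regular expression.
#' @param side Split `"before"` or `"after"` the match.
#' @return Character vector of pieces (the input itself when the pattern
#'   does not occur).
#' @examples
#' strsplit_keep("xAyAz", "A", "before")  # "x"  "Ay" "Az"
#' strsplit_keep("xAyAz", "A", "after")   # "xA" "yA" "z"
#' @export
strsplit_keep <- function(x, pattern, side = c("before", "after")) {
  side <- match.arg(side)
  stopifnot(length(x) == 1)
  m <- gregexpr(pattern, x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(x)
  cuts <- if (side == "before") m else m + attr(m, "match.length")
  cuts <- cuts[cuts > 1 & cuts <= nchar(x)]
  starts <- c(1, cuts)
  ends <- c(cuts - 1, nchar(x))
  vapply(seq_along(starts), function(i) {
    substr(x, starts[i], ends[i])
  }, character(1))
}
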