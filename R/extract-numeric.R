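# Numeric study-characteristic extractors: alpha-level, test power and
# outlier definitions in standard deviations.

alpha_synonyms <- c(
  "significance (level|threshold|criterion)",
  "level of significance", "level of confidence", "level of probability",
  "type[- ](1|i|one)[- ]error( probability| rate)?",
  "alpha[- ]?(level|error|value|criterion)",
  "α[- ]?(level|error|value|criterion)",
  "\\balpha\\b", "α"
)

new_alpha_result <- function(nominal = numeric(), corrected = numeric(),
                             from_ci = numeric()) {
  all_vals <- c(nominal, corrected, from_ci)
  structure(
    list(
      nominal = sort(unique(nominal)),
      corrected = sort(unique(corrected)),
      from_ci = sort(unique(from_ci)),
      max_alpha = if (length(all_vals)) max(all_vals) else NA_real_,
      min_alpha = if (length(all_vals)) min(all_vals) else NA_real_
    ),
    class = "alpha_result"
  )
}

extract_num_groups <- function(s, pattern) {
  m <- regmatches(s, gregexpr(pattern, s, perl = TRUE))[[1]]
  m
}

#' Extract the reported alpha-level(s)
#'
#' Scans the methods/results/captions surface for explicitly reported
#' significance levels. Synonymous phrasings (alpha level, level of
#' significance, significance threshold/criterion, level of
#' confidence/probability, type-1 error) are unified before numeric
#' extraction. A corrected level reported as a fraction of the nominal one
#' (`"α = 0.05/4"`) yields both values. Asterisk-coded p-value legends
#' (`"* p < .05"`) are never treated as alpha-levels. With `p2alpha` on
#' (the default) statements that declare a p-value threshold for
#' significance contribute to the nominal levels, and `x%` confidence
#' intervals contribute `(100 - x)/100` to the CI-derived levels.
#'
#' @param text Character vector (collapsed internally).
#' @param p2alpha Convert significance-threshold p-value statements into
#'   alpha-levels.
#' @return An `alpha_result`: sets `nominal`, `corrected`, `from_ci`, all
#'   within (0, 1), plus `max_alpha`/`min_alpha` over their union.
#' @examples
#' extract_alpha("The α-error was set to 0.05.")
#' extract_alpha("α = 0.05/4 was applied.")
#' @export
extract_alpha <- function(text, p2alpha = TRUE) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  # drop asterisk-coded p-value legends
  sents <- sents[!grepl("\\*\\s*p\\b", sents)]
  nominal <- corrected <- from_ci <- numeric()
  for (s in sents) {
    for (syn in alpha_synonyms) s <- gsub(syn, "alpha", s, perl = TRUE)
    s <- text2num(s, fractions = FALSE)
    if (grepl("alpha", s, fixed = TRUE)) {
      pat <- "alpha[^0-9]{0,30}?(\\d*\\.?\\d+)(\\s*/\\s*(\\d*\\.?\\d+))?"
      for (m in extract_num_groups(s, pat)) {
        g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
        v <- as.numeric(g[2])
        den <- suppressWarnings(as.numeric(g[4]))
        if (!is.na(den) && den > 0) {
          nominal <- c(nominal, v)
          corrected <- c(corrected, v / den)
        } else if (grepl("correct|adjust", s)) {
          corrected <- c(corrected, v)
        } else {
          nominal <- c(nominal, v)
        }
      }
    }
    if (p2alpha && grepl("significan", s) &&
        grepl("consider|deem|regard|defin|set|threshold|criterion|level|interpret|accept|treat", s)) {
      pat <- "\\bp[- ]?(?:values?)?\\s*(?:of\\s*)?(?:[<≤=]|<=>?|below|less than)\\s*(\\d*\\.?\\d+)"
      for (m in extract_num_groups(s, pat)) {
        g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
        nominal <- c(nominal, as.numeric(g[2]))
      }
    }
    ci_pat <- "(\\d*\\.?\\d+)\\s*(?:%|percent)?[- ]?(?:confidence[- ](?:interval|limit|region|level)s?|\\bcis?\\b)"
    for (m in extract_num_groups(s, ci_pat)) {
      g <- regmatches(m, regexec(ci_pat, m, perl = TRUE))[[1]]
      v <- as.numeric(g[2])
      a <- if (v > 1 && v < 100) (100 - v) / 100 else if (v < 1) 1 - v else NA
      if (!is.na(a)) from_ci <- c(from_ci, a)
    }
  }
  in_range <- function(v) v[v > 0 & v < 1]
  vals <- lapply(list(nominal, corrected, from_ci), function(v) {
    round(in_range(v), 6)
  })
  new_alpha_result(vals[[1]], vals[[2]], vals[[3]])
}

#' @export
print.alpha_result <- function(x, ...) {
  cat("<alpha_result>\n")
  cat("  nominal:  ", paste(x$nominal, collapse = ", "), "\n")
  cat("  corrected:", paste(x$corrected, collapse = ", "), "\n")
  cat("  from CI:  ", paste(x$from_ci, collapse = ", "), "\n")
  if (!is.na(x$max_alpha)) {
    cat("  max/min:  ", x$max_alpha, "/", x$min_alpha, "\n")
  }
  invisible(x)
}

# Sentences where "power" refers to physical power, not test power.
power_exclusion <- "\\bvolts?\\b|\\bamps?\\b|\\bamperes?\\b|\\bhz\\b|hertz|\\bwatts?\\b|\\bkw\\b|electric|power supply|powered|horsepower"

#' Extract reported statistical test power
#'
#' Operates on the full document text (power is often reported in the
#' participants or design subsection). Sentences in which "power" has a
#' physical meaning (volts, amps, Hz, ...) are omitted. Values outside the
#' valid power range [0, 1] are dropped, so an erroneous report such as "a
#' power of 80" is never returned. Reported beta-errors are converted to
#' power via 1 - beta and flagged.
#'
#' @param text Character vector (the full article text).
#' @return A `power_result`: `values` (sorted, within [0, 1]) and
#'   `beta_converted` (the subset derived from beta-error reports).
#' @examples
#' extract_power("A power of 0.80 was targeted.")
#' extract_power("We fixed β = 0.20 for the planned test.")
#' @export
extract_power <- function(text) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  sents <- sents[!grepl(power_exclusion, sents, perl = TRUE)]
  values <- beta_vals <- numeric()
  for (s in sents) {
    has_power <- grepl("power", s, fixed = TRUE)
    has_beta <- grepl("β|\\bbeta\\b", s, perl = TRUE)
    if (!has_power && !has_beta) next
    s <- text2num(s, fractions = FALSE)
    if (has_power) {
      s2 <- gsub("1\\s*-\\s*(β|beta)", "power", s, perl = TRUE)
      pat <- "power[^0-9]{0,30}?(\\d*\\.?\\d+)(\\s*(?:and|to|-)\\s*(\\d*\\.?\\d+))?"
      for (m in extract_num_groups(s2, pat)) {
        g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
        values <- c(values, as.numeric(g[2]))
        v2 <- suppressWarnings(as.numeric(g[4]))
        if (!is.na(v2)) values <- c(values, v2)
      }
      # value reported just before the word power ("0.8 power")
      pat_rev <- "(\\d*\\.?\\d+)[^0-9a-z]{0,10}(?:statistical )?power"
      for (m in extract_num_groups(s2, pat_rev)) {
        g <- regmatches(m, regexec(pat_rev, m, perl = TRUE))[[1]]
        values <- c(values, as.numeric(g[2]))
      }
    }
    if (has_beta) {
      pat <- "(?:β|\\bbeta\\b)[- ]?(?:error|level)?\\s*(?:[=<≤]|<=>?|of|was set to|set at|was|at)\\s*(\\d*\\.?\\d+)"
      for (m in extract_num_groups(s, pat)) {
        g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
        b <- as.numeric(g[2])
        if (b >= 0 && b <= 1) beta_vals <- c(beta_vals, round(1 - b, 6))
      }
    }
  }
  values <- round(values, 6)
  keep <- function(v) sort(unique(v[v >= 0 & v <= 1]))
  structure(
    list(values = keep(c(values, beta_vals)), beta_converted = keep(beta_vals)),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result> values:", paste(x$values, collapse = ", "))
  if (length(x$beta_converted)) {
    cat("  (from beta:", paste(x$beta_converted, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Extract outlier definitions expressed in standard deviations
#'
#' Identifies sentences that mention a removal process or an outlier term
#' (outlier, extreme, remove, delete, exclude, ...) together with a number
#' -- numeric or written as a word -- followed by "standard deviation(s)"
#' or "SD". A tolerated plus/minus sign may precede the number. The result
#' space is limited to `[lo, hi]` (1 to 10 by default): very large
#' deviations indicate measurement error rather than an outlier rule, and
#' very small values are mostly erroneous captures.
#'
#' @param text Character vector.
#' @param lo,hi Bounds of the accepted result space.
#' @return An `outlier_defs` object with the sorted set `sd_values`.
#' @examples
#' extract_outlier_def("Extreme looking times (±2 SD) were excluded.")
#' @export
extract_outlier_def <- function(text, lo = 1, hi = 10) {
  sents <- tolower(text2sentences(letter_convert(collapse_text(text))))
  trigger <- "outlier|extreme|remove|delet|exclud|discard|trim|winsor"
  sents <- sents[grepl(trigger, sents, perl = TRUE)]
  vals <- numeric()
  pat <- "[±+-]?\\s*(\\d+(?:\\.\\d+)?)\\s*(?:±\\s*)?(?:standard deviations?|s\\.d\\.|sds?\\b)"
  for (s in sents) {
    s <- text2num(s, fractions = FALSE)
    for (m in extract_num_groups(s, pat)) {
      g <- regmatches(m, regexec(pat, m, perl = TRUE))[[1]]
      vals <- c(vals, as.numeric(g[2]))
    }
  }
  vals <- sort(unique(round(vals[vals >= lo & vals <= hi], 6)))
  structure(list(sd_values = vals, lo = lo, hi = hi), class = "outlier_defs")
}

#' @export
print.outlier_defs <- function(x, ...) {
  cat("<outlier_defs> SD thresholds:",
      if (length(x$sd_values)) paste(x$sd_values, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
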