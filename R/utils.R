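# Internal helpers shared across modules.

# Format a numeric value as a plain decimal string; used everywhere a
# detected number is rewritten into text or compared against a gold coding.
fmt_num <- function(x) {
  vapply(x, function(v) {
    format(round(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

# Canonical string form of an extracted/coded value: numeric-looking values
# are normalized through fmt_num so "0.050" and "0.05" compare equal.
canon_value <- function(v) {
  v <- trimws(as.character(v))
  num <- suppressWarnings(as.numeric(v))
  ifelse(!is.na(num), fmt_num(num), v)
}

# Round half away from zero (the convention used when metrics are printed
# at two decimals).
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Replace every match of `pattern` in `x` by `fn(match)`; regex engine is
# perl. Keeps non-matching text verbatim.
gsub_fn <- function(x, pattern, fn) {
  vapply(x, function(s) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(s)
    pieces <- regmatches(s, gregexpr(pattern, s, perl = TRUE))[[1]]
    repl <- vapply(pieces, fn, character(1), USE.NAMES = FALSE)
    regmatches(s, gregexpr(pattern, s, perl = TRUE)) <- list(repl)
    s
  }, character(1), USE.NAMES = FALSE)
}

# Collapse a character vector to one string; empty input becomes "".
collapse_text <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("")
  paste(x, collapse = " ")
}

has_text <- function(x) {
  length(x) > 0 && any(nzchar(trimws(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
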