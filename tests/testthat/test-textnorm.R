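# Character unification, sentence splitting, number normalization and the
# multi-pattern search helpers.

test_that("letter_convert decodes entities, cleans spaces and repairs operators", {
  expect_equal(letter_convert("t 1.2, p 0.05"), "t <=> 1.2, p <=> 0.05")
  expect_equal(letter_convert("&amp;"), "&")
  expect_equal(letter_convert("a\u200bb"), "ab")
  expect_equal(letter_convert("a\u00a0b"), "a b")          # NBSP
  expect_equal(letter_convert("a\u2009b\u2002c"), "a b c") # thin/en spaces
  expect_equal(letter_convert("&#x3b1; = .05"), "α = .05")
  expect_equal(letter_convert("&alpha; &lt; .05"), "α < .05")
  # chi-square statistics compiled as v2 are repaired in stat contexts only
  expect_equal(letter_convert("v2(3) = 12.4"), "χ2(3) = 12.4")
  expect_equal(letter_convert("a v2 test"), "a χ2 test")
  expect_equal(letter_convert("curriculum v2 rollout"), "curriculum v2 rollout")
  # no operator insertion when one is already present
  expect_equal(letter_convert("t = 1.2"), "t = 1.2")
  expect_equal(letter_convert("chapter 3"), "chapter 3")
})

test_that("letter_convert is idempotent", {
  fixtures <- c(
    "t 1.2, p 0.05", "&amp;", "a\u200bb", "v2(3) = 12.4",
    "plain prose with nothing to fix.", "β 0.20", "95% CI [0.1, 0.9]",
    "x y &lt;3 &#x3c7;2 = 4", ""
  )
  for (s in fixtures) {
    once <- letter_convert(s)
    expect_identical(letter_convert(once), once)
  }
})

test_that("text2sentences splits sentences but protects decimals and abbreviations", {
  expect_length(text2sentences("A was done. B was found."), 2)
  out <- text2sentences("p = .05 was used. Next step.")
  expect_length(out, 2)
  expect_equal(out[1], "p = .05 was used.")
  expect_equal(text2sentences(""), character())
  expect_length(text2sentences("As shown by Smith et al. (2020), effects vary."), 1)
  expect_length(text2sentences("See Fig. 3 for details. The rest follows."), 2)
  expect_length(text2sentences("Values, e.g. Mondays, differ."), 1)
})

test_that("text2sentences conserves the non-whitespace character sequence", {
  texts <- c(
    "A first thing happened. Then a second one! Was there a third? Yes.",
    "Mean age was 23.4 years (SD = 2.1). All p-values are exact.",
    "Dr. Smith met Prof. Jones. They agreed on e.g. the design."
  )
  for (tx in texts) {
    sents <- text2sentences(tx)
    expect_identical(
      gsub("\\s", "", paste(sents, collapse = " ")),
      gsub("\\s", "", tx)
    )
  }
})

test_that("text2num rewrites words, percentages, fractions and exponents", {
  expect_equal(text2num("five percent"), "0.05")
  expect_equal(text2num("0.05/5"), "0.01")
  expect_equal(text2num("3 × 10^-2"), "0.03")
  expect_equal(text2num("3 x 10^-2"), "0.03")
  expect_equal(text2num("two"), "2")
  expect_equal(text2num("twenty-nine infants"), "29 infants")
  expect_equal(text2num("3e-2"), "0.03")
  expect_equal(text2num("a 5% rate"), "a 0.05 rate")
  # denominators of zero leave the fraction untouched
  expect_equal(text2num("1/0 remains"), "1/0 remains")
  # number words fused into ordinary terms are not converted
  expect_equal(text2num("a one-sided test"), "a one-sided test")
})

test_that("text2num preserves non-numeric tokens verbatim", {
  s <- "the quick brown fox kept 0.05/5 of five percent"
  out <- text2num(s)
  expect_match(out, "^the quick brown fox kept ")
  expect_equal(out, "the quick brown fox kept 0.01 of 0.05")
})

test_that("ngram returns truncated token windows around matches", {
  expect_equal(ngram("a b c d", "c", 2, 0), "a b c")
  expect_equal(ngram("a b", "a", 3, 0), "a")
  expect_equal(ngram("a b c d", "b", 1, 2), "a b c d")
  expect_equal(ngram("a b c d", "zzz", 2, 2), character())
})

test_that("which_term flags patterns in input order", {
  expect_equal(unname(which_term("anova was run", c("anova", "manova"))),
               c(1L, 0L))
  expect_equal(unname(which_term("", c("a", "b"))), c(0L, 0L))
  expect_equal(unname(which_term("manova", c("anova", "manova"))), c(1L, 1L))
  expect_equal(which_term("anova", c("anova", "x"), value = TRUE), "anova")
})

test_that("grep_and keeps only texts matching every pattern", {
  expect_equal(grep_and(c("a b", "a", "b"), c("a", "b")), "a b")
  expect_equal(grep_and(c("a b", "a"), "a"), c("a b", "a"))
  expect_equal(grep_and(c("x", "y"), character()), c("x", "y"))
  expect_equal(grep_and(c("a b", "a"), c("a", "b"), value = FALSE), 1L)
})

test_that("strsplit_keep preserves the pattern and conserves the input", {
  expect_equal(strsplit_keep("xAyAz", "A", "before"), c("x", "Ay", "Az"))
  expect_equal(strsplit_keep("xAyAz", "A", "after"), c("xA", "yA", "z"))
  expect_equal(strsplit_keep("hello", "Z", "before"), "hello")
  cases <- list(
    c("xAyAz", "A"), c("AxA", "A"), c("aXbXc", "X"), c("no match here", "Q"),
    c("start 1 mid 2 end", "[0-9]")
  )
  for (side in c("before", "after")) {
    for (cs in cases) {
      expect_identical(
        paste(strsplit_keep(cs[1], cs[2], side), collapse = ""), cs[1]
      )
    }
  }
})
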