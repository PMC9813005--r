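# The ten study-characteristic extractors.

test_that("alpha extraction handles explicit, fraction, p-threshold and CI styles", {
  a <- extract_alpha("The α-error was set to 0.05.")
  expect_equal(a$nominal, 0.05)

  a <- extract_alpha("α = 0.05/4 was applied.")
  expect_equal(a$nominal, 0.05)
  expect_equal(a$corrected, 0.0125)
  expect_equal(a$max_alpha, 0.05)
  expect_equal(a$min_alpha, 0.0125)

  s <- "Results with p-values < 0.05 are considered significant."
  expect_equal(extract_alpha(s, p2alpha = TRUE)$nominal, 0.05)
  a_off <- extract_alpha(s, p2alpha = FALSE)
  expect_length(a_off$nominal, 0)
  expect_true(is.na(a_off$max_alpha))

  expect_equal(extract_alpha("95% confidence intervals were used")$from_ci, 0.05)
  expect_equal(extract_alpha("We report 90% confidence intervals.")$from_ci, 0.1)

  # asterisk-coded p-value legends are never alpha-levels
  legend <- extract_alpha("* p < .05, ** p < .01")
  expect_length(c(legend$nominal, legend$corrected, legend$from_ci), 0)

  # synonym phrasings funnel into the same extraction
  expect_equal(extract_alpha("The level of significance was 0.01.")$nominal, 0.01)
  expect_equal(extract_alpha("An alpha level of five percent was adopted.")$nominal, 0.05)
})

test_that("an ordinary significant test result is not converted to an alpha-level", {
  a <- extract_alpha("The difference was significant (p < .01).")
  expect_length(a$nominal, 0)
})

test_that("power extraction enforces the [0,1] result space and converts beta", {
  expect_equal(extract_power("A power of 0.80 was targeted.")$values, 0.8)
  expect_length(extract_power("achieved a power of 80")$values, 0)
  expect_length(extract_power("the stimulus used 50 hz power")$values, 0)
  p <- extract_power("β = 0.20 for the planned test")
  expect_equal(p$values, 0.8)
  expect_equal(p$beta_converted, 0.8)
  expect_equal(
    extract_power("a power ranging between 0.80 and 0.90 was achieved")$values,
    c(0.8, 0.9)
  )
  # repaired operator placeholder is understood
  expect_equal(extract_power(letter_convert("β 0.20 was fixed"))$values, 0.8)
})

test_that("correction extraction needs a trigger word and canonicalizes spellings", {
  expect_equal(
    extract_multiple_comparison("p-values were Bonfferoni corrected")$authors,
    "Bonferroni"
  )
  expect_length(
    extract_multiple_comparison("a Bonferroni Test was used")$authors, 0
  )
  expect_equal(
    extract_multiple_comparison("post-hoc Tukey comparisons")$authors, "Tukey"
  )
  expect_equal(
    extract_multiple_comparison(
      "we adjusted for the false discovery rate")$procedures,
    "false discovery rate"
  )
})

test_that("all misspelling variants map to the canonical author name", {
  variants <- c(
    Bonferroni = "Bonfferoni", Bonferroni = "Bonferoni",
    Bonferroni = "Bonferonni", Tukey = "Tuckey", "Scheffé" = "Scheffe",
    Sidak = "Sidack", Dunnett = "Dunnet", Keuls = "Keul"
  )
  for (i in seq_along(variants)) {
    got <- extract_multiple_comparison(
      paste("p-values were adjusted with the", variants[i], "procedure")
    )$authors
    expect_equal(got, names(variants)[i], label = variants[i])
  }
})

test_that("interaction detection distinguishes effect types and skips organisms", {
  expect_true(detect_interaction("the A × B interaction was significant")$interaction)
  x <- detect_interaction("mother-infant interaction was coded")
  expect_false(x$interaction)
  expect_false(x$any)
  expect_true(detect_interaction("a mediation analysis was conducted")$mediator)
  expect_true(detect_interaction("age moderated the association")$moderator)
  expect_false(detect_interaction("the treatment was applied immediately")$mediator)
  both <- detect_interaction(
    "The interaction was reliable. The link was mediated by control."
  )
  expect_true(both$interaction && both$mediator && both$any)
})

test_that("test direction maps synonym families with exclusions", {
  expect_equal(extract_test_direction("all tests were two-tailed"), "two_sided")
  expect_equal(extract_test_direction("see one-sided test on page 3"), "none")
  expect_equal(
    extract_test_direction("a one-tailed hypothesis test and a two-sided test"),
    "both"
  )
  expect_equal(extract_test_direction("directional hypotheses were evaluated"),
               "one_sided")
  expect_equal(extract_test_direction("non-directional tests were used"),
               "two_sided")
  expect_equal(extract_test_direction("one-sided aggression was studied"),
               "none")
  # "two tails" only counts with the extended pattern set
  s <- "d = 0.4; two tails, for the test"
  expect_equal(extract_test_direction(s), "none")
  expect_equal(extract_test_direction(s, extended_patterns = TRUE), "two_sided")
})

test_that("outlier definitions respect the configured SD range", {
  expect_equal(
    extract_outlier_def(paste(
      "Twenty-nine additional infants were excluded for following reasons:",
      "..., extreme looking times (±2 SD) ..."
    ))$sd_values, 2
  )
  expect_equal(
    extract_outlier_def(
      "excluded cases more than three standard deviations above the mean"
    )$sd_values, 3
  )
  expect_length(extract_outlier_def("values 15 SD away were removed")$sd_values, 0)
  expect_length(extract_outlier_def("scores of 2 SD were typical")$sd_values, 0)
  expect_equal(
    extract_outlier_def("outliers beyond 2.5 sds were trimmed")$sd_values, 2.5
  )
  expect_equal(
    extract_outlier_def("removed beyond 1.5 SD", lo = 2, hi = 10)$sd_values,
    numeric(0)
  )
})

test_that("assumption extraction is dictionary-bound with longest-match-wins", {
  expect_equal(extract_assumptions("the assumption of sphericity was tested")$assumptions,
               "sphericity")
  expect_equal(
    extract_assumptions("data were missing completely at random")$assumptions,
    "missing completely at random"
  )
  expect_length(
    extract_assumptions("homogeneity of covariance matrices was checked")$assumptions,
    0
  )
  expect_length(extract_assumptions("sampling adequacy was confirmed")$assumptions, 0)
  both <- extract_assumptions(
    "Data were missing at random; other data were missing completely at random."
  )
  expect_setequal(both$assumptions,
                  c("missing at random", "missing completely at random"))
})

test_that("software extraction covers the dictionary and the add argument", {
  expect_equal(extract_software("analyses were run in SPSS version 25")$software,
               "SPSS")
  expect_length(extract_software("ConQuest 2.0 was used")$software, 0)
  expect_equal(
    extract_software("ConQuest 2.0 was used", add = "ConQuest 2.0")$user_added,
    "ConQuest 2.0"
  )
  expect_length(extract_software("")$software, 0)
  # the bare letter R never matches without context
  expect_length(extract_software("group R scored higher than group B")$software, 0)
  expect_equal(extract_software("computed in R version 4.0.2")$software, "R")
  expect_equal(extract_software("G*Power 3.1 estimated the sample size")$software,
               "G*Power")
  # "standard deviations" must not trigger the Stan entry
  expect_length(extract_software("standard deviations are shown")$software, 0)
})

test_that("method harvesting strips redundant words and skips descriptives", {
  expect_equal(extract_methods("we applied the quickfit algorithm")$methods,
               "quickfit algorithm")
  expect_length(
    extract_methods("means and standard deviations were computed")$methods, 0
  )
  expect_equal(
    extract_methods("a repeated measures anova was conducted")$methods,
    "repeated measures anova"
  )
  expect_equal(
    extract_methods("An independent t-test was run on the scores.")$methods,
    "independent t test"
  )
  # bare identifiers are not methods
  expect_length(extract_methods("a test was administered")$methods, 0)
  # user-supplied identifier terms extend the result space
  expect_equal(
    extract_methods("we used latent profile clustering", add = "clustering")$methods,
    "latent profile clustering"
  )
  # duplicates collapse to one mention
  expect_equal(
    extract_methods(paste(
      "A cluster analysis was conducted.", "The cluster analysis converged."
    ))$methods,
    "cluster analysis"
  )
})

test_that("study counting returns the maximum enumeration and defaults to one", {
  expect_equal(count_studies(c("Study 1", "Study 2", "General Discussion")), 2)
  expect_equal(count_studies(c("Methods", "Results")), 1)
  expect_equal(count_studies(paste("Experiment", 1:6)), 6)
  expect_equal(count_studies(c("Study One", "Study Two")), 2)
  expect_equal(count_studies(character(), "We report three experiments."), 3)
  expect_equal(count_studies(c("Methods"), "No enumeration at all."), 1)
})

test_that("study_character aggregates per-surface extractions", {
  xml <- generate_article(fixture_spec(
    id = "sc-1", alpha = 0.05, alpha_style = "explicit", power = 0.8,
    software = "SPSS", methods = "repeated measures anova", seed = 5
  ))
  sc <- study_character(read_jats(xml, id = "sc-1"))
  expect_equal(feature_values(sc, "alpha"), "0.05")
  expect_equal(feature_values(sc, "power"), "0.8")
  expect_equal(feature_values(sc, "software"), "SPSS")
  expect_equal(sc$n_studies, 1L)
  expect_length(sc$errors, 0)
})

test_that("an empty article yields empty features and one study", {
  sc <- study_character(read_jats("<article><body/></article>"))
  for (f in setdiff(studychar:::sc_features, "n_studies")) {
    expect_length(feature_values(sc, f), 0)
  }
  expect_equal(sc$n_studies, 1L)
})

test_that("discussion-only mentions stay outside the extraction surfaces", {
  xml <- jats_doc(list(sec(
    "Discussion",
    paste("An alpha level of 0.01 would be advisable;",
          "a Bonferroni corrected threshold and 99% confidence intervals",
          "with outliers beyond 3 SD removed were all discussed.")
  )))
  sc <- study_character(read_jats(xml))
  expect_length(feature_values(sc, "alpha"), 0)
  expect_length(feature_values(sc, "correction"), 0)
  expect_length(feature_values(sc, "outlier_sd"), 0)
})

test_that("extractor outputs respect their range invariants on random corpora", {
  corpus <- generate_corpus(n = 25, seed = 88,
                            corruption_pool = c("strip_operators", "break_greek"))
  for (id in names(corpus$articles)) {
    sc <- study_character(read_jats(corpus$articles[[id]], id = id))
    av <- c(sc$alpha$nominal, sc$alpha$corrected, sc$alpha$from_ci)
    expect_true(all(av > 0 & av < 1))
    expect_true(all(sc$power$values >= 0 & sc$power$values <= 1))
    expect_true(all(sc$outlier$sd_values >= 1 & sc$outlier$sd_values <= 10))
    expect_gte(sc$n_studies, 1)
  }
})

test_that("identical input text yields identical results across runs", {
  xml <- generate_article(fixture_spec(id = "det-1", alpha = 0.05,
                                       power = 0.9, seed = 17))
  r1 <- as_record(study_character(read_jats(xml, id = "det-1")))
  r2 <- as_record(study_character(read_jats(xml, id = "det-1")))
  expect_identical(r1, r2)
})
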