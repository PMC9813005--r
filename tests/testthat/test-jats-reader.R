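# JATS parsing, section classification and the extraction surface.

test_that("read_jats parses a minimal article and collects captions", {
  art <- read_jats(jats_doc(list(sec("Methods", "We did things."))))
  expect_s3_class(art, "jats_article")
  expect_length(art$sections, 1)
  expect_equal(art$sections[[1]]$title, "Methods")

  art2 <- read_jats(paste0(
    "<article><body>",
    "<fig><caption><p>Figure caption text.</p></caption></fig>",
    "<table-wrap><caption><p>Table caption text.</p></caption>",
    "<table><tr><td>cell-a</td><td>cell-b</td></tr></table></table-wrap>",
    "</body></article>"
  ))
  expect_setequal(art2$captions, c("Figure caption text.", "Table caption text."))
  expect_setequal(art2$table_text, c("cell-a", "cell-b"))
})

test_that("read_jats rejects malformed XML and non-JATS roots", {
  expect_error(read_jats("<article><body></article>"), "malformed")
  expect_error(read_jats("<html><body/></html>"), "unsupported format")
  expect_error(read_jats("no-such-file.xml"), "not found")
})

test_that("references never leak into section text or surfaces", {
  art <- read_jats(jats_doc(
    sections = list(sec("Methods", "Real content here.")),
    refs = c("REFMARKER Anova handbook, SPSS press, outliers beyond 3 SD.")
  ))
  expect_length(art$reference_list, 1)
  st <- classify_sections(art)
  for (f in c("introduction", "methods", "results", "discussion",
              "unclassified", "captions")) {
    expect_false(grepl("REFMARKER", st[[f]], fixed = TRUE))
  }
  expect_false(grepl("REFMARKER", extraction_surface(st), fixed = TRUE))
})

test_that("classify_sections maps canonical and conventional titles", {
  art <- read_jats(jats_doc(list(
    sec("Introduction", "intro-p"), sec("Method", "method-p"),
    sec("Results", "results-p"), sec("Discussion", "discussion-p")
  )))
  st <- classify_sections(art)
  expect_equal(st$introduction, "intro-p")
  expect_equal(st$methods, "method-p")
  expect_equal(st$results, "results-p")
  expect_equal(st$discussion, "discussion-p")

  # conventional methods subsection names all land in methods
  art2 <- read_jats(jats_doc(list(
    sec("Participants", "p1"), sec("Measures", "p2"), sec("Procedure", "p3")
  )))
  st2 <- classify_sections(art2)
  expect_equal(st2$methods, "p1 p2 p3")
  expect_equal(st2$unclassified, "")
})

test_that("titleless sections end up unclassified and nested ones inherit", {
  # PDF-conversion output that lost every section name
  art <- read_jats(jats_doc(list(sec("", "a"), sec("", "b"), sec("", "c"))))
  st <- classify_sections(art)
  expect_equal(st$unclassified, "a b c")
  expect_equal(st$methods, "")

  # a nested untitled/unknown section goes with its classified ancestor
  xml <- paste0(
    "<article><body><sec><title>Methods</title><p>top</p>",
    "<sec><title>Stimulus set</title><p>nested</p></sec></sec>",
    "</body></article>"
  )
  st2 <- classify_sections(read_jats(xml))
  expect_equal(st2$methods, "top nested")
})

test_that("every body paragraph lands in exactly one bucket", {
  corpus <- generate_corpus(n = 12, seed = 303)
  for (id in names(corpus$articles)) {
    art <- read_jats(corpus$articles[[id]], id = id)
    st <- classify_sections(art)
    paras <- unlist(lapply(art$sections, function(s) s$paragraphs))
    all_buckets <- c(st$introduction, st$methods, st$results,
                     st$discussion, st$unclassified)
    hits <- vapply(paras, function(p) {
      sum(vapply(all_buckets, function(b) grepl(p, b, fixed = TRUE),
                 logical(1)))
    }, numeric(1))
    expect_true(all(hits == 1))
  }
})

test_that("fixture articles round-trip their planted section titles", {
  spec <- fixture_spec(id = "rt-1", n_studies = 3, seed = 99)
  art <- read_jats(generate_article(spec), id = "rt-1")
  titles <- section_titles(art)
  expect_equal(titles[1], "Introduction")
  expect_true(all(paste("Study", 1:3) %in% titles))
  expect_equal(titles[length(titles)], "General Discussion")
  # classification recovers the planted structure
  st <- classify_sections(art)
  expect_gt(nchar(st$methods), 0)
  expect_gt(nchar(st$results), 0)
  expect_equal(st$unclassified, "")
})

test_that("extraction_surface composes methods, results and captions", {
  art <- read_jats(jats_doc(
    sections = list(sec("Methods", "A"), sec("Results", "B")),
    captions = "C"
  ))
  st <- classify_sections(art)
  expect_equal(extraction_surface(st, include_captions = TRUE), "A B C")
  expect_equal(extraction_surface(st, include_captions = FALSE), "A B")
})

test_that("extraction_surface falls back to unclassified text", {
  art <- read_jats(jats_doc(list(sec("", "X"))))
  st <- classify_sections(art)
  expect_equal(extraction_surface(st, include_captions = FALSE), "X")
})

test_that("table text joins the surface only on request", {
  xml <- paste0(
    "<article><body><sec><title>Methods</title><p>A</p></sec>",
    "<table-wrap><caption><p>Tab cap</p></caption>",
    "<table><tr><td>TCELL</td></tr></table></table-wrap>",
    "</body></article>"
  )
  st <- classify_sections(read_jats(xml))
  expect_false(grepl("TCELL", extraction_surface(st)))
  expect_true(grepl("TCELL", extraction_surface(st, include_tables = TRUE)))
})

test_that("articles serialize to JSON with all fields", {
  art <- read_jats(jats_doc(list(sec("Methods", "We did things."))))
  parsed <- jsonlite::fromJSON(article_json(art))
  expect_named(parsed, c("id", "title", "abstract", "sections", "captions",
                         "table_text", "reference_list"))
})
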