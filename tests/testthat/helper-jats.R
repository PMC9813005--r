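# Build small JATS documents in code for reader tests.

jats_doc <- function(sections = list(), captions = character(),
                     abstract = "", refs = character(), title = "Example") {
  secs <- vapply(sections, function(s) {
    ps <- paste0("<p>", s$paragraphs, "</p>", collapse = "")
    tt <- if (is.null(s$title) || !nzchar(s$title)) "" else
      paste0("<title>", s$title, "</title>")
    paste0("<sec>", tt, ps, "</sec>")
  }, character(1))
  caps <- vapply(captions, function(cp) {
    paste0("<fig><caption><p>", cp, "</p></caption></fig>")
  }, character(1))
  refs_xml <- if (length(refs)) {
    paste0("<back><ref-list>",
           paste0("<ref>", refs, "</ref>", collapse = ""),
           "</ref-list></back>")
  } else {
    ""
  }
  abs_xml <- if (nzchar(abstract)) {
    paste0("<abstract><p>", abstract, "</p></abstract>")
  } else {
    ""
  }
  paste0(
    "<article dtd-version='1.1'><front><article-meta>",
    "<article-id>test-art</article-id>",
    "<title-group><article-title>", title, "</article-title></title-group>",
    abs_xml,
    "</article-meta></front><body>",
    paste0(secs, collapse = ""), paste0(caps, collapse = ""),
    "</body>", refs_xml, "</article>"
  )
}

sec <- function(title, ...) list(title = title, paragraphs = c(...))
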