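test_that("empty input renders a valid page with a zero-interactions notice", {
  h <- write_mi_html(list())
  doc <- xml2::read_html(h)
  expect_match(xml2::xml_text(xml2::xml_find_first(doc, "//p[@class='empty']")),
               "Zero interactions")
})

test_that("each interaction gets one participants table with one row per participant", {
  i <- h_nary(3L, interaction_type = cv_term("association"),
              experiment = experiment(detection_method = cv_term("two hybrid")))
  h <- write_mi_html(list(i))
  doc <- xml2::read_html(h)
  tables <- xml2::xml_find_all(doc, "//table[@class='participants']")
  expect_length(tables, 1L)
  expect_length(xml2::xml_find_all(tables[[1L]], ".//tbody/tr"), 3L)
  # each participant id appears exactly once in its table
  body <- xml2::xml_text(tables[[1L]])
  for (id in c("P1", "P2", "P3"))
    expect_length(gregexpr(paste0("uniprotkb:", id), body, fixed = TRUE)[[1L]], 1L)
})

test_that("generated networks render deterministically and escape markup", {
  ints <- net_interactions(generate_network(cfg_full(3L)))
  h1 <- write_mi_html(ints); h2 <- write_mi_html(ints)
  expect_identical(h1, h2)
  expect_length(xml2::xml_find_all(xml2::read_html(h1), "//section"), length(ints))

  hostile <- interaction(list(h_participant("P<script>1")),
                         annotations = list(annotation(cv_term("comment"), "<b>x</b>")))
  h <- write_mi_html(list(hostile))
  expect_false(grepl("<script>", h, fixed = TRUE))
  expect_match(h, "P&lt;script&gt;1", fixed = TRUE)
})

test_that("the html read direction is rejected", {
  expect_error(read_html_attempt("x"), class = "mi_capability_error")
  expect_error(format_descriptor("html", direction = "read"), class = "mi_capability_error")
})
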