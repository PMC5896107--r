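test_that("object counts follow the dedup rule", {
  # one binary between distinct molecules: 2 interactor objects + 1 interaction
  b <- spoke_expand(h_nary(2L))[[1L]]
  doc <- jsonlite::fromJSON(write_mijson(list(b)), simplifyVector = FALSE)
  expect_length(doc$data, 3L)
  expect_equal(vapply(doc$data, `[[`, character(1L), "object"),
               c("interactor", "interactor", "interaction"))

  # self-interaction: 1 interactor + 1 interaction
  s <- spoke_expand(h_nary(1L))[[1L]]
  doc <- jsonlite::fromJSON(write_mijson(list(s)), simplifyVector = FALSE)
  expect_length(doc$data, 2L)

  # empty input: empty data list, still schema-conformant
  empty <- write_mijson(list())
  expect_length(jsonlite::fromJSON(empty, simplifyVector = FALSE)$data, 0L)
  expect_length(mijson_conforms(empty), 0L)
})

test_that("interactor objects are unique, sorted, and all references resolve", {
  bins <- expand_interactions(net_interactions(generate_network(cfg_full(4L, n = 10L))),
                              method = "matrix")
  txt <- write_mijson(bins)
  expect_length(mijson_conforms(txt), 0L)
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  kinds <- vapply(doc$data, `[[`, character(1L), "object")
  ids <- vapply(doc$data[kinds == "interactor"], `[[`, character(1L), "id")
  expect_false(any(duplicated(ids)))
  expect_identical(ids, sort(ids, method = "radix"))
  distinct_in <- unique(unlist(lapply(bins, function(b) vapply(b$participants,
    function(p) paste0(tolower(p$interactor$preferred_id$database$short_name), ":",
                       p$interactor$preferred_id$identifier), character(1L)))))
  expect_length(ids, length(distinct_in))
  expect_equal(sum(kinds == "interaction"), length(bins))
  # deterministic output
  expect_identical(txt, write_mijson(bins))
})

test_that("the conformance checker catches broken documents", {
  bad <- '{"format":"mi-json","version":"1.0","data":[
    {"object":"interaction","id":"1","interactorA":{"id":"uniprotkb:P1"},
     "interactorB":{"id":"uniprotkb:P2"}}]}'
  v <- mijson_conforms(bad)
  expect_length(v, 2L)   # both references unresolved
  expect_match(v, "does not resolve", all = TRUE)
  expect_match(mijson_conforms('{"x": 1}'), "no 'data'")
})

test_that("the read direction is rejected by function and registry alike", {
  expect_error(read_mijson_attempt("anything"), class = "mi_capability_error")
  expect_error(format_descriptor("mi-json", direction = "read"),
               class = "mi_capability_error")
  expect_silent(format_descriptor("mi-json", direction = "write"))
})
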