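test_that("compact and expanded serializations re-read to identical models", {
  for (seed in 1:6) {
    es <- generate_network(cfg_full(seed))$entry_set
    ints <- net_interactions(list(entry_set = es))
    for (v in c("2.5", "3.0")) {
      compact <- read_psimi_xml(write_psimi_xml(es, version = v, style = "compact"))
      expanded <- read_psimi_xml(write_psimi_xml(es, version = v, style = "expanded"))
      ic <- compact$entries[[1L]]$interactions
      ie <- expanded$entries[[1L]]$interactions
      expect_true(all_equal_at(ic, ie, "exact"),
                  label = sprintf("seed %d v%s compact == expanded", seed, v))
      expect_true(all_equal_at(ints, ic, "exact"),
                  label = sprintf("seed %d v%s round trip", seed, v))
      expect_equal(vapply(ie, arity, integer(1L)), vapply(ints, arity, integer(1L)))
    }
  }
})

test_that("a single binary interaction compacts to exactly two interactor definitions", {
  es <- entry_set(list(mi_entry(interactions = list(h_nary(2L)))))
  txt <- write_psimi_xml(es, style = "compact")
  doc <- xml2::xml_ns_strip(xml2::read_xml(txt))
  expect_length(xml2::xml_find_all(doc, "//interactorList/interactor"), 2L)
  # shared molecules across interactions are defined once and referenced
  es2 <- entry_set(list(mi_entry(interactions = list(h_nary(3L, id = "a"),
                                                     h_nary(3L, id = "b")))))
  doc2 <- xml2::xml_ns_strip(xml2::read_xml(write_psimi_xml(es2, style = "compact")))
  expect_length(xml2::xml_find_all(doc2, "//interactorList/interactor"), 3L)
  ids <- xml2::xml_attr(xml2::xml_find_all(
    doc2, paste("//interactor[@id]", "//interaction[@id]", "//participant[@id]",
                "//experimentDescription[@id]", "//feature[@id]", sep = " | ")), "id")
  expect_false(any(duplicated(ids)))   # dense, collision-free id assignment
})

test_that("dangling numeric references are raised (or reported) naming the id", {
  txt <- paste0(
    '<entrySet xmlns="http://psi.hupo.org/mi/mif" level="2" version="5"><entry>',
    '<interactorList><interactor id="1"><names><shortLabel>P1</shortLabel></names>',
    '<xref><primaryRef db="uniprotkb" id="P1"/></xref></interactor></interactorList>',
    '<interactionList><interaction id="2"><participantList>',
    '<participant id="3"><interactorRef>1</interactorRef></participant>',
    '<participant id="4"><interactorRef>99</interactorRef></participant>',
    '</participantList></interaction></interactionList></entry></entrySet>')
  expect_error(read_psimi_xml(txt), "99", class = "mi_dangling_reference")
  es <- read_psimi_xml(txt, on_error = "report")
  rep <- attr(es, "report")
  expect_equal(nrow(rep), 1L)
  expect_match(rep$message, "99")
  expect_length(es$entries[[1L]]$interactions, 0L)
})

test_that("an experiment can carry both a publication xref and inline attributes", {
  pub <- publication(pubmed_id = "12345678", journal = "J Synth Biol",
                     title = "Probing a synthetic interactome",
                     authors = c("Adler et al.", "Basu et al."))
  i <- interaction(list(h_participant("P1"), h_participant("P2")), id = "dual",
                   experiment = experiment(publication = pub,
                                           detection_method = cv_term("two hybrid", mi_identifier = "MI:0018")))
  es <- entry_set(list(mi_entry(interactions = list(i))), version = "3.0")
  back <- read_psimi_xml(write_psimi_xml(es, version = "3.0"))
  p2 <- back$entries[[1L]]$interactions[[1L]]$experiment$publication
  expect_equal(p2$pubmed_id, "12345678")        # the cross-reference half
  expect_equal(p2$journal, "J Synth Biol")      # the inline half
  expect_equal(p2$title, "Probing a synthetic interactome")
  expect_equal(p2$authors, c("Adler et al.", "Basu et al."))
  # and survives a second 3.0 round trip unchanged
  again <- read_psimi_xml(write_psimi_xml(back, version = "3.0"))
  expect_equal(again$entries[[1L]]$interactions[[1L]]$experiment$publication, p2)

  # 2.5 allows only one representation: the cross-reference wins
  p25 <- read_psimi_xml(write_psimi_xml(es, version = "2.5"))$entries[[1L]]$
    interactions[[1L]]$experiment$publication
  expect_equal(p25$pubmed_id, "12345678")
  expect_null(p25$journal)
})

test_that("abstract interactions need 3.0; at 3.0 they round trip", {
  cx <- complex_record("exosome mimic", list(h_participant("P1"), h_participant("P2"),
                                             h_participant("P3")),
                       organism = organism(9606L, "human"))
  es <- entry_set(list(mi_entry(complexes = list(cx))), version = "3.0")
  expect_error(write_psimi_xml(es, version = "2.5"), class = "mi_capability_error")
  back <- read_psimi_xml(write_psimi_xml(es, version = "3.0"))
  cx2 <- back$entries[[1L]]$complexes[[1L]]
  expect_equal(cx2$recommended_name, "exosome mimic")
  expect_length(cx2$participants, 3L)
  expect_equal(cx2$organism$taxid, 9606L)
  expect_equal(back$version, "3.0")
})

test_that("out-of-scope 3.0 elements are reported, not silently dropped", {
  txt <- paste0(
    '<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0"><entry>',
    '<interactionList><interaction id="1"><participantList>',
    '<participant id="2"><interactor id="3"><names><shortLabel>P1</shortLabel></names>',
    '<xref><primaryRef db="uniprotkb" id="P1"/></xref></interactor></participant>',
    '</participantList><cooperativeEffectList><cooperativity/></cooperativeEffectList>',
    '</interaction></interactionList></entry></entrySet>')
  es <- read_psimi_xml(txt, on_error = "report")
  rep <- attr(es, "report")
  expect_true(any(rep$type == "unsupported-element"))
  expect_match(rep$message[rep$type == "unsupported-element"], "cooperativeEffect")
  expect_length(es$entries[[1L]]$interactions, 1L)  # the record itself is kept
})

test_that("malformed documents and foreign dialects are rejected", {
  expect_error(read_psimi_xml("<entrySet><entry>"), class = "mi_syntax_error")
  expect_error(read_psimi_xml("<notMI/>"), class = "mi_unsupported_dialect")
  expect_error(read_psimi_xml('<entrySet level="7"/>'), class = "mi_unsupported_dialect")
  expect_error(write_psimi_xml(entry_set(list())), class = "mi_invalid")
  expect_error(write_psimi_xml(entry_set(list(mi_entry(interactions = list(h_nary(2L))))),
                               version = "1.0"),
               class = "mi_unsupported_dialect")
})
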