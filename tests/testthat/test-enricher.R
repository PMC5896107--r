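fixture_fetcher <- function() {
  tsv_fetcher(system.file("extdata", "fetcher-records.tsv", package = "rpsimi"))
}

test_that("the file-backed fetcher is a pure lookup", {
  fx <- fixture_fetcher()
  rec <- fetch(fx, "P00001")
  expect_s3_class(rec, "mi_fetcher_record")
  expect_equal(rec$full_name, "Synthetic kinase alpha")
  expect_equal(rec$organism$taxid, 9606L)
  expect_length(rec$aliases, 2L)
  expect_length(rec$xrefs, 2L)
  expect_null(fetch(fx, "P99999"))
  expect_error(tsv_fetcher("/nonexistent/table.tsv"), class = "mi_config_error")
})

test_that("fill_only fills absent fields only and records conflicts untouched", {
  fx <- fixture_fetcher()
  bare <- h_interactor("P00002")
  r1 <- enrich_interactor(bare, fx, "fill_only")
  expect_setequal(r1$report$fields_filled,
                  c("full_name", "organism", "sequence", "aliases", "xrefs"))
  expect_equal(nrow(r1$report$conflicts), 0L)
  expect_equal(r1$interactor$full_name, "Synthetic kinase beta")

  # an existing organism that disagrees stays put, with one conflict recorded
  clash <- interactor(xref(cv_term("uniprotkb"), "P00002"),
                      organism = organism(10090L, "mouse"))
  r2 <- enrich_interactor(clash, fx, "fill_only")
  expect_equal(r2$interactor$organism$taxid, 10090L)
  expect_equal(r2$report$conflicts$field, "organism")
  expect_equal(r2$report$conflicts$fetched, "9606")

  # overwrite applies the fetched value and still records the conflict
  r3 <- enrich_interactor(clash, fx, "overwrite")
  expect_equal(r3$interactor$organism$taxid, 9606L)
  expect_equal(nrow(r3$report$conflicts), 1L)
})

test_that("enrichment is idempotent and never removes information", {
  fx <- fixture_fetcher()
  x <- interactor(xref(cv_term("uniprotkb"), "P00006"),
                  aliases = list(mi_alias("my-private-alias")))
  r1 <- enrich_interactor(x, fx, "fill_only")
  r2 <- enrich_interactor(r1$interactor, fx, "fill_only")
  expect_length(r2$report$fields_filled, 0L)
  expect_identical(r2$interactor, r1$interactor)
  alias_names <- vapply(r1$interactor$aliases, `[[`, character(1L), "name")
  expect_true("my-private-alias" %in% alias_names)   # pre-existing data kept
  expect_true(length(alias_names) > 1L)              # fetched data merged in

  miss <- enrich_interactor(h_interactor("ZZZZ"), fx, "fill_only")
  expect_equal(miss$report$misses, "ZZZZ")
  expect_identical(miss$interactor, h_interactor("ZZZZ"))
})

test_that("CV terms gain canonical names from the ontology fetcher", {
  cvf <- obo_cv_fetcher()
  hit <- enrich_cvterm(cv_term("MI:0407", mi_identifier = "MI:0407"), cvf)
  expect_equal(hit$term$short_name, "direct interaction")
  expect_equal(hit$term$full_name, "direct interaction")
  again <- enrich_cvterm(hit$term, cvf)
  expect_length(again$report$fields_filled, 0L)

  # resolution by name fills the accession
  by_name <- enrich_cvterm(cv_term("two hybrid"), cvf)
  expect_equal(by_name$term$mi_identifier, "MI:0018")

  unknown <- enrich_cvterm(cv_term("made-up term"), cvf)
  expect_equal(unknown$report$misses, "made-up term")
})
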