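test_that("the mini ontology loads with the expected is_a structure", {
  ont <- read_obo(mini_obo_path())
  expect_gt(length(ont), 45L)
  expect_true(obo_is_descendant(ont, "MI:0018", "MI:0001"))   # two hybrid -> detection
  expect_true(obo_is_descendant(ont, "MI:0096", "MI:0001"))   # via affinity chromatography
  expect_false(obo_is_descendant(ont, "MI:0326", "MI:0001"))  # protein is not a method
  expect_true(obo_is_descendant(ont, "MI:0499", "MI:0500"))   # unspecified role, both parents
  expect_true(obo_is_descendant(ont, "MI:0499", "MI:0495"))
  expect_error(read_obo("/nonexistent.obo"), class = "mi_config_error")
})

test_that("rule files are validated as configuration", {
  rules <- read_validation_rules()
  expect_true(all(c("location", "required_ancestor", "severity") %in% names(rules)))
  bad <- tempfile(fileext = ".tsv")
  writeLines("location\trequired_ancestor\tseverity\ninteraction.colour\tMI:0001\terror", bad)
  expect_error(read_validation_rules(bad), class = "mi_config_error")
  badanc <- data.frame(location = "interaction.interaction_type",
                       required_ancestor = "MI:8888", severity = "error")
  class(badanc) <- c("mi_rule_set", "data.frame")
  expect_error(check_cv_usage(list(h_nary(2L)), read_obo(mini_obo_path()), badanc),
               class = "mi_config_error")
})

test_that("clean generator output yields zero findings (no false positives)", {
  net <- generate_network(cfg_full(6L, n = 12L))
  f_mitab <- tempfile(fileext = ".tsv")
  write_mitab(expand_interactions(net_interactions(net), method = "matrix"),
              "2.7", f_mitab)
  expect_equal(nrow(validate_file(f_mitab)), 0L)
  f_xml <- tempfile(fileext = ".xml")
  write_psimi_xml(net$entry_set, path = f_xml)
  expect_equal(nrow(validate_file(f_xml)), 0L)
})

test_that("wrong-location and unknown terms are flagged where they sit", {
  ont <- read_obo(mini_obo_path())
  rules <- read_validation_rules()
  # detection method slot holding an interactor-type term: one wrong-location
  i <- h_nary(2L, experiment = experiment(
    detection_method = cv_term("protein", mi_identifier = "MI:0326")))
  rep <- check_cv_usage(list(i), ont, rules)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$type, "wrong-location")
  expect_equal(rep$location, "experiment.detection_method")
  # unknown accession: one term-not-found
  j <- h_nary(2L, interaction_type = cv_term("mystery", mi_identifier = "MI:9999"))
  rep2 <- check_cv_usage(list(j), ont, rules)
  expect_equal(nrow(rep2), 1L)
  expect_equal(rep2$type, "term-not-found")
  # a term under the right root passes
  k <- h_nary(2L, experiment = experiment(
    detection_method = cv_term("two hybrid", mi_identifier = "MI:0018")))
  expect_equal(nrow(check_cv_usage(list(k), ont, rules)), 0L)
  # terms with no accession cannot be checked and are skipped
  l <- h_nary(2L, interaction_type = cv_term("free-text type"))
  expect_equal(nrow(check_cv_usage(list(l), ont, rules)), 0L)
})

test_that("syntax checking reuses reader reports for both families", {
  net <- generate_network(cfg_full(7L, n = 10L))
  f <- tempfile(fileext = ".tsv")
  write_mitab(expand_interactions(net_interactions(net), method = "matrix"), "2.7", f)
  expect_equal(nrow(check_syntax(f)$report), 0L)

  cr <- corrupt(f, c(wrong_column_count = 1L), seed = 2L)
  syn <- check_syntax(cr$path)
  expect_equal(nrow(syn$report), 1L)
  expect_equal(syn$report$type, "column-count")

  fx <- tempfile(fileext = ".xml")
  write_psimi_xml(net$entry_set, path = fx)
  crx <- corrupt(fx, c(dangling_ref = 2L), seed = 2L)
  synx <- check_syntax(crx$path)
  expect_equal(nrow(synx$report), 2L)
  expect_true(all(synx$report$type == "dangling-reference"))

  notxml <- tempfile(fileext = ".xml")
  writeLines("<entrySet", notxml)
  expect_equal(check_syntax(notxml)$report$type, "syntax")
  expect_error(check_syntax("/nonexistent.file"), class = "mi_io_error")
})

test_that("every injected corruption is reported exactly once", {
  net <- generate_network(cfg_full(8L, n = 14L, arity_distribution = c("2" = 1.0)))
  f <- tempfile(fileext = ".tsv")
  write_mitab(expand_interactions(net_interactions(net), method = "none"), "2.7", f)
  spec <- c(wrong_column_count = 2L, unbalanced_quote = 2L,
            wrong_location_cv = 2L, unknown_cv = 2L)
  cr <- corrupt(f, spec, seed = 9L)
  rep <- validate_file(cr$path)
  expect_equal(nrow(rep), sum(spec))
  counts <- table(rep$type)
  expect_equal(unname(counts[c("column-count", "malformed-field",
                               "wrong-location", "term-not-found")]),
               rep(2L, 4L), ignore_attr = TRUE)
  # determinism of injection sites; zero-corruption spec leaves bytes alone
  cr2 <- corrupt(f, spec, seed = 9L, out_path = tempfile())
  expect_identical(readLines(cr$path), readLines(cr2$path))
  cr0 <- corrupt(f, c(wrong_column_count = 0L), seed = 1L, out_path = tempfile())
  expect_identical(readLines(cr0$path), readLines(f))
  expect_error(corrupt(f, c(dangling_ref = 1L)), class = "mi_config_error")
})
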