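test_that("column counts identify the dialect lattice", {
  expect_equal(detect_mitab_version(15L), "2.5")
  expect_equal(detect_mitab_version(36L), "2.6")
  expect_equal(detect_mitab_version(42L), "2.7")
  expect_error(detect_mitab_version(17L), class = "mi_unsupported_dialect")
  expect_error(detect_mitab_version(1L), class = "mi_unsupported_dialect")
})

test_that("the field grammar parses bare, quoted and empty values", {
  f <- parse_mitab_field("uniprotkb:P12345")
  expect_length(f, 1L)
  expect_equal(f[[1L]][c("db", "id", "text")],
               list(db = "uniprotkb", id = "P12345", text = ""))

  expect_identical(parse_mitab_field("-"), list())

  f <- parse_mitab_field('psi-mi:"MI:0407"(direct interaction)')
  expect_equal(f[[1L]], list(db = "psi-mi", id = "MI:0407", text = "direct interaction"))

  f <- parse_mitab_field("uniprotkb:P1|uniprotkb:P2(gene)")
  expect_length(f, 2L)
  expect_equal(f[[2L]]$text, "gene")

  # quoted pipe does not split; escaped quote inside quotes survives
  f <- parse_mitab_field('db:"a|b"|db:"say \\"hi\\""')
  expect_length(f, 2L)
  expect_equal(f[[1L]]$id, "a|b")
  expect_equal(f[[2L]]$id, 'say "hi"')

  expect_error(parse_mitab_field('db:"unterminated'), class = "mi_malformed_field")
  expect_error(parse_mitab_field("db:id(unclosed"), class = "mi_malformed_field")
})

test_that("a small 2.5 document maps rows onto binary interactions", {
  txt <- paste(
    "#ID(s) interactor A\tID(s) interactor B\tthe rest of the header",
    paste(c("uniprotkb:P1", "uniprotkb:P2", rep("-", 13L)), collapse = "\t"),
    paste(c("uniprotkb:P3", "uniprotkb:P4", rep("-", 13L)), collapse = "\t"),
    sep = "\n")
  res <- read_mitab(txt)
  expect_length(res, 2L)
  expect_equal(attr(res, "mitab_version"), "2.5")
  expect_equal(nrow(parse_report(res)), 0L)
  ids <- vapply(res, function(b) vapply(b$participants, function(p)
    p$interactor$preferred_id$identifier, character(1L)), character(2L))
  expect_equal(as.vector(ids), c("P1", "P2", "P3", "P4"))

  # 2.5 self-interaction convention: all B columns empty means A == B
  selfrow <- paste(c("uniprotkb:P9", rep("-", 14L)), collapse = "\t")
  b <- read_mitab(selfrow)[[1L]]
  expect_equal(b$participants[[2L]]$interactor$preferred_id$identifier, "P9")
})

test_that("a 2.7 feature column yields a participant feature with its range", {
  net <- generate_network(cfg_full(1L, n = 1L))
  b <- expand_interactions(net_interactions(net), method = "matrix")[1L]
  row <- strsplit(write_mitab(b, "2.7"), "\n")[[1L]][2L]
  cells <- strsplit(row, "\t", fixed = TRUE)[[1L]]
  cells[37L] <- "binding-associated region:1-10"
  b2 <- read_mitab(paste(cells, collapse = "\t"), version = "2.7")
  ft <- b2[[1L]]$participants[[1L]]$features
  expect_length(ft, 1L)
  expect_equal(ft[[1L]]$feature_type$short_name, "binding-associated region")
  expect_equal(ft[[1L]]$ranges[[1L]]$start, 1L)
  expect_equal(ft[[1L]]$ranges[[1L]]$end, 10L)
})

test_that("empty input reads to an empty sequence and writes a bare header", {
  res <- read_mitab("#header only")
  expect_length(res, 0L)
  expect_equal(nrow(parse_report(res)), 0L)
  out <- write_mitab(list(), "2.6")
  lines <- strsplit(out, "\n")[[1L]]
  expect_length(lines, 1L)
  expect_true(startsWith(lines, "#"))
  expect_length(strsplit(lines, "\t")[[1L]], 36L)
})

test_that("read-write round trips are exact for dialect-expressible networks", {
  for (seed in 1:8) {
    cases <- list(list(cfg_mitab25(seed), "2.5"), list(cfg_mitab26(seed), "2.6"),
                  list(cfg_full(seed), "2.7"))
    for (case in cases) {
      bins <- expand_interactions(net_interactions(generate_network(case[[1L]])),
                                  method = "matrix")
      back <- read_mitab(write_mitab(bins, case[[2L]]))
      expect_true(all_equal_at(bins, back, "exact"),
                  label = sprintf("seed %d version %s exact round trip", seed, case[[2L]]))
      expect_equal(nrow(parse_report(back)), 0L)
    }
  }
})

test_that("writing a lower version truncates monotonically and keeps identity", {
  bins <- expand_interactions(net_interactions(generate_network(cfg_full(5L, p_negative = 0))),
                              method = "spoke", spoke_fallback = "first_participant")
  t25 <- write_mitab(bins, "2.5")
  rows <- strsplit(t25, "\n")[[1L]][-1L]
  expect_true(all(lengths(strsplit(rows, "\t", fixed = TRUE)) == 15L))
  back <- read_mitab(t25)
  expect_true(all_equal_at(bins, back, "identity"))

  # monotone lattice: whatever survives 2.5 also survives 2.6 and 2.7
  b26 <- read_mitab(write_mitab(bins, "2.6"))
  b27 <- read_mitab(write_mitab(bins, "2.7"))
  expect_true(all_equal_at(b26, b27, "default"))
  expect_true(all_equal_at(back, b26, "identity"))
})

test_that("negative evidence has no 2.5 slot and is dropped with a warning", {
  b <- spoke_expand(h_nary(2L, is_negative = TRUE))[[1L]]
  expect_warning(txt <- write_mitab(list(b), "2.5"), "negative")
  expect_false(read_mitab(txt)[[1L]]$is_negative)
  expect_silent(t26 <- write_mitab(list(b), "2.6"))
  expect_true(read_mitab(t26)[[1L]]$is_negative)
})

test_that("malformed rows are skipped with exactly one report entry each", {
  bins <- expand_interactions(net_interactions(generate_network(cfg_full(2L))),
                              method = "matrix")
  lines <- strsplit(write_mitab(bins, "2.7"), "\n")[[1L]]
  n_rows <- length(lines) - 1L
  cells <- strsplit(lines[[3L]], "\t")[[1L]]
  lines[[3L]] <- paste(cells[-42L], collapse = "\t")           # wrong column count
  cells5 <- strsplit(lines[[5L]], "\t")[[1L]]
  cells5[[7L]] <- paste0(cells5[[7L]], '"')                    # unbalanced quote
  lines[[5L]] <- paste(cells5, collapse = "\t")
  res <- read_mitab(paste(lines, collapse = "\n"))
  rep <- parse_report(res)
  expect_equal(nrow(rep), 2L)
  expect_setequal(rep$type, c("column-count", "malformed-field"))
  expect_equal(length(res) + nrow(rep), n_rows)   # row conservation
  expect_error(write_mitab(res, "2.8"), class = "mi_unsupported_dialect")
})

test_that("reserved characters in identifiers survive quoting round trips", {
  weird <- binary_interaction(
    h_participant("P|1(x)"), h_participant("P:2"),
    annotations = list(annotation(cv_term("comment"), 'he said "go"')))
  back <- read_mitab(write_mitab(list(weird), "2.7"))
  expect_length(back, 1L)
  expect_true(semantic_equals(weird, back[[1L]], "exact"))
  ids <- vapply(back[[1L]]$participants, function(p)
    p$interactor$preferred_id$identifier, character(1L))
  expect_setequal(ids, c("P|1(x)", "P:2"))
})
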