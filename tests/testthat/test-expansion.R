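test_that("spoke and matrix match brute-force pair enumeration for arity 2..10", {
  for (n in 2:10) {
    i <- h_nary(n)
    sp <- spoke_expand(i)
    mx <- matrix_expand(i)
    expect_length(sp, n - 1L)
    expect_length(mx, n * (n - 1L) / 2L)
    expect_identical(sort(vapply(mx, pair_key, character(1L))), brute_force_pairs(i))
    expect_false(any(duplicated(vapply(mx, pair_key, character(1L)))))
    # every spoke pair contains the bait and is a subset of the matrix pairs
    expect_true(all(grepl("(^|\\+)P1(\\+|$)", vapply(sp, pair_key, character(1L)))))
    expect_true(all(vapply(sp, pair_key, character(1L)) %in%
                      vapply(mx, pair_key, character(1L))))
  }
})

test_that("natively binary and self records pass through untagged", {
  b <- spoke_expand(h_nary(2L))
  expect_length(b, 1L)
  expect_null(b[[1L]]$complex_expansion)
  m <- matrix_expand(h_nary(2L))
  expect_length(m, 1L)
  expect_null(m[[1L]]$complex_expansion)

  s <- spoke_expand(h_nary(1L))
  expect_length(s, 1L)
  ids <- vapply(s[[1L]]$participants, function(p) p$interactor$preferred_id$identifier,
                character(1L))
  expect_equal(ids, c("P1", "P1"))   # self-interaction, A == B

  # true expansion products carry the method term
  expect_equal(spoke_expand(h_nary(3L))[[1L]]$complex_expansion$mi_identifier, "MI:1060")
  expect_equal(matrix_expand(h_nary(3L))[[1L]]$complex_expansion$mi_identifier, "MI:1061")
})

test_that("the hub policy handles missing and duplicate baits", {
  no_bait <- h_nary(3L, with_bait = FALSE)
  expect_error(spoke_expand(no_bait, fallback = "error"), class = "mi_ambiguous_hub")
  res <- spoke_expand(no_bait, fallback = "first_participant")
  expect_length(res, 2L)
  # deterministic hub: lexicographically smallest preferred id (P1)
  expect_true(all(grepl("(^|\\+)P1(\\+|$)", vapply(res, pair_key, character(1L)))))
  expect_match(attr(res, "hub_fallback"), "P1")

  two_baits <- interaction(list(h_participant("P1", bait_cv()),
                                h_participant("P2", bait_cv()),
                                h_participant("P3", prey_cv())), id = "tb")
  expect_error(spoke_expand(two_baits, fallback = "error"), class = "mi_ambiguous_hub")
  expect_length(spoke_expand(two_baits, fallback = "first_participant"), 2L)
})

test_that("interaction-level fields are inherited verbatim by every product", {
  i <- h_nary(4L, interaction_type = cv_term("association", mi_identifier = "MI:0914"),
              confidences = list(confidence(cv_term("intact-miscore"), "0.62")),
              annotations = list(annotation(cv_term("comment"), "carried")),
              is_negative = TRUE)
  for (b in c(spoke_expand(i), matrix_expand(i))) {
    expect_equal(b$interaction_type$mi_identifier, "MI:0914")
    expect_equal(b$confidences[[1L]]$value, "0.62")
    expect_equal(b$annotations[[1L]]$value, "carried")
    expect_true(b$is_negative)
    # participant multiset is a sub-multiset of the input's
    in_ids <- vapply(i$participants, function(p) p$interactor$preferred_id$identifier,
                     character(1L))
    out_ids <- vapply(b$participants, function(p) p$interactor$preferred_id$identifier,
                      character(1L))
    expect_true(all(out_ids %in% in_ids))
  }
})

test_that("expand_interactions enforces binary-only targets and skip policy", {
  mixed <- list(h_nary(2L, id = "b"), h_nary(4L, id = "n"),
                h_nary(3L, with_bait = FALSE, id = "nb"))
  expect_error(expand_interactions(mixed, method = "none"), class = "mi_capability_error")
  mx <- expand_interactions(mixed, method = "matrix")
  expect_length(mx, 1L + 6L + 3L)
  sp <- expand_interactions(mixed, method = "spoke", spoke_fallback = "skip")
  expect_length(sp, 1L + 3L)                      # the no-bait record is skipped
  expect_equal(parse_report(sp)$type, "ambiguous-hub-skipped")
  sp2 <- expand_interactions(mixed, method = "spoke", spoke_fallback = "first_participant")
  expect_length(sp2, 1L + 3L + 2L)
})
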