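test_that("constructors enforce their invariants", {
  expect_error(cv_term(""), class = "mi_invalid")
  expect_error(cv_term("x", mi_identifier = "MI:12"), class = "mi_invalid")
  expect_error(cv_term("x", mi_identifier = "GO:0001"), class = "mi_invalid")
  expect_silent(cv_term("x", mi_identifier = "MI:0001"))

  expect_error(organism(0L), class = "mi_invalid")
  expect_error(organism(-6L), class = "mi_invalid")
  expect_silent(organism(-1L))          # in vitro
  expect_silent(organism(9606L))

  expect_error(interactor(preferred_id = "not an xref"), class = "mi_invalid")
  expect_error(h_interactor("P1", sequence = "MK T"), class = "mi_invalid")

  expect_error(feature_range(10L, 2L), class = "mi_invalid")
  expect_error(feature_range(0L, 5L), class = "mi_invalid")
  expect_silent(feature_range(NA, 10L))  # undetermined start is fine

  expect_error(stoichiometry(3L, 1L), class = "mi_invalid")
  expect_error(stoichiometry(-1L), class = "mi_invalid")

  expect_error(publication(), class = "mi_invalid")
  expect_silent(publication(title = "inline only"))

  expect_error(interaction(list()), class = "mi_invalid")
  expect_equal(arity(h_nary(4L)), 4L)
})

test_that("defaults are applied on construction and by apply_defaults, idempotently", {
  p <- h_participant("P1")
  expect_equal(p$biological_role$mi_identifier, "MI:0499")
  e <- experiment()
  expect_equal(e$detection_method$mi_identifier, "MI:0686")

  i <- h_nary(3L, experiment = experiment(publication = publication(pubmed_id = "1")))
  once <- apply_defaults(i)
  twice <- apply_defaults(once)
  expect_true(semantic_equals(once, twice, "exact"))
  expect_true(semantic_equals(i, once, "exact"))  # fully specified input unchanged
})

test_that("semantic_equals distinguishes the three stringency levels", {
  a <- interaction(list(h_participant("P1"), h_participant("P2")),
                   interaction_type = cv_term("direct interaction", mi_identifier = "MI:0407"))
  b <- interaction(list(h_participant("P2"), h_participant("P1")),
                   interaction_type = cv_term("association", mi_identifier = "MI:0914"))
  for (s in c("identity", "default", "exact"))
    expect_true(semantic_equals(a, a, s))       # reflexivity
  expect_true(semantic_equals(a, b, "identity"))  # same molecules, any order
  expect_false(semantic_equals(a, b, "default"))  # type differs
  expect_true(semantic_equals(a, b, "default") == semantic_equals(b, a, "default"))
  expect_error(semantic_equals(a, b, "strictest"), class = "mi_invalid")
})

test_that("collections compare as multisets: annotation order is irrelevant at exact", {
  anns <- list(annotation(cv_term("comment"), "one"),
               annotation(cv_term("caution"), "two"),
               annotation(cv_term("comment"), "three"))
  a <- interaction(list(h_participant("P1"), h_participant("P2")), annotations = anns)
  b <- interaction(list(h_participant("P2"), h_participant("P1")),
                   annotations = rev(anns))
  # independent oracle: serialized annotation multisets must agree
  ser <- function(i) sort(vapply(i$annotations, function(x)
    paste0(x$topic$short_name, "=", x$value), character(1L)))
  expect_identical(ser(a), ser(b))
  expect_true(semantic_equals(a, b, "exact"))
})

test_that("equality levels nest: exact implies default implies identity (1000 pairs)", {
  set.seed(42)
  types <- list(NULL, cv_term("direct interaction", mi_identifier = "MI:0407"),
                cv_term("association", mi_identifier = "MI:0914"))
  roles <- list(NULL, bait_cv(), prey_cv())
  mk <- function() {
    n <- sample(1:4, 1L)
    parts <- lapply(sample(1:5, n), function(k)
      participant(h_interactor(paste0("P", k)),
                  experimental_role = roles[[sample.int(3L, 1L)]],
                  features = if (runif(1) < 0.3)
                    list(feature(cv_term("region"), list(feature_range(1L, 10L))))
                  else list()))
    interaction(parts, interaction_type = types[[sample.int(3L, 1L)]],
                is_negative = runif(1) < 0.2,
                annotations = if (runif(1) < 0.3) list(annotation(cv_term("comment"), "x"))
                else list())
  }
  for (rep in seq_len(1000L)) {
    a <- mk(); b <- if (runif(1) < 0.5) a else mk()
    if (semantic_equals(a, b, "exact")) expect_true(semantic_equals(a, b, "default"))
    if (semantic_equals(a, b, "default")) expect_true(semantic_equals(a, b, "identity"))
  }
})
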