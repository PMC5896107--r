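test_that("configuration is validated", {
  expect_error(generator_config(p_feature = 1.5), class = "mi_config_error")
  expect_error(generator_config(arity_distribution = c("2" = 0.5)), class = "mi_config_error")
  expect_error(generator_config(arity_distribution = c(a = 1.0)), class = "mi_config_error")
  expect_error(generate_network(list()), class = "mi_config_error")
})

test_that("identical config and seed give byte-identical serializations", {
  cfg <- cfg_full(12L, n = 8L)
  a <- generate_network(cfg); b <- generate_network(cfg)
  expect_identical(write_psimi_xml(a$entry_set), write_psimi_xml(b$entry_set))
  expect_identical(
    write_mitab(expand_interactions(net_interactions(a), method = "matrix"), "2.7"),
    write_mitab(expand_interactions(net_interactions(b), method = "matrix"), "2.7"))
  expect_identical(a$sidecar, b$sidecar)
  # a different seed gives a different network
  c <- generate_network(cfg_full(13L, n = 8L))
  expect_false(identical(write_psimi_xml(a$entry_set), write_psimi_xml(c$entry_set)))
  # the generator must not disturb the caller's RNG stream
  set.seed(99L); before <- runif(1L)
  set.seed(99L); invisible(generate_network(cfg)); after <- runif(1L)
  expect_identical(before, after)
})

test_that("a degenerate arity distribution gives only native binaries", {
  net <- generate_network(generator_config(arity_distribution = c("2" = 1.0),
                                           n_interactions = 15L, seed = 4L))
  expect_true(all(vapply(net_interactions(net), arity, integer(1L)) == 2L))
  expect_equal(net$sidecar$matrix_rows, 15L)
})

test_that("sidecar arithmetic predicts expansion counts exactly", {
  cfg <- generator_config(n_interactions = 50L, n_interactors = 25L,
                          arity_distribution = c("2" = 0.5, "4" = 0.5), seed = 21L)
  net <- generate_network(cfg)
  side <- net$sidecar$interactions
  expect_equal(nrow(side), 50L)
  mx <- expand_interactions(net_interactions(net), method = "matrix")
  expect_length(mx, sum(side$arity * (side$arity - 1L) / 2L))
  expect_length(mx, net$sidecar$matrix_rows)
  sp <- expand_interactions(net_interactions(net), method = "spoke",
                            spoke_fallback = "skip")
  expect_length(sp, net$sidecar$spoke_rows)
  # arity histogram in the sidecar matches the objects
  expect_equal(as.vector(table(vapply(net_interactions(net), arity, integer(1L)))),
               as.vector(table(side$arity)))
})

test_that("generator output is clean under the packaged ontology and rules", {
  net <- generate_network(cfg_full(30L, n = 10L))
  expect_equal(nrow(check_cv_usage(net_interactions(net))), 0L)
})
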