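# Shared builders for test fixtures, all constructed in code.

h_interactor <- function(id, db = "uniprotkb", ...) {
  interactor(xref(cv_term(db), id), ...)
}

h_participant <- function(id, experimental_role = NULL, ...) {
  participant(h_interactor(id), experimental_role = experimental_role, ...)
}

bait_cv <- function() cv_term("bait", mi_identifier = "MI:0496")
prey_cv <- function() cv_term("prey", mi_identifier = "MI:0498")

# n-ary interaction over ids P1..Pn; first participant is the bait when asked
h_nary <- function(n, with_bait = TRUE, id = "i1", ...) {
  parts <- lapply(seq_len(n), function(k)
    h_participant(paste0("P", k),
                  experimental_role = if (!with_bait) NULL
                  else if (k == 1L) bait_cv() else prey_cv()))
  interaction(parts, id = id, ...)
}

# unordered participant id pair of a binary interaction, as "a+b" with a <= b
pair_key <- function(b) {
  ids <- sort(vapply(b$participants, function(p) p$interactor$preferred_id$identifier,
                     character(1L)))
  paste(ids, collapse = "+")
}

# brute-force enumeration of all unordered id pairs of an n-ary interaction
brute_force_pairs <- function(i) {
  ids <- vapply(i$participants, function(p) p$interactor$preferred_id$identifier,
                character(1L))
  out <- character(0L)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b) out <- c(out, paste(sort(c(ids[[a]], ids[[b]])), collapse = "+"))
  }
  sort(out)
}

# generator configs expressible per MITAB dialect (fields a dialect cannot
# carry are switched off so exact round trips are meaningful)
cfg_mitab25 <- function(seed, n = 6L) generator_config(
  n_interactors = 10L, n_interactions = n, arity_distribution = c("2" = 1.0),
  p_bait_present = 0, p_feature = 0, p_negative = 0, p_stoichiometry = 0,
  p_annotation = 0, seed = seed)

cfg_mitab26 <- function(seed, n = 6L) generator_config(
  n_interactors = 10L, n_interactions = n, arity_distribution = c("2" = 1.0),
  p_feature = 0, p_stoichiometry = 0, seed = seed)

cfg_full <- function(seed, n = 6L, ...) generator_config(
  n_interactors = 10L, n_interactions = n, seed = seed, ...)

net_interactions <- function(net) net$entry_set$entries[[1L]]$interactions

all_equal_at <- function(xs, ys, stringency) {
  length(xs) == length(ys) &&
    all(mapply(function(a, b) semantic_equals(a, b, stringency), xs, ys))
}
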