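# Spoke and matrix expansion: convert n-ary interactions into binary
# interactions, the view most downstream tools require. The hub of a spoke
# expansion is the unique bait participant; matrix expansion enumerates all
# unordered pairs. Natively binary records (arity <= 2) pass through
# untagged; true expansion products carry the expansion method CV term.

SPOKE_CV <- function() cv_term("spoke expansion", mi_identifier = "MI:1060")
MATRIX_CV <- function() cv_term("matrix expansion", mi_identifier = "MI:1061")

is_bait <- function(p) {
  r <- p$experimental_role
  if (is.null(r)) return(FALSE)
  identical(r$mi_identifier, "MI:0496") || tolower(r$short_name) == "bait"
}

expansion_id <- function(i, k) if (is.null(i$id)) NULL else paste0(i$id, ".", k)

#' Spoke expansion of an n-ary interaction
#'
#' The hub is the unique participant with experimental role "bait"
#' (case-insensitive short name, or MI:0496). The result is one bait--prey
#' binary per non-hub participant, each tagged with the "spoke expansion"
#' CV term (MI:1060) and inheriting all interaction-level fields. An
#' arity-2 interaction is returned as the single untagged pair (natively
#' binary); arity 1 yields one untagged self-interaction.
#'
#' When the bait is missing or not unique, `fallback = "error"` raises an
#' ambiguous-hub error, while `fallback = "first_participant"` takes the
#' participant with the lexicographically smallest preferred identifier as
#' the hub and records the choice in `attr(result, "hub_fallback")`.
#'
#' @param i An [interaction()].
#' @param fallback `"error"` or `"first_participant"`.
#' @return A list of [binary_interaction()].
#' @export
spoke_expand <- function(i, fallback = c("error", "first_participant")) {
  fallback <- match.arg(fallback)
  if (!inherits(i, "mi_interaction")) mi_stop("mi_invalid", "i must be an mi_interaction")
  n <- arity(i)
  if (n == 1L) return(list(as_binary(i, i$participants[[1L]], i$participants[[1L]])))
  if (n == 2L) return(list(as_binary(i, i$participants[[1L]], i$participants[[2L]])))
  baits <- which(vapply(i$participants, is_bait, logical(1L)))
  fallback_note <- NULL
  if (length(baits) == 1L) {
    hub <- baits
  } else if (fallback == "error") {
    mi_stop("mi_ambiguous_hub",
            sprintf("spoke expansion needs exactly one bait; found %d in interaction %s",
                    length(baits), i$id %||% "<unnamed>"),
            n_baits = length(baits))
  } else {
    keys <- vapply(i$participants, function(p) xref_key(p$interactor$preferred_id),
                   character(1L))
    hub <- which(keys == min(keys))[[1L]]
    fallback_note <- sprintf("no unique bait (%d found); hub fixed to first participant %s",
                             length(baits), keys[[hub]])
  }
  preys <- setdiff(seq_len(n), hub)
  out <- lapply(seq_along(preys), function(k)
    as_binary(i, i$participants[[hub]], i$participants[[preys[[k]]]],
              complex_expansion = SPOKE_CV(), id = expansion_id(i, k)))
  if (!is.null(fallback_note)) attr(out, "hub_fallback") <- fallback_note
  out
}

#' Matrix expansion of an n-ary interaction
#'
#' One binary per unordered participant pair: `n(n-1)/2` results for arity
#' `n >= 2`, each tagged with the "matrix expansion" CV term (MI:1061).
#' An arity-2 interaction is the single untagged pair; arity 1 yields one
#' untagged self-interaction.
#'
#' @param i An [interaction()].
#' @return A list of [binary_interaction()].
#' @export
matrix_expand <- function(i) {
  if (!inherits(i, "mi_interaction")) mi_stop("mi_invalid", "i must be an mi_interaction")
  n <- arity(i)
  if (n == 1L) return(list(as_binary(i, i$participants[[1L]], i$participants[[1L]])))
  if (n == 2L) return(list(as_binary(i, i$participants[[1L]], i$participants[[2L]])))
  pairs <- utils::combn(n, 2L)
  lapply(seq_len(ncol(pairs)), function(k)
    as_binary(i, i$participants[[pairs[1L, k]]], i$participants[[pairs[2L, k]]],
              complex_expansion = MATRIX_CV(), id = expansion_id(i, k)))
}

#' Expand a list of interactions for a binary-only target
#'
#' Applies [spoke_expand()] or [matrix_expand()] to every n-ary record and
#' passes natively binary records (arity <= 2) through untouched. With
#' `method = "none"` any n-ary input is a capability error. Under spoke
#' expansion, `spoke_fallback = "skip"` drops records lacking an
#' unambiguous bait and collects a report entry per skipped record (so a
#' conversion's spoke row count runs over hub-bearing interactions only);
#' `"first_participant"` keeps them with a deterministic hub;
#' `"error"` fails.
#'
#' @param interactions List of [interaction()].
#' @param method `"none"`, `"spoke"` or `"matrix"`.
#' @param spoke_fallback `"skip"`, `"error"` or `"first_participant"`.
#' @return A list of [binary_interaction()] (class `mi_binary_list`) with a
#'   [parse_report()]-style report attribute.
#' @export
expand_interactions <- function(interactions, method = c("none", "spoke", "matrix"),
                                spoke_fallback = c("skip", "error", "first_participant")) {
  method <- match.arg(method); spoke_fallback <- match.arg(spoke_fallback)
  out <- list(); report <- empty_report()
  for (k in seq_along(interactions)) {
    i <- interactions[[k]]
    if (inherits(i, "mi_binary_interaction")) { out <- c(out, list(i)); next }
    if (arity(i) <= 2L) {  # natively binary (or self): untagged pass-through
      out <- c(out, spoke_expand(i, fallback = "first_participant")); next
    }
    if (method == "none")
      mi_stop("mi_capability_error",
              sprintf("interaction %s has %d participants; a binary-only target needs --expansion spoke or matrix",
                      i$id %||% as.character(k), arity(i)))
    if (method == "matrix") {
      out <- c(out, matrix_expand(i))
    } else {
      res <- tryCatch(
        spoke_expand(i, fallback = if (spoke_fallback == "skip") "error" else spoke_fallback),
        mi_ambiguous_hub = function(e) e)
      if (inherits(res, "condition")) {
        report <- report_add(report, k, "ambiguous-hub-skipped", conditionMessage(res))
      } else {
        if (!is.null(attr(res, "hub_fallback")))
          report <- report_add(report, k, "hub-fallback", attr(res, "hub_fallback"))
        out <- c(out, res)
      }
    }
  }
  structure(out, class = "mi_binary_list", report = report)
}
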