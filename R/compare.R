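# Semantic comparison of interactions at three stringency levels, built on
# canonical signature strings. Equality of signatures is automatically
# reflexive, symmetric, transitive and order-insensitive, which is exactly
# the contract: files are ordered, semantics are not.
#
#   identity  participant interactor preferred_ids as an unordered multiset
#   default   + interaction_type, is_negative, biological/experimental roles
#   exact     + features, stoichiometry, confidences, annotations

xref_key <- function(x) paste0(tolower(x$database$short_name), ":", x$identifier)

cv_key <- function(t) {
  if (is.null(t)) return("")
  t$mi_identifier %||% tolower(t$short_name)
}

range_key <- function(r) {
  pos <- function(p) if (is.na(p)) "?" else as.character(p)
  sprintf("%s..%s[%s,%s]%s", pos(r$start), pos(r$end),
          cv_key(r$start_status), cv_key(r$end_status), if (r$is_link) "L" else "")
}

feature_key <- function(f) {
  sprintf("%s{%s}", cv_key(f$feature_type),
          paste(sort(vapply(f$ranges, range_key, character(1L))), collapse = ","))
}

annotation_key <- function(a) paste0(cv_key(a$topic), "=", a$value %||% "")
confidence_key <- function(cf) paste0(cv_key(cf$type), "=", cf$value)

stoich_key <- function(s) {
  if (is.null(s)) "" else sprintf("%d..%d", s$min_value, s$max_value)
}

participant_key <- function(p, stringency) {
  key <- xref_key(p$interactor$preferred_id)
  if (stringency %in% c("default", "exact"))
    key <- paste0(key, "|bio=", cv_key(p$biological_role),
                  "|exp=", cv_key(p$experimental_role))
  if (stringency == "exact")
    key <- paste0(key, "|ft=", paste(sort(vapply(p$features, feature_key, character(1L))), collapse = ";"),
                  "|st=", stoich_key(p$stoichiometry))
  key
}

interaction_signature <- function(x, stringency) {
  parts <- sort(vapply(x$participants, participant_key, character(1L),
                       stringency = stringency))
  sig <- paste(parts, collapse = " // ")
  if (stringency %in% c("default", "exact"))
    sig <- paste0(sig, " || type=", cv_key(x$interaction_type),
                  " neg=", x$is_negative)
  if (stringency == "exact")
    sig <- paste0(sig,
                  " conf=", paste(sort(vapply(x$confidences, confidence_key, character(1L))), collapse = ";"),
                  " ann=", paste(sort(vapply(x$annotations, annotation_key, character(1L))), collapse = ";"))
  sig
}

#' Compare two interactions semantically
#'
#' Order-insensitive comparison at one of three stringency levels:
#' `"identity"` compares only the participants' interactor preferred
#' identifiers as an unordered multiset; `"default"` adds the interaction
#' type, the negative flag and participant roles; `"exact"` further adds
#' features, stoichiometry, confidences and annotations. The levels nest:
#' exact equality implies default equality implies identity equality.
#'
#' @param a,b [interaction()] objects (binary or n-ary).
#' @param stringency One of `"identity"`, `"default"`, `"exact"`.
#' @return Logical scalar.
#' @examples
#' p <- function(id) participant(interactor(xref("uniprotkb", id)))
#' x <- interaction(list(p("P1"), p("P2")), interaction_type = cv_term("association"))
#' y <- interaction(list(p("P2"), p("P1")))
#' semantic_equals(x, y, "identity")  # TRUE: same molecules
#' semantic_equals(x, y, "default")   # FALSE: type differs
#' @export
semantic_equals <- function(a, b, stringency = c("default", "identity", "exact")) {
  if (!is.character(stringency) || !all(stringency %in% c("default", "identity", "exact")))
    mi_stop("mi_invalid", "unknown stringency: must be one of identity, default, exact")
  stringency <- stringency[[1L]]
  for (x in list(a, b))
    if (!inherits(x, "mi_interaction"))
      mi_stop("mi_invalid", "semantic_equals compares mi_interaction objects")
  identical(interaction_signature(a, stringency), interaction_signature(b, stringency))
}

#' Fill in default controlled-vocabulary terms
#'
#' Fills a missing participant biological role with "unspecified role"
#' (MI:0499) and a missing experiment detection method with "unspecified
#' method" (MI:0686). Idempotent; all other fields pass through untouched.
#' The model constructors already apply these defaults, so this matters for
#' records assembled field-by-field (e.g. by readers of sparse dialects).
#'
#' @param i An [interaction()].
#' @return The interaction with defaults applied.
#' @export
apply_defaults <- function(i) {
  if (!inherits(i, "mi_interaction")) mi_stop("mi_invalid", "i must be an mi_interaction")
  i$participants <- lapply(i$participants, function(p) {
    p$biological_role <- p$biological_role %||% cv_term("unspecified role", mi_identifier = "MI:0499")
    p
  })
  if (!is.null(i$experiment))
    i$experiment$detection_method <- i$experiment$detection_method %||%
      cv_term("unspecified method", mi_identifier = "MI:0686")
  i
}
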