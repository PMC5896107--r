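# MI-JSON: the write-only JSON dialect served to JavaScript visualisation
# clients. The document is a flat "data" array of interactor objects
# followed by interaction objects referencing them; each distinct
# interactor appears exactly once. The dialect is defined by the packaged
# schema file (inst/extdata/mi-json-schema.json), which is the contract
# this writer and the conformance checker implement.

interactor_json <- function(x) {
  obj <- list(
    object = "interactor",
    id = xref_key(x$preferred_id),
    label = if (length(x$aliases)) x$aliases[[1L]]$name else x$preferred_id$identifier,
    type = x$interactor_type$short_name)
  if (!is.null(x$organism))
    obj$organism <- list(taxid = x$organism$taxid,
                         name = x$organism$common_name %||%
                           x$organism$scientific_name %||% as.character(x$organism$taxid))
  if (!is.null(x$sequence)) obj$sequence <- x$sequence
  obj
}

participant_json <- function(p) {
  obj <- list(id = xref_key(p$interactor$preferred_id))
  if (!is.null(p$biological_role)) obj$biologicalRole <- p$biological_role$short_name
  if (!is.null(p$experimental_role)) obj$experimentalRole <- p$experimental_role$short_name
  if (length(p$features))
    obj$features <- lapply(p$features, function(f) list(
      type = if (!is.null(f$feature_type)) f$feature_type$short_name else "unknown",
      ranges = vapply(f$ranges, range_to_string, character(1L))))
  if (!is.null(p$stoichiometry)) obj$stoichiometry <- p$stoichiometry$min_value
  obj
}

interaction_json <- function(b, k) {
  obj <- list(
    object = "interaction",
    id = b$id %||% as.character(k),
    interactorA = participant_json(b$participants[[1L]]),
    interactorB = participant_json(b$participants[[2L]]))
  if (!is.null(b$interaction_type)) obj$interactionType <- b$interaction_type$short_name
  if (!is.null(b$experiment)) {
    obj$detectionMethod <- b$experiment$detection_method$short_name
    pub <- b$experiment$publication
    if (!is.null(pub) && !is.null(pub$pubmed_id))
      obj$sourceIds <- list(paste0("pubmed:", pub$pubmed_id))
  }
  if (length(b$confidences))
    obj$confidences <- vapply(b$confidences, function(cf)
      paste0(cf$type$short_name, ":", cf$value), character(1L))
  if (!is.null(b$complex_expansion)) obj$expansion <- b$complex_expansion$short_name
  if (b$is_negative) obj$negative <- TRUE
  obj
}

#' Write binary interactions as MI-JSON
#'
#' Produces the write-only JSON document consumed by viewer applications:
#' a `data` array holding each distinct interactor exactly once (sorted by
#' preferred identifier), followed by one interaction object per input
#' record in input order, with feature ranges serialized as
#' `"start-end"` strings. Output is deterministic and conforms to the
#' packaged schema (see [mijson_schema_path()] and [mijson_conforms()]).
#'
#' @param interactions List of [binary_interaction()] (may be empty).
#' @param path Optional output file; when `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when `path` is given).
#' @export
write_mijson <- function(interactions, path = NULL) {
  interactions <- as_binary_list(interactions)
  ints <- unlist(lapply(interactions, function(b)
    lapply(b$participants, `[[`, "interactor")), recursive = FALSE)
  keys <- vapply(ints, function(x) xref_key(x$preferred_id), character(1L))
  uniq <- ints[!duplicated(keys)]
  uniq <- uniq[order(vapply(uniq, function(x) xref_key(x$preferred_id), character(1L)),
                     method = "radix")]
  data <- c(lapply(uniq, interactor_json),
            lapply(seq_along(interactions), function(k)
              interaction_json(interactions[[k]], k)))
  doc <- list(format = "mi-json", version = "1.0", data = data)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path, useBytes = TRUE)
  invisible(as.character(txt))
}

#' @rdname write_mijson
#' @return `mijson_schema_path()` returns the path of the packaged schema file.
#' @export
mijson_schema_path <- function() {
  system.file("extdata", "mi-json-schema.json", package = "rpsimi", mustWork = TRUE)
}

#' Check a document against the packaged MI-JSON contract
#'
#' Implements exactly the packaged schema: a top-level `data` array whose
#' members are labelled `"interactor"` or `"interaction"`, required fields
#' per object kind, every participant reference resolving to an interactor
#' object in the same document, and each distinct interactor appearing
#' exactly once.
#'
#' @param json MI-JSON text (or a parsed list).
#' @return Character vector of violations; empty when conformant.
#' @export
mijson_conforms <- function(json) {
  doc <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE) else json
  bad <- character(0L)
  if (!is.list(doc) || is.null(doc$data)) return("document has no 'data' array")
  interactor_ids <- character(0L)
  for (k in seq_along(doc$data)) {
    obj <- doc$data[[k]]
    kind <- obj$object
    if (is.null(kind) || !kind %in% c("interactor", "interaction")) {
      bad <- c(bad, sprintf("data[%d]: missing or unknown 'object' label", k)); next
    }
    if (kind == "interactor") {
      for (fld in c("id", "label", "type"))
        if (is.null(obj[[fld]]))
          bad <- c(bad, sprintf("data[%d]: interactor lacks '%s'", k, fld))
      if (!is.null(obj$id)) {
        if (obj$id %in% interactor_ids)
          bad <- c(bad, sprintf("data[%d]: duplicate interactor '%s'", k, obj$id))
        interactor_ids <- c(interactor_ids, obj$id)
      }
    } else {
      for (fld in c("id", "interactorA", "interactorB"))
        if (is.null(obj[[fld]]))
          bad <- c(bad, sprintf("data[%d]: interaction lacks '%s'", k, fld))
      for (side in c("interactorA", "interactorB")) {
        ref <- obj[[side]]$id
        if (!is.null(ref) && !ref %in% interactor_ids)
          bad <- c(bad, sprintf("data[%d]: %s '%s' does not resolve to an interactor object",
                                k, side, ref))
      }
    }
  }
  bad
}

#' Reading MI-JSON is not supported
#'
#' MI-JSON is a write-only dialect in the support matrix; any attempt to
#' read it raises a capability error. This mirrors the registry rule that
#' the descriptor (mi-json, read) is invalid.
#'
#' @param x Ignored.
#' @return Never returns.
#' @export
read_mijson_attempt <- function(x) {
  mi_stop("mi_capability_error", "MI-JSON is write-only: the (mi-json, read) direction is not supported")
}
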