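# Minimal OBO ontology support: [Term] stanzas with id, name and is_a are
# all the controlled-vocabulary machinery needs (the MI ontology uses is_a
# for the slots validated here; part_of is deliberately ignored). No OBO
# parser ships with this R environment, so the subset is implemented here.

#' Load an ontology from an OBO file
#'
#' Parses `[Term]` stanzas, keeping the accession (`id`), `name`, `is_a`
#' parents and the obsolete flag. This is sufficient for term lookup and
#' transitive is_a closure, the two operations validation and CV
#' enrichment need.
#'
#' @param path Path to an OBO file.
#' @return An object of class `mi_ontology`: a named list of terms, each
#'   `list(id, name, parents)`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path))
    mi_stop("mi_config_error", sprintf("ontology file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete))
      terms[[cur$id]] <- cur
    terms
  }
  for (line in lines) {
    line <- trimws(sub("!.*$", "", line))
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NULL, parents = character(0L), obsolete = FALSE)
    } else if (startsWith(line, "[")) {        # [Typedef] etc.: end current term
      terms <- flush(cur, terms)
      cur <- NULL
    } else if (!is.null(cur) && grepl(":", line)) {
      key <- sub(":.*$", "", line)
      value <- trimws(sub("^[^:]+:", "", line))
      if (key == "id") cur$id <- value
      else if (key == "name") cur$name <- value
      else if (key == "is_a") cur$parents <- c(cur$parents, sub("\\s.*$", "", value))
      else if (key == "is_obsolete" && value == "true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  structure(terms, class = "mi_ontology")
}

#' @export
print.mi_ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms\n", length(x)))
  invisible(x)
}

obo_has <- function(ontology, id) !is.null(ontology[[id]])

#' Transitive is_a ancestry
#'
#' @param ontology An `mi_ontology` from [read_obo()].
#' @param id A term accession.
#' @param ancestor Candidate ancestor accession.
#' @return `obo_ancestors()` returns all accessions reachable through
#'   `is_a` (including `id` itself); `obo_is_descendant()` tests membership
#'   of `ancestor` in that closure.
#' @export
obo_ancestors <- function(ontology, id) {
  seen <- character(0L); queue <- id
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    t <- ontology[[cur]]
    if (!is.null(t)) queue <- c(queue, t$parents)
  }
  seen
}

#' @rdname obo_ancestors
#' @export
obo_is_descendant <- function(ontology, id, ancestor) {
  ancestor %in% obo_ancestors(ontology, id)
}

#' Path of the packaged mini MI ontology
#'
#' A ~50-term OBO file mirroring the structure of the PSI-MI controlled
#' vocabulary (roots for detection method, interaction type, biological and
#' experimental roles, interactor types, expansion methods, feature
#' machinery). It is the single CV source for the synthetic generator and
#' the validator, keeping every test hermetic.
#'
#' @return File path.
#' @export
mini_obo_path <- function() {
  system.file("extdata", "mi-mini.obo", package = "rpsimi", mustWork = TRUE)
}
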