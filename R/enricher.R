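# Enrichment: fill sparsely annotated interactors and CV terms from
# pluggable fetchers. The fetcher is an abstraction boundary — a pure
# lookup from identifier to record with no side effects on the model — so
# enrichment policy is independent of where records come from. The shipped
# fetchers are file-backed (a TSV table for molecules, an OBO graph for CV
# terms); live web-service clients are deliberately out of scope.

#' Construct a file-backed molecule fetcher
#'
#' Reads a TSV table with header columns `id`, `name`, `taxid`,
#' `organism_name`, `sequence`, `aliases`, `xrefs` (aliases `;`-separated;
#' xrefs `;`-separated `db:id` pairs; empty cells for missing values) and
#' returns a fetcher whose lookups yield enrichment records.
#'
#' @param path Path to the TSV table.
#' @return An object of class `mi_fetcher`.
#' @export
tsv_fetcher <- function(path) {
  if (!file.exists(path))
    mi_stop("mi_config_error", sprintf("fetcher table '%s' is unreadable", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("id", "name", "taxid", "organism_name", "sequence", "aliases", "xrefs")
  if (!all(needed %in% names(tab)))
    mi_stop("mi_config_error",
            sprintf("fetcher table lacks columns: %s",
                    paste(setdiff(needed, names(tab)), collapse = ", ")))
  rows <- split(tab, seq_len(nrow(tab)))
  names(rows) <- tab$id
  lookup <- function(identifier) {
    row <- rows[[identifier]]
    if (is.null(row)) return(NULL)
    nz <- function(s) if (is.na(s) || !nzchar(s)) NULL else s
    org <- if (!is.null(nz(row$taxid)))
      organism(as.integer(row$taxid), common_name = nz(row$organism_name))
    else NULL
    aliases <- if (!is.null(nz(row$aliases)))
      lapply(strsplit(row$aliases, ";", fixed = TRUE)[[1L]], mi_alias)
    else list()
    xrefs <- if (!is.null(nz(row$xrefs)))
      lapply(strsplit(row$xrefs, ";", fixed = TRUE)[[1L]], function(s) {
        parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
        xref(cv_term(parts[[1L]]), paste(parts[-1L], collapse = ":"))
      })
    else list()
    fetcher_record(identifier, full_name = nz(row$name), organism = org,
                   sequence = nz(row$sequence), aliases = aliases, xrefs = xrefs)
  }
  structure(list(lookup = lookup, source = path), class = "mi_fetcher")
}

#' Enrichment record returned by a fetcher
#'
#' @param identifier Non-empty identifier the record answers for.
#' @param full_name,sequence Optional scalars.
#' @param organism Optional [organism()].
#' @param aliases,xrefs Lists of [mi_alias()] / [xref()].
#' @return An object of class `mi_fetcher_record`.
#' @export
fetcher_record <- function(identifier, full_name = NULL, organism = NULL,
                           sequence = NULL, aliases = list(), xrefs = list()) {
  chr1(identifier, "identifier")
  structure(list(identifier = identifier, full_name = full_name,
                 organism = organism, sequence = sequence,
                 aliases = assert_list_of(aliases, "mi_alias", "aliases"),
                 xrefs = assert_list_of(xrefs, "mi_xref", "xrefs")),
            class = c("mi_fetcher_record", "mi_object"))
}

#' Look up an identifier through a fetcher
#'
#' @param fetcher An `mi_fetcher` (see [tsv_fetcher()], [obo_cv_fetcher()]).
#' @param identifier Identifier to resolve.
#' @return The fetched record, or `NULL` when the id is unknown.
#' @export
fetch <- function(fetcher, identifier) {
  if (!inherits(fetcher, "mi_fetcher"))
    mi_stop("mi_config_error", "fetcher does not implement the fetcher contract")
  fetcher$lookup(identifier)
}

#' Construct an ontology-backed CV term fetcher
#'
#' Resolves `MI:NNNN` accessions (or exact term names) against an OBO
#' graph loaded with [read_obo()].
#'
#' @param ontology An `mi_ontology` or a path to an OBO file.
#' @return An object of class `mi_fetcher`.
#' @export
obo_cv_fetcher <- function(ontology = mini_obo_path()) {
  if (is.character(ontology)) ontology <- read_obo(ontology)
  if (!inherits(ontology, "mi_ontology"))
    mi_stop("mi_config_error", "ontology must be an mi_ontology or an OBO file path")
  by_name <- stats::setNames(names(ontology),
                             tolower(vapply(ontology, function(t) t$name %||% "", character(1L))))
  lookup <- function(identifier) {
    t <- ontology[[identifier]]
    if (is.null(t)) {
      hit <- unname(by_name[tolower(identifier)])
      if (is.na(hit)) return(NULL)
      t <- ontology[[hit]]
    }
    fetcher_record(t$id, full_name = t$name)
  }
  structure(list(lookup = lookup, source = "obo"), class = "mi_fetcher")
}

enrichment_report <- function(filled = character(0L), conflicts = NULL,
                              misses = character(0L)) {
  structure(list(
    fields_filled = filled,
    conflicts = conflicts %||% data.frame(field = character(0L), existing = character(0L),
                                          fetched = character(0L), stringsAsFactors = FALSE),
    misses = misses), class = "mi_enrichment_report")
}

#' @export
print.mi_enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment report> filled: %s | conflicts: %d | misses: %s\n",
              if (length(x$fields_filled)) paste(x$fields_filled, collapse = ", ") else "none",
              nrow(x$conflicts),
              if (length(x$misses)) paste(x$misses, collapse = ", ") else "none"))
  invisible(x)
}

#' Enrich an interactor from a fetcher
#'
#' Looks the interactor's preferred identifier up through the fetcher and
#' fills in what the record offers. Under `policy = "fill_only"` only
#' absent scalar fields (full name, organism, sequence) are set and a
#' differing fetched value is recorded as a conflict, never applied; under
#' `"overwrite"` mismatching scalars are replaced, with each replacement
#' recorded as a conflict entry. List fields (aliases, xrefs) are merged
#' set-wise under both policies. Enrichment never removes information and
#' is idempotent at fixed fetcher and policy.
#'
#' @param x An [interactor()].
#' @param fetcher An `mi_fetcher`.
#' @param policy `"fill_only"` or `"overwrite"`.
#' @return `list(interactor = enriched interactor, report = enrichment report)`.
#' @export
enrich_interactor <- function(x, fetcher, policy = c("fill_only", "overwrite")) {
  policy <- match.arg(policy)
  if (!inherits(x, "mi_interactor")) mi_stop("mi_invalid", "x must be an mi_interactor")
  id <- x$preferred_id$identifier
  rec <- fetch(fetcher, id)
  if (is.null(rec))
    return(list(interactor = x, report = enrichment_report(misses = id)))

  filled <- character(0L)
  conflicts <- data.frame(field = character(0L), existing = character(0L),
                          fetched = character(0L), stringsAsFactors = FALSE)
  set_scalar <- function(field, existing, fetched, existing_str, fetched_str) {
    if (is.null(fetched)) return(existing)
    if (is.null(existing)) {
      filled <<- c(filled, field)
      return(fetched)
    }
    if (!identical(existing_str, fetched_str)) {
      conflicts <<- rbind(conflicts, data.frame(field = field, existing = existing_str,
                                                fetched = fetched_str,
                                                stringsAsFactors = FALSE))
      if (policy == "overwrite") return(fetched)
    }
    existing
  }
  x$full_name <- set_scalar("full_name", x$full_name, rec$full_name,
                            x$full_name %||% "", rec$full_name %||% "")
  x$organism <- set_scalar("organism", x$organism, rec$organism,
                           if (is.null(x$organism)) "" else as.character(x$organism$taxid),
                           if (is.null(rec$organism)) "" else as.character(rec$organism$taxid))
  x$sequence <- set_scalar("sequence", x$sequence, rec$sequence,
                           x$sequence %||% "", rec$sequence %||% "")

  merge_list <- function(field, existing, fetched, key_fun) {
    if (length(fetched) == 0L) return(existing)
    keys <- vapply(existing, key_fun, character(1L))
    added <- FALSE
    for (item in fetched) {
      if (!key_fun(item) %in% keys) {
        existing <- c(existing, list(item)); keys <- c(keys, key_fun(item)); added <- TRUE
      }
    }
    if (added) filled <<- c(filled, field)
    existing
  }
  x$aliases <- merge_list("aliases", x$aliases, rec$aliases,
                          function(a) paste0(a$name, "/", cv_key(a$alias_type)))
  x$xrefs <- merge_list("xrefs", x$xrefs, rec$xrefs, xref_key)

  list(interactor = x, report = enrichment_report(filled, conflicts))
}

#' Enrich a CV term from an ontology fetcher
#'
#' Resolves the term through its `MI:NNNN` accession (or, failing that, its
#' short name) and fills the full name and the canonical short name from
#' the ontology; a term resolved by name also gains its accession.
#' Idempotent; unknown terms are reported as misses, never raised.
#'
#' @param t A [cv_term()].
#' @param ontology_fetcher An `mi_fetcher` from [obo_cv_fetcher()].
#' @return `list(term = enriched term, report = enrichment report)`.
#' @export
enrich_cvterm <- function(t, ontology_fetcher) {
  if (!inherits(t, "mi_cv_term")) mi_stop("mi_invalid", "t must be a cv_term")
  key <- t$mi_identifier %||% t$short_name
  rec <- fetch(ontology_fetcher, key)
  if (is.null(rec))
    return(list(term = t, report = enrichment_report(misses = key)))
  filled <- character(0L)
  if (is.null(t$mi_identifier) && grepl("^MI:[0-9]{4}$", rec$identifier)) {
    t$mi_identifier <- rec$identifier; filled <- c(filled, "mi_identifier")
  }
  if (is.null(t$full_name) && !is.null(rec$full_name)) {
    t$full_name <- rec$full_name; filled <- c(filled, "full_name")
  }
  if (!is.null(rec$full_name) && !identical(t$short_name, rec$full_name)) {
    t$short_name <- rec$full_name   # canonical name from the ontology
    filled <- c(filled, "short_name")
  }
  list(term = t, report = enrichment_report(filled))
}
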