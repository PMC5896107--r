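# Structural + CV-usage validation: a reduced re-implementation of the
# semantic validator's behaviour. Syntax checking reuses the readers'
# parse reports; CV-usage checking tests, for each rule, that a term
# exists in the ontology and sits under the required ancestor in the
# transitive is_a closure. The rule set is data (a packaged TSV), not
# code: the full HUPO rule catalogue is out of scope but the mechanism is
# general.

#' Load CV-usage validation rules
#'
#' A rule table is a TSV with columns `location` (a model slot:
#' `experiment.detection_method`, `interaction.interaction_type`,
#' `participant.biological_role`, `participant.experimental_role`,
#' `interactor.interactor_type`, `participant.identification_method`,
#' `feature.feature_type`), `required_ancestor` (an `MI:NNNN` accession)
#' and `severity` (`error` or `warning`).
#'
#' @param path Path to the rule TSV; defaults to the packaged rule set.
#' @return A data frame of class `mi_rule_set`.
#' @export
read_validation_rules <- function(path = default_rules_path()) {
  if (!file.exists(path))
    mi_stop("mi_config_error", sprintf("rule file '%s' does not exist", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("location", "required_ancestor", "severity")
  if (!all(needed %in% names(tab)))
    mi_stop("mi_config_error", "rule table needs columns location, required_ancestor, severity")
  known <- c("experiment.detection_method", "interaction.interaction_type",
             "participant.biological_role", "participant.experimental_role",
             "interactor.interactor_type", "participant.identification_method",
             "feature.feature_type")
  bad <- setdiff(tab$location, known)
  if (length(bad))
    mi_stop("mi_config_error", sprintf("rule locations name no model slot: %s",
                                       paste(bad, collapse = ", ")))
  if (!all(tab$severity %in% c("error", "warning")))
    mi_stop("mi_config_error", "rule severity must be 'error' or 'warning'")
  structure(tab, class = c("mi_rule_set", class(tab)))
}

#' @rdname read_validation_rules
#' @return `default_rules_path()` returns the packaged rule file path.
#' @export
default_rules_path <- function() {
  system.file("extdata", "mi-rules.tsv", package = "rpsimi", mustWork = TRUE)
}

validation_report <- function(entries = NULL) {
  entries <- entries %||% data.frame(
    record = integer(0L), location = character(0L), severity = character(0L),
    type = character(0L), term = character(0L), message = character(0L),
    stringsAsFactors = FALSE)
  structure(entries, class = c("mi_validation_report", "data.frame"))
}

#' @export
print.mi_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation report> clean: no findings\n")
  } else {
    cat(sprintf("<validation report> %d finding%s (%d error%s, %d warning%s)\n",
                nrow(x), if (nrow(x) == 1L) "" else "s",
                sum(x$severity == "error"), if (sum(x$severity == "error") == 1L) "" else "s",
                sum(x$severity == "warning"), if (sum(x$severity == "warning") == 1L) "" else "s"))
    print.data.frame(utils::head(as.data.frame(x), 20L))
  }
  invisible(x)
}

# extract (term, location label) pairs for a rule location from one interaction
rule_terms <- function(i, location) {
  grab <- function(terms) Filter(Negate(is.null), terms)
  switch(location,
    "experiment.detection_method" =
      if (!is.null(i$experiment)) grab(list(i$experiment$detection_method)) else list(),
    "interaction.interaction_type" = grab(list(i$interaction_type)),
    "participant.biological_role" = grab(lapply(i$participants, `[[`, "biological_role")),
    "participant.experimental_role" = grab(lapply(i$participants, `[[`, "experimental_role")),
    "interactor.interactor_type" =
      grab(lapply(i$participants, function(p) p$interactor$interactor_type)),
    "participant.identification_method" =
      grab(unlist(lapply(i$participants, `[[`, "identification_methods"), recursive = FALSE)),
    "feature.feature_type" =
      grab(unlist(lapply(i$participants, function(p)
        lapply(p$features, `[[`, "feature_type")), recursive = FALSE)),
    mi_stop("mi_config_error", sprintf("unknown rule location '%s'", location)))
}

#' Check controlled-vocabulary usage
#'
#' For every rule and every interaction: a term whose accession is missing
#' from the ontology yields a term-not-found error entry; a term present
#' but not a descendant (transitive `is_a` closure) of the rule's required
#' ancestor yields a wrong-location entry at the rule's severity. Terms
#' carrying no `MI:NNNN` accession cannot be checked and are skipped.
#' Entries are ordered by record then rule.
#'
#' @param interactions List of [interaction()] (e.g. from a reader).
#' @param ontology An `mi_ontology` from [read_obo()].
#' @param rules An `mi_rule_set` from [read_validation_rules()].
#' @return An `mi_validation_report` data frame.
#' @export
check_cv_usage <- function(interactions, ontology = read_obo(mini_obo_path()),
                           rules = read_validation_rules()) {
  if (!inherits(ontology, "mi_ontology"))
    mi_stop("mi_config_error", "ontology must be an mi_ontology")
  for (anc in unique(rules$required_ancestor))
    if (!obo_has(ontology, anc))
      mi_stop("mi_config_error",
              sprintf("rule references ancestor %s absent from the ontology", anc))
  rows <- list()
  for (rec in seq_along(interactions)) {
    i <- interactions[[rec]]
    for (r in seq_len(nrow(rules))) {
      loc <- rules$location[[r]]; anc <- rules$required_ancestor[[r]]
      for (t in rule_terms(i, loc)) {
        if (is.null(t$mi_identifier)) next
        if (!obo_has(ontology, t$mi_identifier)) {
          rows <- c(rows, list(data.frame(
            record = rec, location = loc, severity = "error", type = "term-not-found",
            term = t$mi_identifier,
            message = sprintf("term %s (%s) not found in the ontology",
                              t$mi_identifier, t$short_name),
            stringsAsFactors = FALSE)))
        } else if (!obo_is_descendant(ontology, t$mi_identifier, anc)) {
          rows <- c(rows, list(data.frame(
            record = rec, location = loc, severity = rules$severity[[r]],
            type = "wrong-location", term = t$mi_identifier,
            message = sprintf("term %s (%s) is not a descendant of required ancestor %s for %s",
                              t$mi_identifier, t$short_name, anc, loc),
            stringsAsFactors = FALSE)))
        }
      }
    }
  }
  validation_report(if (length(rows)) do.call(rbind, rows) else NULL)
}

sniff_format <- function(path) {
  first <- ""
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- line; break }
  }
  if (grepl("^\\s*<", first)) "psi-xml" else "mitab"
}

#' Check the syntax of an interaction file
#'
#' Reuses the readers' parse reports: for MITAB, column-count and
#' malformed-field entries; for PSI-MI XML, well-formedness, unsupported
#' elements and dangling numeric references. A clean file yields an empty
#' report. All three MITAB dialects and both XML versions are supported.
#'
#' @param path File to check.
#' @param declared_format `"mitab"`, `"psi-xml"` or `NULL` to sniff.
#' @return `list(report, interactions)`: the syntax findings (as an
#'   `mi_validation_report`) and the successfully parsed interactions
#'   (for subsequent CV checking).
#' @export
check_syntax <- function(path, declared_format = NULL) {
  if (!file.exists(path))
    mi_stop("mi_io_error", sprintf("cannot read '%s'", path))
  fmt <- declared_format %||% sniff_format(path)
  if (!fmt %in% c("mitab", "psi-xml"))
    mi_stop("mi_unsupported_dialect", sprintf("unknown format '%s'", fmt))
  if (fmt == "mitab") {
    res <- read_mitab(path)
    rep <- parse_report(res)
    interactions <- res
  } else {
    es <- tryCatch(read_psimi_xml(path, on_error = "report"),
                   mi_syntax_error = function(e) e,
                   mi_unsupported_dialect = function(e) e)
    if (inherits(es, "condition")) {
      return(list(report = validation_report(data.frame(
        record = NA_integer_, location = "document", severity = "error",
        type = "syntax", term = "", message = conditionMessage(es),
        stringsAsFactors = FALSE)), interactions = list()))
    }
    rep <- attr(es, "report") %||% empty_report()
    interactions <- es_interactions(es)
  }
  entries <- if (nrow(rep)) data.frame(
    record = rep$row, location = "document", severity = "error",
    type = rep$type, term = "", message = rep$message, stringsAsFactors = FALSE)
  else NULL
  list(report = validation_report(entries), interactions = interactions)
}

#' Validate a file: syntax plus CV usage
#'
#' Runs [check_syntax()] and, on whatever parsed cleanly, [check_cv_usage()]
#' with the given ontology and rules; findings are concatenated (syntax
#' first, then CV findings ordered by record and rule).
#'
#' @inheritParams check_syntax
#' @inheritParams check_cv_usage
#' @return An `mi_validation_report`.
#' @export
validate_file <- function(path, ontology = read_obo(mini_obo_path()),
                          rules = read_validation_rules(), declared_format = NULL) {
  syn <- check_syntax(path, declared_format)
  cv <- check_cv_usage(syn$interactions, ontology, rules)
  validation_report(rbind(as.data.frame(syn$report), as.data.frame(cv)))
}

#' Serialize a validation report as JSON
#'
#' @param report An `mi_validation_report`.
#' @param path Optional output file.
#' @return JSON text (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  txt <- as.character(jsonlite::toJSON(list(
    findings = as.data.frame(report), n = nrow(report),
    clean = nrow(report) == 0L), auto_unbox = TRUE, pretty = TRUE))
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}
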