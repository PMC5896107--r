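# The format registry and the conversion / validation / statistics front
# end. The registry enforces the support matrix: PSI-MI XML 2.5/3.0 and
# MITAB 2.5/2.6/2.7 read + write; MI-JSON and HTML write-only. Conversion
# is a single read into the abstract model followed by a single write —
# no chained intermediate formats.

#' Format descriptor
#'
#' A (format, version, direction) triple governing what the registry will
#' read or write. The write-only dialects reject the read direction.
#'
#' @param format One of `"mitab"`, `"psi-xml"`, `"mi-json"`, `"html"`.
#' @param version Dialect version where applicable (`"2.5"/"2.6"/"2.7"`
#'   for MITAB, `"2.5"/"3.0"` for XML).
#' @param direction `"read"` or `"write"`.
#' @return An object of class `mi_format_descriptor`.
#' @export
format_descriptor <- function(format, version = NULL, direction = c("read", "write")) {
  direction <- match.arg(direction)
  if (!format %in% c("mitab", "psi-xml", "mi-json", "html"))
    mi_stop("mi_unsupported_dialect", sprintf("unknown format '%s'", format))
  if (format %in% c("mi-json", "html") && direction == "read")
    mi_stop("mi_capability_error",
            sprintf("(%s, read) is not a valid descriptor: %s is write-only", format, format))
  versions <- switch(format, mitab = c("2.5", "2.6", "2.7"),
                     "psi-xml" = c("2.5", "3.0"), NULL)
  if (!is.null(version)) {
    if (is.null(versions) || !version %in% versions)
      mi_stop("mi_unsupported_dialect",
              sprintf("version '%s' is not a %s dialect", version, format))
  }
  structure(list(format = format, version = version, direction = direction),
            class = "mi_format_descriptor")
}

#' The read/write support matrix
#'
#' @return A data frame with columns `format`, `version`, `read`, `write`.
#' @export
format_matrix <- function() {
  data.frame(
    format = c("psi-xml", "psi-xml", "mitab", "mitab", "mitab", "mi-json", "html"),
    version = c("2.5", "3.0", "2.5", "2.6", "2.7", NA, NA),
    read = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    write = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname format_matrix
#' @param format,direction Pair to test.
#' @return `registry_supports()` returns a logical scalar.
#' @export
registry_supports <- function(format, direction) {
  !inherits(tryCatch(format_descriptor(format, direction = direction),
                     mi_error = function(e) e), "condition")
}

FORMAT_CODES <- list(
  mitab25 = list(format = "mitab", version = "2.5"),
  mitab26 = list(format = "mitab", version = "2.6"),
  mitab27 = list(format = "mitab", version = "2.7"),
  xml25 = list(format = "psi-xml", version = "2.5"),
  xml30 = list(format = "psi-xml", version = "3.0"),
  mijson = list(format = "mi-json", version = NULL),
  html = list(format = "html", version = NULL))

resolve_code <- function(code, direction) {
  spec <- FORMAT_CODES[[code]]
  if (is.null(spec))
    mi_stop("mi_unsupported_dialect", sprintf("unknown format code '%s'", code))
  format_descriptor(spec$format, spec$version, direction)
}

# read any supported input into the model; auto-detection: content sniff
# (XML declaration vs tab counts), explicit code always wins
read_any <- function(input, from = "auto") {
  if (!file.exists(input)) mi_stop("mi_io_error", sprintf("cannot read '%s'", input))
  if (from == "auto") {
    fmt <- sniff_format(input)
    desc <- format_descriptor(fmt, direction = "read")
  } else {
    desc <- resolve_code(from, "read")
  }
  if (desc$format == "mitab") {
    res <- read_mitab(input, version = desc$version)
    list(kind = "mitab", interactions = res, entry_set = NULL,
         version = attr(res, "mitab_version"), report = parse_report(res))
  } else {
    es <- read_psimi_xml(input, on_error = "stop")
    if (!is.null(desc$version) && !identical(es$version, desc$version))
      mi_stop("mi_unsupported_dialect",
              sprintf("declared %s but document is version %s", desc$version, es$version))
    list(kind = "psi-xml", interactions = es_interactions(es), entry_set = es,
         version = es$version, report = attr(es, "report") %||% empty_report())
  }
}

#' Convert between interaction formats
#'
#' One read into the abstract model, one write out — never a chain of
#' format-to-format conversions. Binary-only targets (MITAB, MI-JSON)
#' require `expansion` other than `"none"` when the input holds n-ary
#' interactions; with `"spoke"`, records lacking an unambiguous bait are
#' skipped and reported (set `spoke_fallback = "first_participant"` to
#' keep them, or `"error"` to fail).
#'
#' @param input Input file (MITAB or PSI-MI XML).
#' @param to Target code: `"mitab25"`, `"mitab26"`, `"mitab27"`, `"xml25"`,
#'   `"xml30"`, `"mijson"`, `"html"`.
#' @param output Output file; when `NULL` the serialized text is returned
#'   in the result.
#' @param from Source code (as `to`, minus the write-only dialects) or
#'   `"auto"` to sniff.
#' @param expansion `"none"`, `"spoke"` or `"matrix"`.
#' @param spoke_fallback Policy for spoke expansion without a unique bait:
#'   `"skip"`, `"error"` or `"first_participant"`.
#' @param style XML reference style for XML targets.
#' @return Invisibly, `list(status, n_in, n_out, report, output, text)`.
#' @export
mi_convert <- function(input, to, output = NULL, from = "auto",
                       expansion = c("none", "spoke", "matrix"),
                       spoke_fallback = c("skip", "error", "first_participant"),
                       style = c("compact", "expanded")) {
  expansion <- match.arg(expansion); spoke_fallback <- match.arg(spoke_fallback)
  style <- match.arg(style)
  if (from %in% c("mijson", "html"))
    mi_stop("mi_capability_error",
            sprintf("--from %s: %s is write-only (no read support)", from,
                    FORMAT_CODES[[from]]$format))
  target <- resolve_code(to, "write")
  src <- read_any(input, from)
  report <- src$report
  n_in <- length(src$interactions)

  if (target$format %in% c("mitab", "mi-json")) {
    binaries <- expand_interactions(src$interactions, method = expansion,
                                    spoke_fallback = spoke_fallback)
    report <- rbind(report, parse_report(binaries))
    text <- if (target$format == "mitab") write_mitab(binaries, target$version, output)
    else write_mijson(binaries, output)
    n_out <- length(binaries)
  } else if (target$format == "psi-xml") {
    es <- src$entry_set %||% entry_set(list(mi_entry(interactions = src$interactions)),
                                       version = target$version)
    text <- write_psimi_xml(es, version = target$version, style = style, path = output)
    n_out <- n_in
  } else { # html
    text <- write_mi_html(src$interactions, output)
    n_out <- n_in
  }
  invisible(list(status = 0L, n_in = n_in, n_out = n_out, report = report,
                 output = output, text = if (is.null(output)) text else NULL))
}

#' Validate a file from the front end
#'
#' Wraps [validate_file()]: status 0 for a clean file, 3 when there are
#' findings.
#'
#' @param input File to validate.
#' @param obo Path to the ontology OBO file (default: packaged mini ontology).
#' @param rules Path to the rule TSV (default: packaged rules).
#' @param json_path Optional path for a machine-readable JSON report.
#' @return `list(status, report)`.
#' @export
mi_check <- function(input, obo = mini_obo_path(), rules = default_rules_path(),
                     json_path = NULL) {
  report <- validate_file(input, ontology = read_obo(obo),
                          rules = read_validation_rules(rules))
  if (!is.null(json_path)) report_to_json(report, json_path)
  list(status = if (nrow(report) == 0L) 0L else 3L, report = report)
}

#' Summary statistics of an interaction file
#'
#' @param input File to summarise.
#' @param from Format code or `"auto"`.
#' @return `list(interactions, distinct_interactors, arity_histogram,
#'   negatives)`.
#' @export
mi_stats <- function(input, from = "auto") {
  src <- read_any(input, from)
  ints <- src$interactions
  arities <- vapply(ints, arity, integer(1L))
  ids <- unlist(lapply(ints, function(i)
    vapply(i$participants, function(p) xref_key(p$interactor$preferred_id), character(1L))))
  list(interactions = length(ints),
       distinct_interactors = length(unique(ids)),
       arity_histogram = if (length(arities)) table(arities) else table(integer(0L)),
       negatives = sum(vapply(ints, `[[`, logical(1L), "is_negative")))
}

#' Read a key: value configuration file
#'
#' The optional front-end configuration is a YAML-like flat file of
#' `key: value` lines (`#` comments allowed); recognised keys are
#' `expansion`, `rules` and `obo`.
#'
#' @param path Config file path.
#' @return Named character vector (empty if the file does not exist).
#' @export
mi_read_config <- function(path) {
  if (!file.exists(path)) return(stats::setNames(character(0L), character(0L)))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(vals, keys)
}
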