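# MITAB 2.5 / 2.6 / 2.7 reader and writer.
#
# Grammar (public MITAB specification): tab separates columns, "|" separates
# multiple values inside a column, "-" is the empty column. Each value is
# db:identifier or db:identifier(free text); any sub-field containing a
# reserved character (| ( ) : tab double-quote backslash) is wrapped in
# double quotes, with backslash escaping of " and \ inside quotes.
# The writer is strict-out (always quotes when needed); the reader is
# permissive-in (accepts quoted and bare forms).

MITAB_VERSIONS <- c("2.5" = 15L, "2.6" = 36L, "2.7" = 42L)

MITAB_COLUMNS <- c(
  "ID(s) interactor A", "ID(s) interactor B",
  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
  "Alias(es) interactor A", "Alias(es) interactor B",
  "Interaction detection method(s)", "Publication 1st author(s)",
  "Publication Identifier(s)", "Taxid interactor A", "Taxid interactor B",
  "Interaction type(s)", "Source database(s)", "Interaction identifier(s)",
  "Confidence value(s)",
  # 2.6 additions
  "Expansion method(s)",
  "Biological role(s) interactor A", "Biological role(s) interactor B",
  "Experimental role(s) interactor A", "Experimental role(s) interactor B",
  "Type(s) interactor A", "Type(s) interactor B",
  "Xref(s) interactor A", "Xref(s) interactor B", "Interaction Xref(s)",
  "Annotation(s) interactor A", "Annotation(s) interactor B",
  "Interaction annotation(s)", "Host organism(s)", "Interaction parameter(s)",
  "Creation date", "Update date",
  "Checksum(s) interactor A", "Checksum(s) interactor B",
  "Interaction Checksum(s)", "Negative",
  # 2.7 additions
  "Feature(s) interactor A", "Feature(s) interactor B",
  "Stoichiometry(s) interactor A", "Stoichiometry(s) interactor B",
  "Identification method participant A", "Identification method participant B")

#' Detect the MITAB dialect from a data row's column count
#'
#' The three public dialects have fixed widths: 15 columns is 2.5, 36 is
#' 2.6, 42 is 2.7. Any other width is not a MITAB dialect this package
#' knows.
#'
#' @param first_data_row_column_count Integer column count (>= 1).
#' @return The version string `"2.5"`, `"2.6"` or `"2.7"`.
#' @export
detect_mitab_version <- function(first_data_row_column_count) {
  n <- int1(first_data_row_column_count, "column count")
  hit <- names(MITAB_VERSIONS)[MITAB_VERSIONS == n]
  if (length(hit) != 1L)
    mi_stop("mi_unsupported_dialect",
            sprintf("no MITAB dialect has %d columns (known: 15 = 2.5, 36 = 2.6, 42 = 2.7)", n))
  hit
}

# ---- field grammar ---------------------------------------------------------

# split one cell on unescaped "|"; fast path when no quotes are present
mitab_split_entries <- function(raw, context = "") {
  if (!grepl('"', raw, fixed = TRUE)) {
    return(strsplit(raw, "|", fixed = TRUE)[[1L]])
  }
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  parts <- character(0L); buf <- character(0L)
  in_quote <- FALSE; i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (in_quote) {
      if (ch == "\\" && i < n) { buf <- c(buf, ch, chars[[i + 1L]]); i <- i + 2L; next }
      if (ch == '"') in_quote <- FALSE
      buf <- c(buf, ch)
    } else if (ch == '"') {
      in_quote <- TRUE; buf <- c(buf, ch)
    } else if (ch == "|") {
      parts <- c(parts, paste(buf, collapse = "")); buf <- character(0L)
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  if (in_quote)
    mi_stop("mi_malformed_field", sprintf("unbalanced quote in field%s: %s", context, raw))
  c(parts, paste(buf, collapse = ""))
}

# parse one db:id(text) entry into list(db, id, text); text "" when absent
mitab_parse_entry <- function(entry, context = "") {
  if (!grepl('"', entry, fixed = TRUE)) {
    # bare form: first ":" splits db from id, trailing (...) is free text
    m <- regmatches(entry, regexec("^([^:()]*):([^()]*)(\\(([^()]*)\\))?$", entry))[[1L]]
    if (!length(m)) {
      if (grepl("[()\"]", entry))
        mi_stop("mi_malformed_field",
                sprintf("unbalanced parentheses in field%s: %s", context, entry))
      return(list(db = "", id = entry, text = ""))   # no ":" at all
    }
    return(list(db = m[[2L]], id = m[[3L]], text = m[[5L]] %||% ""))
  }
  # quoted form: scan characters with quote/escape handling
  chars <- strsplit(entry, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  part <- 1L # 1 = db, 2 = id, 3 = text
  acc <- list(character(0L), character(0L), character(0L))
  in_quote <- FALSE; paren_open <- FALSE; i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (in_quote) {
      if (ch == "\\" && i < n) {
        acc[[part]] <- c(acc[[part]], chars[[i + 1L]]); i <- i + 2L; next
      }
      if (ch == '"') in_quote <- FALSE else acc[[part]] <- c(acc[[part]], ch)
    } else if (ch == '"') {
      in_quote <- TRUE
    } else if (ch == ":" && part == 1L) {
      part <- 2L
    } else if (ch == "(" && part == 2L) {
      part <- 3L; paren_open <- TRUE
    } else if (ch == ")" && part == 3L) {
      paren_open <- FALSE
    } else {
      acc[[part]] <- c(acc[[part]], ch)
    }
    i <- i + 1L
  }
  if (in_quote || paren_open)
    mi_stop("mi_malformed_field",
            sprintf("unbalanced %s in field%s: %s",
                    if (in_quote) "quote" else "parenthesis", context, entry))
  out <- vapply(acc, paste, character(1L), collapse = "")
  if (part == 1L) return(list(db = "", id = out[[1L]], text = ""))
  list(db = out[[1L]], id = out[[2L]], text = out[[3L]])
}

#' Parse one MITAB cell into its values
#'
#' Splits a tab-separated cell on unescaped `|` and parses each value as
#' `db:identifier` or `db:identifier(free text)`, honouring double-quote
#' escaping of the reserved characters. `"-"` denotes the empty cell.
#'
#' @param raw One cell of a MITAB row.
#' @param context Optional context string used in error messages.
#' @return A list of `list(db, id, text)` values (`text` is `""` when absent).
#' @examples
#' parse_mitab_field("uniprotkb:P12345")
#' parse_mitab_field('psi-mi:"MI:0407"(direct interaction)')
#' parse_mitab_field("-")
#' @export
parse_mitab_field <- function(raw, context = "") {
  chr1(raw, "raw", allow_empty = TRUE)
  if (raw == "-" || raw == "") return(list())
  entries <- mitab_split_entries(raw, context)
  lapply(entries, mitab_parse_entry, context = context)
}

# needs quoting if it holds a reserved character or is exactly "-"
mitab_quote <- function(s) {
  if (s == "-" || grepl('[|():\t"\\\\]', s)) {
    paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s)), '"')
  } else s
}

mitab_format_entry <- function(db, id, text = "") {
  # tabs/newlines in values cannot survive the row structure; degrade to space
  clean <- function(s) gsub("[\t\r\n]", " ", s)
  out <- paste0(mitab_quote(clean(db)), ":", mitab_quote(clean(id)))
  if (nzchar(text)) out <- paste0(out, "(", mitab_quote(clean(text)), ")")
  out
}

mitab_cell <- function(entries) {
  if (length(entries) == 0L) return("-")
  paste(vapply(entries, function(e) mitab_format_entry(e$db, e$id, e$text %||% ""),
               character(1L)), collapse = "|")
}

# ---- model <-> entry helpers ----------------------------------------------

cv_to_entry <- function(t) {
  if (is.null(t)) return(NULL)
  if (!is.null(t$mi_identifier))
    list(db = "psi-mi", id = t$mi_identifier, text = t$short_name)
  else
    list(db = "unknown", id = t$short_name, text = t$full_name %||% "")
}

entry_to_cv <- function(e) {
  if (is.null(e)) return(NULL)
  if (identical(e$db, "psi-mi") && grepl("^MI:[0-9]{4}$", e$id))
    cv_term(if (nzchar(e$text)) e$text else e$id, mi_identifier = e$id)
  else
    cv_term(if (nzchar(e$id)) e$id else e$db,
            full_name = if (nzchar(e$text)) e$text else NULL)
}

cv_cell <- function(t) mitab_cell(if (is.null(t)) list() else list(cv_to_entry(t)))
cv_list_cell <- function(ts) mitab_cell(lapply(ts, cv_to_entry))

cell_to_cv <- function(entries) {
  if (length(entries) == 0L) return(NULL)
  entry_to_cv(entries[[1L]])
}
cell_to_cv_list <- function(entries) lapply(entries, entry_to_cv)

xref_to_entry <- function(x) {
  list(db = x$database$short_name, id = x$identifier,
       text = if (!is.null(x$qualifier)) x$qualifier$short_name else "")
}
entry_to_xref <- function(e) {
  xref(cv_term(if (nzchar(e$db)) e$db else "unknown"), e$id,
       qualifier = if (nzchar(e$text)) cv_term(e$text) else NULL)
}

organism_cell <- function(o) {
  if (is.null(o)) return("-")
  mitab_cell(list(list(db = "taxid", id = as.character(o$taxid),
                       text = o$common_name %||% "")))
}
cell_to_organism <- function(entries) {
  if (length(entries) == 0L) return(NULL)
  e <- entries[[1L]]
  taxid <- suppressWarnings(as.integer(e$id))
  if (is.na(taxid)) return(NULL)
  organism(taxid, common_name = if (nzchar(e$text)) e$text else NULL)
}

range_to_string <- function(r) {
  pos <- function(p) if (is.na(p)) "?" else as.character(p)
  paste0(pos(r$start), "-", pos(r$end))
}
string_to_range <- function(s) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) return(NULL)
  num <- function(p) if (p == "?") NA_integer_ else suppressWarnings(as.integer(p))
  feature_range(num(parts[[1L]]), num(parts[[2L]]))
}

# Feature column grammar: type:range1,range2(text). The text slot carries
# the feature's display name when it has one, otherwise the type's MI
# accession (which the bare type label cannot), keeping round trips exact.
features_cell <- function(fs) {
  mitab_cell(lapply(fs, function(f) {
    text <- if (length(f$names)) f$names[[1L]]$name
    else if (!is.null(f$feature_type)) f$feature_type$mi_identifier %||% ""
    else ""
    list(db = if (is.null(f$feature_type)) "unknown" else f$feature_type$short_name,
         id = if (length(f$ranges)) paste(vapply(f$ranges, range_to_string, character(1L)),
                                          collapse = ",") else "?-?",
         text = text)
  }))
}
cell_to_features <- function(entries) {
  lapply(entries, function(e) {
    ranges <- Filter(Negate(is.null), lapply(strsplit(e$id, ",", fixed = TRUE)[[1L]],
                                             string_to_range))
    ranges <- Filter(function(r) !(is.na(r$start) && is.na(r$end)), ranges)
    text_is_ac <- grepl("^MI:[0-9]{4}$", e$text)
    feature(feature_type = if (nzchar(e$db) && e$db != "unknown")
      cv_term(e$db, mi_identifier = if (text_is_ac) e$text else NULL)
      else NULL,
      ranges = ranges,
      names = if (nzchar(e$text) && !text_is_ac) list(mi_alias(e$text)) else list())
  })
}

stoich_cell <- function(s) {
  if (is.null(s)) "-"
  else if (s$min_value == s$max_value) as.character(s$min_value)
  else paste0(s$min_value, ",", s$max_value)
}
cell_to_stoich <- function(raw) {
  if (raw == "-" || raw == "") return(NULL)
  vals <- suppressWarnings(as.integer(strsplit(raw, ",", fixed = TRUE)[[1L]]))
  if (any(is.na(vals)) || length(vals) < 1L || length(vals) > 2L) return(NULL)
  stoichiometry(vals[[1L]], vals[[length(vals)]])
}

annotations_cell <- function(as) {
  mitab_cell(lapply(as, function(a) list(db = a$topic$short_name,
                                         id = a$value %||% "", text = "")))
}
cell_to_annotations <- function(entries) {
  lapply(entries, function(e) annotation(cv_term(if (nzchar(e$db)) e$db else "comment"),
                                         value = if (nzchar(e$id)) e$id else NULL))
}

# ---- writer ----------------------------------------------------------------

mitab_row <- function(b, version, row_id) {
  ncol <- MITAB_VERSIONS[[version]]
  pa <- b$participants[[1L]]; pb <- b$participants[[2L]]
  exp <- b$experiment; pub <- if (!is.null(exp)) exp$publication else NULL

  pub_ids <- list()
  if (!is.null(pub)) {
    if (!is.null(pub$pubmed_id)) pub_ids <- c(pub_ids, list(list(db = "pubmed", id = pub$pubmed_id, text = "")))
    if (!is.null(pub$doi)) pub_ids <- c(pub_ids, list(list(db = "doi", id = pub$doi, text = "")))
    pub_ids <- c(pub_ids, lapply(pub$identifiers, xref_to_entry))
  }

  interactor_cells <- function(p) {
    x <- p$interactor
    list(id = mitab_cell(list(xref_to_entry(x$preferred_id))),
         alt = mitab_cell(lapply(x$alternative_ids, xref_to_entry)),
         alias = mitab_cell(lapply(x$aliases, function(a)
           list(db = "unknown", id = a$name,
                text = if (!is.null(a$alias_type)) a$alias_type$short_name else ""))),
         tax = organism_cell(x$organism))
  }
  ca <- interactor_cells(pa); cb <- interactor_cells(pb)

  cells <- character(ncol)
  cells[1:15] <- c(
    ca$id, cb$id, ca$alt, cb$alt, ca$alias, cb$alias,
    if (is.null(exp)) "-" else cv_cell(exp$detection_method),
    if (!is.null(pub) && length(pub$authors)) gsub("[\t\r\n]", " ", pub$authors[[1L]]) else "-",
    mitab_cell(pub_ids),
    ca$tax, cb$tax,
    cv_cell(b$interaction_type),
    if (!is.null(pub)) cv_cell(pub$source) else "-",
    if (!is.null(b$id)) mitab_cell(list(list(db = "synthetic", id = b$id, text = "")))
      else mitab_cell(list(list(db = "synthetic", id = as.character(row_id), text = ""))),
    mitab_cell(lapply(b$confidences, function(cf)
      list(db = cf$type$short_name, id = cf$value, text = ""))))

  if (ncol >= 36L) {
    cells[16:36] <- c(
      cv_cell(b$complex_expansion),
      cv_cell(pa$biological_role), cv_cell(pb$biological_role),
      cv_cell(pa$experimental_role), cv_cell(pb$experimental_role),
      cv_cell(pa$interactor$interactor_type), cv_cell(pb$interactor$interactor_type),
      mitab_cell(lapply(pa$interactor$xrefs, xref_to_entry)),
      mitab_cell(lapply(pb$interactor$xrefs, xref_to_entry)),
      mitab_cell(lapply(b$xrefs, xref_to_entry)),
      annotations_cell(pa$annotations), annotations_cell(pb$annotations),
      annotations_cell(b$annotations),
      if (is.null(exp)) "-" else organism_cell(exp$host_organism),
      mitab_cell(lapply(b$parameters, function(p)
        list(db = p$type$short_name, id = p$value, text = ""))),
      "-", "-",   # creation / update dates: no model slot
      "-", "-",   # interactor checksums: no model slot
      mitab_cell(lapply(b$checksums, function(ck)
        list(db = ck$method, id = ck$value, text = ""))),
      if (b$is_negative) "true" else "false")
  }
  if (ncol >= 42L) {
    cells[37:42] <- c(
      features_cell(pa$features), features_cell(pb$features),
      stoich_cell(pa$stoichiometry), stoich_cell(pb$stoichiometry),
      cv_list_cell(pa$identification_methods), cv_list_cell(pb$identification_methods))
  }
  paste(cells, collapse = "\t")
}

#' Write binary interactions as MITAB
#'
#' Emits a header line and one data row per binary interaction, with exactly
#' the column count of the requested dialect. Model fields with no slot in
#' the dialect are silently truncated (writing 2.5 of a 2.7-read record
#' keeps the first 15 columns' worth of information); the negative flag has
#' no 2.5 slot and is dropped with a warning.
#'
#' @param interactions List of [binary_interaction()] (e.g. from
#'   [read_mitab()] or [spoke_expand()]/[matrix_expand()]).
#' @param version `"2.5"`, `"2.6"` or `"2.7"`.
#' @param path Optional output file; when `NULL` the document is returned as
#'   a single string.
#' @return The MITAB text (invisibly when `path` is given).
#' @export
write_mitab <- function(interactions, version = "2.7", path = NULL) {
  if (!version %in% names(MITAB_VERSIONS))
    mi_stop("mi_unsupported_dialect",
            sprintf("unsupported MITAB version '%s' (supported: 2.5, 2.6, 2.7)", version))
  interactions <- as_binary_list(interactions)
  if (version == "2.5" && any(vapply(interactions, `[[`, logical(1L), "is_negative")))
    warning("MITAB 2.5 has no negative column; negative flags dropped on write",
            call. = FALSE)
  ncol <- MITAB_VERSIONS[[version]]
  header <- paste0("#", paste(MITAB_COLUMNS[seq_len(ncol)], collapse = "\t"))
  rows <- vapply(seq_along(interactions), function(k)
    mitab_row(interactions[[k]], version, k), character(1L))
  out <- paste(c(header, rows), collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

# accept a bare binary interaction, a plain list, or an mi_binary_list
as_binary_list <- function(x) {
  if (inherits(x, "mi_binary_interaction")) x <- list(x)
  if (!is.list(x)) mi_stop("mi_invalid", "expected a list of binary interactions")
  for (b in x)
    if (!inherits(b, "mi_binary_interaction"))
      mi_stop("mi_invalid", "all records must be binary interactions (expand n-ary input first)")
  x
}

# ---- reader ----------------------------------------------------------------

empty_report <- function() {
  data.frame(row = integer(0L), type = character(0L), message = character(0L),
             stringsAsFactors = FALSE)
}

report_add <- function(report, row, type, message) {
  rbind(report, data.frame(row = row, type = type, message = message,
                           stringsAsFactors = FALSE))
}

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

mitab_row_to_binary <- function(cells, version, row_id) {
  ncol <- length(cells)
  f <- function(i) if (i <= ncol) parse_mitab_field(cells[[i]], sprintf(" (column %d)", i)) else list()
  raw <- function(i) if (i <= ncol) cells[[i]] else "-"

  # 2.5 dialect convention: all B columns "-" means a self-interaction
  b_empty <- version == "2.5" && all(cells[c(2L, 4L, 6L, 11L)] == "-")

  build_interactor <- function(id_i, alt_i, alias_i, tax_i, type_i, xref_i) {
    ids <- f(id_i)
    if (length(ids) == 0L) return(NULL)
    aliases <- lapply(f(alias_i), function(e)
      mi_alias(if (nzchar(e$id)) e$id else e$db,
               alias_type = if (nzchar(e$text)) cv_term(e$text) else NULL))
    itype <- if (version != "2.5" && type_i <= ncol) cell_to_cv(f(type_i)) else NULL
    interactor(
      preferred_id = entry_to_xref(ids[[1L]]),
      alternative_ids = lapply(f(alt_i), entry_to_xref),
      aliases = aliases,
      interactor_type = itype %||% cv_term("unknown participant", mi_identifier = "MI:0329"),
      organism = cell_to_organism(f(tax_i)),
      xrefs = if (version != "2.5" && xref_i <= ncol) lapply(f(xref_i), entry_to_xref) else list())
  }

  ia <- build_interactor(1L, 3L, 5L, 10L, 21L, 23L)
  if (is.null(ia))
    mi_stop("mi_malformed_field", "interactor A has no identifier (column 1)")
  ib <- if (b_empty) ia else build_interactor(2L, 4L, 6L, 11L, 22L, 24L)
  if (is.null(ib)) ib <- ia  # missing B id in any dialect: treat as self

  build_participant <- function(x, bio_i, exp_i, ann_i, feat_i, st_i, idm_i) {
    participant(
      x,
      biological_role = if (version != "2.5") cell_to_cv(f(bio_i)) else NULL,
      experimental_role = if (version != "2.5") cell_to_cv(f(exp_i)) else NULL,
      identification_methods = if (version == "2.7") cell_to_cv_list(f(idm_i)) else list(),
      features = if (version == "2.7") cell_to_features(f(feat_i)) else list(),
      stoichiometry = if (version == "2.7") cell_to_stoich(raw(st_i)) else NULL,
      annotations = if (version != "2.5") cell_to_annotations(f(ann_i)) else list())
  }
  pa <- build_participant(ia, 17L, 19L, 26L, 37L, 39L, 41L)
  pb <- build_participant(ib, 18L, 20L, 27L, 38L, 40L, 42L)

  # publication: identifiers (col 9), first author (col 8), source db (col 13)
  pub <- NULL
  pub_entries <- f(9L)
  author <- raw(8L); source_cv <- cell_to_cv(f(13L))
  if (length(pub_entries) || (author != "-" && nzchar(author))) {
    pubmed <- NULL; doi <- NULL; idents <- list()
    for (e in pub_entries) {
      if (identical(e$db, "pubmed") && is.null(pubmed)) pubmed <- e$id
      else if (identical(e$db, "doi") && is.null(doi)) doi <- e$id
      else idents <- c(idents, list(entry_to_xref(e)))
    }
    authors <- if (author != "-" && nzchar(author)) author else character(0L)
    if (!is.null(pubmed) || !is.null(doi) || length(idents))
      pub <- publication(pubmed_id = pubmed, doi = doi, identifiers = idents,
                         authors = authors, source = source_cv)
    else if (length(authors))
      pub <- publication(title = authors[[1L]], authors = authors, source = source_cv)
  }

  det <- cell_to_cv(f(7L))
  host <- if (version != "2.5") cell_to_organism(f(29L)) else NULL
  exp <- if (!is.null(det) || !is.null(pub) || !is.null(host))
    experiment(publication = pub, detection_method = det, host_organism = host)
  else NULL

  id_entries <- f(14L)
  id <- if (length(id_entries)) id_entries[[1L]]$id else NULL

  binary_interaction(
    pa, pb, id = id,
    interaction_type = cell_to_cv(f(12L)),
    experiment = exp,
    confidences = lapply(f(15L), function(e) confidence(cv_term(e$db), e$id)),
    parameters = if (version != "2.5") lapply(f(30L), function(e)
      parameter(cv_term(e$db), e$id)) else list(),
    is_negative = version != "2.5" && tolower(raw(36L)) == "true",
    xrefs = if (version != "2.5") lapply(f(25L), entry_to_xref) else list(),
    annotations = if (version != "2.5") cell_to_annotations(f(28L)) else list(),
    checksums = if (version != "2.5") lapply(f(35L), function(e)
      checksum(e$db, e$id)) else list(),
    complex_expansion = if (version != "2.5") cell_to_cv(f(16L)) else NULL)
}

#' Read a MITAB file into binary interactions
#'
#' Auto-detects the dialect from the first data row's column count unless a
#' version is declared. A leading `#` line is consumed as the header; its
#' absence is tolerated. Rows whose column count differs from the detected
#' dialect, or that contain a malformed field, are skipped and collected in
#' the parse report (fatal only if the very first row is undecidable).
#'
#' @param path A file path, or the MITAB text itself (a string containing
#'   newlines or a character vector of lines).
#' @param version Declared dialect (`"2.5"`, `"2.6"`, `"2.7"`) or `NULL` to
#'   auto-detect.
#' @return A list of [binary_interaction()] of class `mi_binary_list`, with
#'   the parse report available through [parse_report()] and the detected
#'   dialect in `attr(, "mitab_version")`.
#' @export
read_mitab <- function(path, version = NULL) {
  lines <- as_lines(path)
  report <- empty_report()
  offset <- 0L
  if (length(lines) && startsWith(lines[[1L]], "#")) {
    lines <- lines[-1L]; offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  line_no <- which(keep) + offset
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(structure(list(), class = "mi_binary_list", report = report,
                     mitab_version = version %||% NA_character_))
  split_rows <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(version)) {
    # first row with a recognisable width decides the dialect; rows of other
    # widths become report entries. Fatal only when no row is decidable.
    counts <- lengths(split_rows)
    decidable <- which(counts %in% MITAB_VERSIONS)
    if (length(decidable) == 0L)
      version <- detect_mitab_version(counts[[1L]])  # raises, naming the count
    else
      version <- detect_mitab_version(counts[[decidable[[1L]]]])
  } else if (!version %in% names(MITAB_VERSIONS)) {
    mi_stop("mi_unsupported_dialect", sprintf("unsupported MITAB version '%s'", version))
  }
  expected <- MITAB_VERSIONS[[version]]
  out <- vector("list", length(lines)); n_ok <- 0L
  for (k in seq_along(split_rows)) {
    cells <- split_rows[[k]]
    if (length(cells) != expected) {
      report <- report_add(report, line_no[[k]], "column-count",
                           sprintf("row has %d columns, MITAB %s requires %d",
                                   length(cells), version, expected))
      next
    }
    rec <- tryCatch(mitab_row_to_binary(cells, version, k),
                    mi_malformed_field = function(e) e,
                    mi_invalid = function(e) e)
    if (inherits(rec, "condition")) {
      report <- report_add(report, line_no[[k]], "malformed-field", conditionMessage(rec))
      next
    }
    n_ok <- n_ok + 1L
    out[[n_ok]] <- rec
  }
  structure(out[seq_len(n_ok)], class = "mi_binary_list", report = report,
            mitab_version = version)
}

#' Parse report of a reader result
#'
#' Readers never abort on a recoverable row-level problem; they skip the
#' record and collect one report entry. This accessor returns those entries.
#'
#' @param x A result of [read_mitab()] or [read_psimi_xml()].
#' @return A data frame with columns `row`, `type`, `message`.
#' @export
parse_report <- function(x) {
  attr(x, "report") %||% empty_report()
}
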