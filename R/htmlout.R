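# Write-only HTML rendering for quick human consumption in a browser:
# a single self-contained document (inline style, fixed layout), one
# section per interaction with a participants table and a summary block.

html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

HTML_STYLE <- paste(
  "body{font-family:sans-serif;margin:2em;color:#222}",
  "table.participants{border-collapse:collapse;margin:0.5em 0}",
  "table.participants th,table.participants td{border:1px solid #999;padding:0.25em 0.6em}",
  "table.participants th{background:#eee;text-align:left}",
  "section{margin-bottom:2em;border-bottom:1px solid #ccc;padding-bottom:1em}",
  "dl.summary dt{font-weight:bold;float:left;clear:left;width:11em}",
  "dl.summary dd{margin-left:12em}",
  ".negative{color:#a00;font-weight:bold}", sep = "\n")

participant_row <- function(p) {
  x <- p$interactor
  feats <- if (length(p$features))
    paste(vapply(p$features, function(f) paste0(
      if (!is.null(f$feature_type)) f$feature_type$short_name else "feature",
      if (length(f$ranges)) paste0(" [", paste(vapply(f$ranges, range_to_string,
                                                      character(1L)), collapse = ", "), "]")
      else ""), character(1L)), collapse = "; ")
  else "&mdash;"
  org <- if (!is.null(x$organism))
    html_escape(paste0(x$organism$common_name %||% "", " (taxid ", x$organism$taxid, ")"))
  else "&mdash;"
  sprintf("<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
          html_escape(xref_key(x$preferred_id)),
          html_escape(p$biological_role$short_name),
          if (!is.null(p$experimental_role)) html_escape(p$experimental_role$short_name) else "&mdash;",
          org,
          if (length(p$features)) html_escape(feats) else feats)
}

interaction_section <- function(i, k) {
  title <- sprintf("Interaction %s", html_escape(i$id %||% as.character(k)))
  rows <- vapply(i$participants, participant_row, character(1L))
  summary_items <- character(0L)
  add_item <- function(dt, dd) sprintf("<dt>%s</dt><dd>%s</dd>", dt, dd)
  if (!is.null(i$interaction_type))
    summary_items <- c(summary_items, add_item("Type", html_escape(i$interaction_type$short_name)))
  if (!is.null(i$experiment)) {
    summary_items <- c(summary_items,
                       add_item("Detection method", html_escape(i$experiment$detection_method$short_name)))
    pub <- i$experiment$publication
    if (!is.null(pub) && !is.null(pub$pubmed_id))
      summary_items <- c(summary_items, add_item("Publication", html_escape(paste0("pubmed:", pub$pubmed_id))))
  }
  if (length(i$confidences))
    summary_items <- c(summary_items, add_item("Confidence", html_escape(
      paste(vapply(i$confidences, function(cf) paste0(cf$type$short_name, ":", cf$value),
                   character(1L)), collapse = ", "))))
  if (!is.null(i$complex_expansion))
    summary_items <- c(summary_items, add_item("Expansion", html_escape(i$complex_expansion$short_name)))
  if (i$is_negative)
    summary_items <- c(summary_items, add_item("Evidence", "<span class=\"negative\">negative</span>"))
  paste0(
    "<section>\n<h2>", title, "</h2>\n",
    "<table class=\"participants\">\n",
    "<thead><tr><th>Identifier</th><th>Biological role</th><th>Experimental role</th>",
    "<th>Organism</th><th>Features</th></tr></thead>\n<tbody>\n",
    paste(rows, collapse = "\n"), "\n</tbody>\n</table>\n",
    if (length(summary_items))
      paste0("<dl class=\"summary\">", paste(summary_items, collapse = ""), "</dl>\n")
    else "",
    "</section>")
}

#' Write interactions as a self-contained HTML page
#'
#' Renders a human-readable report: one section per interaction with a
#' participants table (identifier, roles, organism, features) and a
#' summary block (type, detection method, publication, confidences,
#' expansion, negative flag). The layout is hardwired with inline CSS so
#' the document is fully self-contained; output is deterministic.
#'
#' @param interactions List of [interaction()] (binary or n-ary; may be empty).
#' @param path Optional output file; when `NULL` the HTML text is returned.
#' @return The HTML text (invisibly when `path` is given).
#' @export
write_mi_html <- function(interactions, path = NULL) {
  if (inherits(interactions, "mi_interaction")) interactions <- list(interactions)
  for (i in interactions)
    if (!inherits(i, "mi_interaction"))
      mi_stop("mi_invalid", "write_mi_html takes a list of interactions")
  body <- if (length(interactions) == 0L)
    "<p class=\"empty\">Zero interactions in this document.</p>"
  else paste(vapply(seq_along(interactions), function(k)
    interaction_section(interactions[[k]], k), character(1L)), collapse = "\n")
  out <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>Molecular interactions</title>\n<style>\n", HTML_STYLE, "\n</style>\n</head>\n<body>\n",
    "<h1>Molecular interactions</h1>\n",
    sprintf("<p>%d interaction%s.</p>\n", length(interactions),
            if (length(interactions) == 1L) "" else "s"),
    body, "\n</body>\n</html>\n")
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Reading HTML is not supported
#'
#' HTML is a write-only rendering in the support matrix; the descriptor
#' (html, read) is invalid.
#'
#' @param x Ignored.
#' @return Never returns.
#' @export
read_html_attempt <- function(x) {
  mi_stop("mi_capability_error", "HTML is write-only: the (html, read) direction is not supported")
}
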