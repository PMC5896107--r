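# Abstract, format-agnostic molecular interaction data model. Every reader
# populates these objects and every writer consumes them; no format leaks in.
#
# All constructors validate their invariants, so a model object that exists
# is a valid one. Collections preserve order (files are ordered) but
# semantic_equals() treats them as multisets (semantics are not).

RESERVED_TAXIDS <- c(-1L, -2L, -3L, -4L, -5L) # in vitro, chem synthesis, unknown, in vivo, in silico

#' Controlled-vocabulary term
#'
#' The atom of annotation in every PSI-MI dialect: a short name, an optional
#' full name, and an optional accession in the PSI-MI ontology of the form
#' `MI:NNNN`.
#'
#' @param short_name Non-empty character scalar.
#' @param full_name Optional character scalar.
#' @param mi_identifier Optional accession matching `MI:` + 4 digits.
#' @param xrefs List of [xref()] objects.
#' @return An object of class `mi_cv_term`.
#' @examples
#' cv_term("direct interaction", mi_identifier = "MI:0407")
#' @export
cv_term <- function(short_name, full_name = NULL, mi_identifier = NULL, xrefs = list()) {
  chr1(short_name, "short_name")
  chr1_or_null(full_name, "full_name")
  if (!is.null(mi_identifier)) {
    chr1(mi_identifier, "mi_identifier")
    if (!grepl("^MI:[0-9]{4}$", mi_identifier))
      mi_stop("mi_invalid", sprintf("mi_identifier '%s' does not match 'MI:' + 4 digits", mi_identifier))
  }
  structure(
    list(short_name = short_name, full_name = full_name,
         mi_identifier = mi_identifier,
         xrefs = assert_list_of(xrefs, "mi_xref", "xrefs")),
    class = c("mi_cv_term", "mi_object"))
}

#' Database cross-reference
#'
#' @param database A [cv_term()] naming the database.
#' @param identifier Non-empty character scalar.
#' @param version,qualifier Optional version text / qualifier term.
#' @return An object of class `mi_xref`.
#' @export
xref <- function(database, identifier, version = NULL, qualifier = NULL) {
  if (is.character(database)) database <- cv_term(database)
  if (!inherits(database, "mi_cv_term")) mi_stop("mi_invalid", "database must be a cv_term")
  chr1(identifier, "identifier")
  chr1_or_null(version, "version")
  if (!is.null(qualifier) && !inherits(qualifier, "mi_cv_term"))
    mi_stop("mi_invalid", "qualifier must be a cv_term or NULL")
  structure(list(database = database, identifier = identifier,
                 version = version, qualifier = qualifier),
            class = c("mi_xref", "mi_object"))
}

#' Molecule alias
#' @param name Non-empty character scalar.
#' @param alias_type Optional [cv_term()] (e.g. "gene name").
#' @return An object of class `mi_alias`.
#' @export
mi_alias <- function(name, alias_type = NULL) {
  chr1(name, "name")
  if (!is.null(alias_type) && !inherits(alias_type, "mi_cv_term"))
    mi_stop("mi_invalid", "alias_type must be a cv_term or NULL")
  structure(list(name = name, alias_type = alias_type),
            class = c("mi_alias", "mi_object"))
}

#' Free-text annotation attached to a record
#' @param topic A [cv_term()] (or character short name) naming the topic.
#' @param value Optional character scalar.
#' @return An object of class `mi_annotation`.
#' @export
annotation <- function(topic, value = NULL) {
  if (is.character(topic)) topic <- cv_term(topic)
  if (!inherits(topic, "mi_cv_term")) mi_stop("mi_invalid", "topic must be a cv_term")
  chr1_or_null(value, "value")
  structure(list(topic = topic, value = value),
            class = c("mi_annotation", "mi_object"))
}

#' Source organism
#'
#' `taxid` is a positive NCBI taxonomy identifier or one of the PSI-MI
#' reserved negatives: -1 in vitro, -2 chemical synthesis, -3 unknown,
#' -4 in vivo, -5 in silico.
#' @param taxid Integer taxid.
#' @param common_name,scientific_name Optional names.
#' @return An object of class `mi_organism`.
#' @export
organism <- function(taxid, common_name = NULL, scientific_name = NULL) {
  taxid <- int1(taxid, "taxid")
  if (taxid <= 0L && !(taxid %in% RESERVED_TAXIDS))
    mi_stop("mi_invalid", sprintf("taxid %d is neither positive nor a reserved negative (-1..-5)", taxid))
  structure(list(taxid = taxid, common_name = chr1_or_null(common_name, "common_name"),
                 scientific_name = chr1_or_null(scientific_name, "scientific_name")),
            class = c("mi_organism", "mi_object"))
}

#' Interactor (a molecule)
#'
#' A protein, small molecule or nucleic acid participating in interactions.
#' Every interactor is identifiable through `preferred_id`.
#'
#' @param preferred_id An [xref()]; the primary identifier.
#' @param alternative_ids,xrefs Lists of [xref()].
#' @param aliases List of [mi_alias()].
#' @param interactor_type A [cv_term()]; defaults to "unknown participant".
#' @param organism Optional [organism()].
#' @param full_name Optional descriptive name.
#' @param sequence Optional non-empty, whitespace-free sequence string.
#' @param annotations List of [annotation()].
#' @return An object of class `mi_interactor`.
#' @export
interactor <- function(preferred_id, alternative_ids = list(), aliases = list(),
                       interactor_type = cv_term("unknown participant", mi_identifier = "MI:0329"),
                       organism = NULL, full_name = NULL, sequence = NULL,
                       xrefs = list(), annotations = list()) {
  if (!inherits(preferred_id, "mi_xref"))
    mi_stop("mi_invalid", "preferred_id must be an xref (every molecule is identifiable)")
  if (!inherits(interactor_type, "mi_cv_term"))
    mi_stop("mi_invalid", "interactor_type must be a cv_term")
  if (!is.null(organism) && !inherits(organism, "mi_organism"))
    mi_stop("mi_invalid", "organism must be an mi_organism or NULL")
  if (!is.null(sequence)) {
    chr1(sequence, "sequence")
    if (grepl("[[:space:]]", sequence))
      mi_stop("mi_invalid", "sequence must be whitespace-free")
  }
  structure(
    list(preferred_id = preferred_id,
         alternative_ids = assert_list_of(alternative_ids, "mi_xref", "alternative_ids"),
         aliases = assert_list_of(aliases, "mi_alias", "aliases"),
         interactor_type = interactor_type,
         organism = organism,
         full_name = chr1_or_null(full_name, "full_name"),
         sequence = sequence,
         xrefs = assert_list_of(xrefs, "mi_xref", "xrefs"),
         annotations = assert_list_of(annotations, "mi_annotation", "annotations")),
    class = c("mi_interactor", "mi_object"))
}

#' Feature range
#'
#' Coordinates are 1-based and inclusive at both ends. A position may be
#' undetermined (`NA`) with the status term saying why.
#'
#' @param start,end Integer positions or `NA`.
#' @param start_status,end_status [cv_term()] range statuses; default "certain"
#'   for determinate and "undetermined" for `NA` positions.
#' @param is_link Logical; whether the range links two molecules.
#' @return An object of class `mi_range`.
#' @export
feature_range <- function(start, end, start_status = NULL, end_status = NULL,
                          is_link = FALSE) {
  start <- if (length(start) == 1L && is.na(start)) NA_integer_ else int1(start, "start")
  end <- if (length(end) == 1L && is.na(end)) NA_integer_ else int1(end, "end")
  default_status <- function(pos) {
    if (is.na(pos)) cv_term("undetermined", mi_identifier = "MI:0339")
    else cv_term("certain", mi_identifier = "MI:0335")
  }
  start_status <- start_status %||% default_status(start)
  end_status <- end_status %||% default_status(end)
  if (!is.na(start) && start < 1L) mi_stop("mi_invalid", "positions are 1-based: start < 1")
  if (!is.na(start) && !is.na(end) && start > end)
    mi_stop("mi_invalid", sprintf("range start (%d) exceeds end (%d)", start, end))
  structure(list(start = start, end = end, start_status = start_status,
                 end_status = end_status, is_link = isTRUE(is_link)),
            class = c("mi_range", "mi_object"))
}

#' Participant feature (binding site, tag, ...)
#' @param feature_type,detection_method Optional [cv_term()]s.
#' @param ranges List of [feature_range()]; may be empty (unknown position).
#' @param names List of [mi_alias()].
#' @return An object of class `mi_feature`.
#' @export
feature <- function(feature_type = NULL, ranges = list(), detection_method = NULL,
                    names = list()) {
  for (t in list(feature_type, detection_method))
    if (!is.null(t) && !inherits(t, "mi_cv_term"))
      mi_stop("mi_invalid", "feature type/detection method must be cv_terms")
  structure(list(feature_type = feature_type,
                 ranges = assert_list_of(ranges, "mi_range", "ranges"),
                 detection_method = detection_method,
                 names = assert_list_of(names, "mi_alias", "names")),
            class = c("mi_feature", "mi_object"))
}

#' Participant stoichiometry
#' @param min_value,max_value Non-negative integers, `min_value <= max_value`.
#' @return An object of class `mi_stoichiometry`.
#' @export
stoichiometry <- function(min_value, max_value = min_value) {
  min_value <- int1(min_value, "min_value"); max_value <- int1(max_value, "max_value")
  if (min_value < 0L) mi_stop("mi_invalid", "min_value must be non-negative")
  if (min_value > max_value) mi_stop("mi_invalid", "min_value exceeds max_value")
  structure(list(min_value = min_value, max_value = max_value),
            class = c("mi_stoichiometry", "mi_object"))
}

#' Interaction participant
#'
#' The join between a molecule and one interaction: the interactor plus its
#' biological and experimental roles, features and stoichiometry. A missing
#' biological role defaults to "unspecified role" on construction.
#'
#' @param interactor An [interactor()].
#' @param biological_role,experimental_role [cv_term()]s; experimental role optional.
#' @param identification_methods List of [cv_term()].
#' @param features List of [feature()].
#' @param stoichiometry Optional [stoichiometry()].
#' @param xrefs,annotations Lists of [xref()] / [annotation()].
#' @return An object of class `mi_participant`.
#' @export
participant <- function(interactor, biological_role = NULL, experimental_role = NULL,
                        identification_methods = list(), features = list(),
                        stoichiometry = NULL, xrefs = list(), annotations = list()) {
  if (!inherits(interactor, "mi_interactor"))
    mi_stop("mi_invalid", "interactor must be an mi_interactor")
  biological_role <- biological_role %||% cv_term("unspecified role", mi_identifier = "MI:0499")
  if (!inherits(biological_role, "mi_cv_term"))
    mi_stop("mi_invalid", "biological_role must be a cv_term")
  if (!is.null(experimental_role) && !inherits(experimental_role, "mi_cv_term"))
    mi_stop("mi_invalid", "experimental_role must be a cv_term or NULL")
  if (!is.null(stoichiometry) && !inherits(stoichiometry, "mi_stoichiometry"))
    mi_stop("mi_invalid", "stoichiometry must be an mi_stoichiometry or NULL")
  structure(
    list(interactor = interactor, biological_role = biological_role,
         experimental_role = experimental_role,
         identification_methods = assert_list_of(identification_methods, "mi_cv_term", "identification_methods"),
         features = assert_list_of(features, "mi_feature", "features"),
         stoichiometry = stoichiometry,
         xrefs = assert_list_of(xrefs, "mi_xref", "xrefs"),
         annotations = assert_list_of(annotations, "mi_annotation", "annotations")),
    class = c("mi_participant", "mi_object"))
}

#' Publication
#'
#' May be identified by a cross-reference (pubmed/doi), carry inline
#' attributes (authors, journal, title), or — the XML 3.0 duality — both at
#' once. At least one of pubmed_id, doi, a non-empty identifiers list, or a
#' title must be present.
#'
#' @param pubmed_id,doi,title,journal Optional character scalars.
#' @param authors Character vector of author strings.
#' @param publication_date Optional `Date` or "YYYY-MM-DD" string.
#' @param source Optional [cv_term()] (providing database).
#' @param identifiers List of [xref()].
#' @return An object of class `mi_publication`.
#' @export
publication <- function(pubmed_id = NULL, doi = NULL, title = NULL, journal = NULL,
                        authors = character(), publication_date = NULL,
                        source = NULL, identifiers = list()) {
  chr1_or_null(pubmed_id, "pubmed_id"); chr1_or_null(doi, "doi")
  chr1_or_null(title, "title"); chr1_or_null(journal, "journal")
  if (!is.character(authors)) mi_stop("mi_invalid", "authors must be a character vector")
  if (!is.null(publication_date)) publication_date <- as.Date(publication_date)
  if (!is.null(source) && !inherits(source, "mi_cv_term"))
    mi_stop("mi_invalid", "source must be a cv_term or NULL")
  identifiers <- assert_list_of(identifiers, "mi_xref", "identifiers")
  if (is.null(pubmed_id) && is.null(doi) && length(identifiers) == 0L && is.null(title))
    mi_stop("mi_invalid", "a publication needs at least one of pubmed_id, doi, identifiers, title")
  structure(list(pubmed_id = pubmed_id, doi = doi, title = title, journal = journal,
                 authors = authors, publication_date = publication_date,
                 source = source, identifiers = identifiers),
            class = c("mi_publication", "mi_object"))
}

#' Experiment
#'
#' Experimental context of an interaction evidence. A missing detection
#' method defaults to "unspecified method" on construction.
#'
#' @param publication Optional [publication()].
#' @param detection_method A [cv_term()].
#' @param host_organism Optional [organism()].
#' @param annotations,xrefs Lists.
#' @return An object of class `mi_experiment`.
#' @export
experiment <- function(publication = NULL, detection_method = NULL,
                       host_organism = NULL, annotations = list(), xrefs = list()) {
  if (!is.null(publication) && !inherits(publication, "mi_publication"))
    mi_stop("mi_invalid", "publication must be an mi_publication or NULL")
  detection_method <- detection_method %||% cv_term("unspecified method", mi_identifier = "MI:0686")
  if (!inherits(detection_method, "mi_cv_term"))
    mi_stop("mi_invalid", "detection_method must be a cv_term")
  if (!is.null(host_organism) && !inherits(host_organism, "mi_organism"))
    mi_stop("mi_invalid", "host_organism must be an mi_organism or NULL")
  structure(list(publication = publication, detection_method = detection_method,
                 host_organism = host_organism,
                 annotations = assert_list_of(annotations, "mi_annotation", "annotations"),
                 xrefs = assert_list_of(xrefs, "mi_xref", "xrefs")),
            class = c("mi_experiment", "mi_object"))
}

#' Confidence / parameter / checksum value holders
#' @param type,method A [cv_term()] (confidence/parameter) or character (checksum method).
#' @param value Character scalar value.
#' @return Small classed records used inside [interaction()].
#' @export
confidence <- function(type, value) {
  if (is.character(type)) type <- cv_term(type)
  if (!inherits(type, "mi_cv_term")) mi_stop("mi_invalid", "confidence type must be a cv_term")
  structure(list(type = type, value = chr1(as.character(value), "value")),
            class = c("mi_confidence", "mi_object"))
}

#' @rdname confidence
#' @export
parameter <- function(type, value) {
  if (is.character(type)) type <- cv_term(type)
  if (!inherits(type, "mi_cv_term")) mi_stop("mi_invalid", "parameter type must be a cv_term")
  structure(list(type = type, value = chr1(as.character(value), "value")),
            class = c("mi_parameter", "mi_object"))
}

#' @rdname confidence
#' @export
checksum <- function(method, value) {
  structure(list(method = chr1(method, "method"), value = chr1(value, "value")),
            class = c("mi_checksum", "mi_object"))
}

#' Interaction evidence
#'
#' The central unit every format maps onto: an evidence with one or more
#' participants, an optional type and experiment, confidences, parameters
#' and a negative flag.
#'
#' @param participants Non-empty list of [participant()].
#' @param id Internal text identifier; writer-assigned when `NULL`.
#' @param interaction_type Optional [cv_term()].
#' @param experiment Optional [experiment()].
#' @param confidences,parameters,checksums Lists of [confidence()]/[parameter()]/[checksum()].
#' @param is_negative Logical; whether the evidence shows the interaction does
#'   NOT occur.
#' @param xrefs,annotations Lists.
#' @return An object of class `mi_interaction`.
#' @export
interaction <- function(participants, id = NULL, interaction_type = NULL,
                        experiment = NULL, confidences = list(), parameters = list(),
                        is_negative = FALSE, xrefs = list(), annotations = list(),
                        checksums = list()) {
  participants <- assert_list_of(participants, "mi_participant", "participants")
  if (length(participants) == 0L)
    mi_stop("mi_invalid", "an interaction needs at least one participant")
  if (!is.null(interaction_type) && !inherits(interaction_type, "mi_cv_term"))
    mi_stop("mi_invalid", "interaction_type must be a cv_term or NULL")
  if (!is.null(experiment) && !inherits(experiment, "mi_experiment"))
    mi_stop("mi_invalid", "experiment must be an mi_experiment or NULL")
  structure(
    list(id = chr1_or_null(if (!is.null(id)) as.character(id) else NULL, "id"),
         participants = participants,
         interaction_type = interaction_type, experiment = experiment,
         confidences = assert_list_of(confidences, "mi_confidence", "confidences"),
         parameters = assert_list_of(parameters, "mi_parameter", "parameters"),
         is_negative = isTRUE(is_negative),
         xrefs = assert_list_of(xrefs, "mi_xref", "xrefs"),
         annotations = assert_list_of(annotations, "mi_annotation", "annotations"),
         checksums = assert_list_of(checksums, "mi_checksum", "checksums")),
    class = c("mi_interaction", "mi_object"))
}

#' Number of participants of an interaction
#' @param x An [interaction()].
#' @return Integer arity (>= 1).
#' @export
arity <- function(x) {
  if (!inherits(x, "mi_interaction")) mi_stop("mi_invalid", "x must be an mi_interaction")
  length(x$participants)
}

#' Binary interaction
#'
#' An interaction restricted to exactly two participant slots A and B
#' (A may equal B for a self-interaction). `complex_expansion` records the
#' expansion method that produced it and is absent iff the record was
#' natively binary.
#'
#' @param participant_a,participant_b [participant()] slots A and B.
#' @param complex_expansion Optional [cv_term()] (spoke/matrix expansion).
#' @inheritParams interaction
#' @return An object of class `mi_binary_interaction` (also `mi_interaction`).
#' @export
binary_interaction <- function(participant_a, participant_b, id = NULL,
                               interaction_type = NULL, experiment = NULL,
                               confidences = list(), parameters = list(),
                               is_negative = FALSE, xrefs = list(),
                               annotations = list(), checksums = list(),
                               complex_expansion = NULL) {
  if (!is.null(complex_expansion) && !inherits(complex_expansion, "mi_cv_term"))
    mi_stop("mi_invalid", "complex_expansion must be a cv_term or NULL")
  base <- interaction(list(participant_a, participant_b), id = id,
                      interaction_type = interaction_type, experiment = experiment,
                      confidences = confidences, parameters = parameters,
                      is_negative = is_negative, xrefs = xrefs,
                      annotations = annotations, checksums = checksums)
  base$complex_expansion <- complex_expansion
  class(base) <- c("mi_binary_interaction", class(base))
  base
}

# build a binary view of an interaction, inheriting evidence-level fields
as_binary <- function(i, a, b, complex_expansion = NULL, id = NULL) {
  binary_interaction(a, b, id = id %||% i$id,
                     interaction_type = i$interaction_type, experiment = i$experiment,
                     confidences = i$confidences, parameters = i$parameters,
                     is_negative = i$is_negative, xrefs = i$xrefs,
                     annotations = i$annotations, checksums = i$checksums,
                     complex_expansion = complex_expansion)
}

#' Curated complex record (abstract interaction)
#'
#' A macromolecular assembly curated from multiple publications, as opposed
#' to a single experimental evidence. Serializable only at PSI-MI XML 3.0.
#'
#' @param recommended_name Non-empty name.
#' @param participants Non-empty list of [participant()].
#' @param evidence_type Optional [cv_term()].
#' @param organism Optional [organism()].
#' @param xrefs,annotations Lists.
#' @return An object of class `mi_complex_record`.
#' @export
complex_record <- function(recommended_name, participants, evidence_type = NULL,
                           organism = NULL, xrefs = list(), annotations = list()) {
  chr1(recommended_name, "recommended_name")
  participants <- assert_list_of(participants, "mi_participant", "participants")
  if (length(participants) == 0L)
    mi_stop("mi_invalid", "a complex needs at least one participant")
  if (!is.null(evidence_type) && !inherits(evidence_type, "mi_cv_term"))
    mi_stop("mi_invalid", "evidence_type must be a cv_term or NULL")
  if (!is.null(organism) && !inherits(organism, "mi_organism"))
    mi_stop("mi_invalid", "organism must be an mi_organism or NULL")
  structure(list(recommended_name = recommended_name, participants = participants,
                 evidence_type = evidence_type, organism = organism,
                 xrefs = assert_list_of(xrefs, "mi_xref", "xrefs"),
                 annotations = assert_list_of(annotations, "mi_annotation", "annotations")),
            class = c("mi_complex_record", "mi_object"))
}

#' Entry and entry set (document model)
#'
#' An entry set is the top-level document unit of the XML dialects; an entry
#' groups a source with its interactions and (3.0) complexes. Readers of
#' binary formats wrap their records in a single entry.
#'
#' @param entries List of [mi_entry()].
#' @param version "2.5" or "3.0".
#' @return Objects of class `mi_entry_set` / `mi_entry`.
#' @export
entry_set <- function(entries, version = "2.5") {
  entries <- assert_list_of(entries, "mi_entry", "entries")
  version <- match.arg(version, c("2.5", "3.0"))
  structure(list(entries = entries, version = version),
            class = c("mi_entry_set", "mi_object"))
}

#' @rdname entry_set
#' @param source Optional [cv_term()] describing the providing source.
#' @param interactions List of [interaction()].
#' @param complexes List of [complex_record()] (XML 3.0 only).
#' @export
mi_entry <- function(source = NULL, interactions = list(), complexes = list()) {
  if (!is.null(source) && !inherits(source, "mi_cv_term"))
    mi_stop("mi_invalid", "source must be a cv_term or NULL")
  structure(list(source = source,
                 interactions = assert_list_of(interactions, "mi_interaction", "interactions"),
                 complexes = assert_list_of(complexes, "mi_complex_record", "complexes")),
            class = c("mi_entry", "mi_object"))
}

# flatten an entry set into one list of interactions
es_interactions <- function(es) {
  do.call(c, c(lapply(es$entries, `[[`, "interactions"), list(list())))
}

#' @export
print.mi_interaction <- function(x, ...) {
  ids <- vapply(x$participants, function(p) xref_key(p$interactor$preferred_id), character(1L))
  cat(sprintf("<%s> %s [%s]%s\n",
              if (inherits(x, "mi_binary_interaction")) "binary interaction" else "interaction",
              paste(ids, collapse = " + "),
              if (is.null(x$interaction_type)) "untyped" else x$interaction_type$short_name,
              if (x$is_negative) " (negative)" else ""))
  invisible(x)
}

#' @export
print.mi_entry_set <- function(x, ...) {
  n_int <- sum(vapply(x$entries, function(e) length(e$interactions), integer(1L)))
  n_cpx <- sum(vapply(x$entries, function(e) length(e$complexes), integer(1L)))
  cat(sprintf("<PSI-MI entry set v%s> %d entr%s, %d interaction%s, %d complex%s\n",
              x$version, length(x$entries), if (length(x$entries) == 1L) "y" else "ies",
              n_int, if (n_int == 1L) "" else "s", n_cpx, if (n_cpx == 1L) "" else "es"))
  invisible(x)
}

#' @export
print.mi_cv_term <- function(x, ...) {
  cat(sprintf("<cv term> %s%s\n", x$short_name,
              if (is.null(x$mi_identifier)) "" else sprintf(" (%s)", x$mi_identifier)))
  invisible(x)
}
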