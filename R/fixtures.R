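# Seeded synthetic interaction networks with ground-truth sidecars, plus a
# corruption injector. Every round-trip, expansion, enrichment and
# validation test runs on this generator's output: no downloads, and the
# packaged mini ontology is the single CV source, so clean output always
# validates cleanly.

GEN_DETECTION <- function() list(
  cv_term("two hybrid", mi_identifier = "MI:0018"),
  cv_term("pull down", mi_identifier = "MI:0096"),
  cv_term("x-ray crystallography", mi_identifier = "MI:0114"))

GEN_TYPES <- function() list(
  cv_term("direct interaction", mi_identifier = "MI:0407"),
  cv_term("physical association", mi_identifier = "MI:0915"),
  cv_term("association", mi_identifier = "MI:0914"))

GEN_ORGANISMS <- function() list(
  organism(9606L, "human", "Homo sapiens"),
  organism(10090L, "mouse", "Mus musculus"),
  organism(4932L, "yeast", "Saccharomyces cerevisiae"),
  organism(562L, "ecoli", "Escherichia coli"))

GEN_SURNAMES <- c("Adler", "Basu", "Chen", "Diaz", "Ekstrom", "Fujita", "Garcia", "Hansen")

#' Configuration of the synthetic network generator
#'
#' The defaults describe a small experimental interactome as deposited in
#' the public interaction databases: mostly binary evidences with a tail
#' of n-ary pull-down style records (70/20/10% arity 2/3/4), a bait
#' present in 90% of evidences, occasional binding-region features, and a
#' small negative-evidence rate (5%). Identical config + seed gives
#' byte-identical serializations.
#'
#' @param n_interactors Size of the molecule pool.
#' @param n_interactions Number of interaction evidences.
#' @param arity_distribution Named numeric vector mapping arity to
#'   probability; must sum to 1.
#' @param p_bait_present Probability an evidence has exactly one bait.
#' @param p_feature Per-participant probability of a binding-region feature
#'   (requires a sequence).
#' @param p_negative Probability of a negative evidence.
#' @param p_sequence Per-interactor probability of carrying a sequence.
#' @param p_stoichiometry Per-participant probability of a stated stoichiometry.
#' @param p_annotation Per-interaction probability of a free-text comment.
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @return An object of class `mi_generator_config`.
#' @export
generator_config <- function(n_interactors = 20L, n_interactions = 30L,
                             arity_distribution = c("2" = 0.7, "3" = 0.2, "4" = 0.1),
                             p_bait_present = 0.9, p_feature = 0.3,
                             p_negative = 0.05, p_sequence = 0.8,
                             p_stoichiometry = 0.2, p_annotation = 0.3,
                             seed = 1L) {
  n_interactors <- int1(n_interactors, "n_interactors")
  n_interactions <- int1(n_interactions, "n_interactions")
  probs <- c(p_bait_present, p_feature, p_negative, p_sequence,
             p_stoichiometry, p_annotation)
  if (any(probs < 0 | probs > 1))
    mi_stop("mi_config_error", "probabilities must lie in [0, 1]")
  if (is.null(names(arity_distribution)) ||
      any(is.na(suppressWarnings(as.integer(names(arity_distribution))))))
    mi_stop("mi_config_error", "arity_distribution must be named by integer arities")
  if (abs(sum(arity_distribution) - 1) > 1e-9)
    mi_stop("mi_config_error", "arity_distribution must sum to 1")
  if (any(arity_distribution < 0))
    mi_stop("mi_config_error", "arity probabilities must be non-negative")
  structure(list(n_interactors = n_interactors, n_interactions = n_interactions,
                 arity_distribution = arity_distribution,
                 p_bait_present = p_bait_present, p_feature = p_feature,
                 p_negative = p_negative, p_sequence = p_sequence,
                 p_stoichiometry = p_stoichiometry, p_annotation = p_annotation,
                 seed = int1(seed, "seed")),
            class = "mi_generator_config")
}

#' Generate a synthetic interaction network
#'
#' Draws a pool of protein interactors (synthetic UniProtKB-style
#' accessions, organisms from a small fixed pool, optional sequences) and
#' a set of interaction evidences with arity sampled from the configured
#' distribution, one bait assigned with probability `p_bait_present`, and
#' binding-region features placed within sequence length. All CV terms
#' come from the packaged mini ontology, so the output validates cleanly.
#' The sidecar records every sampled choice, giving tests an exact oracle
#' for expansion counts and corruption ground truth.
#'
#' @param cfg A [generator_config()].
#' @return `list(entry_set, sidecar)`; the sidecar holds a per-interaction
#'   data frame (`id`, `arity`, `has_bait`, `negative`, `n_features`) plus
#'   the expected `matrix_rows` and `spoke_rows` totals and the distinct
#'   interactor count.
#' @export
generate_network <- function(cfg = generator_config()) {
  if (!inherits(cfg, "mi_generator_config"))
    mi_stop("mi_config_error", "cfg must be a generator_config()")
  with_gen_seed(cfg$seed, generate_network_impl(cfg))
}

generate_network_impl <- function(cfg) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  orgs <- GEN_ORGANISMS(); dets <- GEN_DETECTION(); types <- GEN_TYPES()

  pool <- lapply(seq_len(cfg$n_interactors), function(k) {
    seq <- if (stats::runif(1L) < cfg$p_sequence)
      paste(sample(aa, sample(50:400, 1L), replace = TRUE), collapse = "")
    else NULL
    interactor(
      preferred_id = xref(cv_term("uniprotkb", mi_identifier = "MI:0486"),
                          sprintf("P%05d", k)),
      aliases = list(mi_alias(sprintf("gene%d", k),
                              alias_type = cv_term("gene name", mi_identifier = "MI:0301"))),
      interactor_type = cv_term("protein", mi_identifier = "MI:0326"),
      organism = orgs[[sample.int(length(orgs), 1L)]],
      sequence = seq)
  })

  arities <- as.integer(names(cfg$arity_distribution))
  max_arity <- min(max(arities), cfg$n_interactors)

  interactions <- vector("list", cfg$n_interactions)
  side <- data.frame(id = character(cfg$n_interactions), arity = integer(cfg$n_interactions),
                     has_bait = logical(cfg$n_interactions),
                     negative = logical(cfg$n_interactions),
                     n_features = integer(cfg$n_interactions),
                     stringsAsFactors = FALSE)
  used <- character(0L)

  for (k in seq_len(cfg$n_interactions)) {
    n <- arities[sample.int(length(arities), 1L, prob = cfg$arity_distribution)]
    n <- min(n, max_arity)
    members <- sample.int(cfg$n_interactors, n)
    has_bait <- stats::runif(1L) < cfg$p_bait_present
    n_features <- 0L
    parts <- lapply(seq_len(n), function(j) {
      x <- pool[[members[[j]]]]
      feats <- list()
      if (!is.null(x$sequence) && stats::runif(1L) < cfg$p_feature) {
        len <- nchar(x$sequence)
        start <- sample.int(max(1L, len - 10L), 1L)
        end <- min(len, start + sample(4:9, 1L))
        feats <- list(feature(
          feature_type = cv_term("binding-associated region", mi_identifier = "MI:0117"),
          ranges = list(feature_range(start, end))))
        n_features <<- n_features + 1L
      }
      stoich <- if (stats::runif(1L) < cfg$p_stoichiometry)
        stoichiometry(sample.int(4L, 1L)) else NULL
      participant(
        x,
        biological_role = cv_term("unspecified role", mi_identifier = "MI:0499"),
        experimental_role = if (has_bait) {
          if (j == 1L) cv_term("bait", mi_identifier = "MI:0496")
          else cv_term("prey", mi_identifier = "MI:0498")
        } else NULL,
        identification_methods = list(cv_term("predetermined participant",
                                              mi_identifier = "MI:0396")),
        features = feats, stoichiometry = stoich)
    })
    used <- union(used, vapply(parts, function(p) xref_key(p$interactor$preferred_id),
                               character(1L)))
    pub <- publication(
      pubmed_id = as.character(sample(10000000:99999999, 1L)),
      authors = paste0(sample(GEN_SURNAMES, 1L), " et al."))
    exp <- experiment(
      publication = pub,
      detection_method = dets[[sample.int(length(dets), 1L)]],
      host_organism = if (stats::runif(1L) < 0.5) organism(-1L, "in vitro")
      else organism(9606L, "human"))
    anns <- if (stats::runif(1L) < cfg$p_annotation)
      list(annotation(cv_term("comment"),
                      value = sprintf("synthetic evidence %d", k)))
    else list()
    neg <- stats::runif(1L) < cfg$p_negative
    interactions[[k]] <- interaction(
      parts, id = sprintf("intx-%d", k),
      interaction_type = types[[sample.int(length(types), 1L)]],
      experiment = exp,
      confidences = list(confidence(cv_term("intact-miscore"),
                                    sprintf("%.3f", stats::runif(1L)))),
      is_negative = neg, annotations = anns)
    side$id[[k]] <- sprintf("intx-%d", k); side$arity[[k]] <- n
    side$has_bait[[k]] <- has_bait; side$negative[[k]] <- neg
    side$n_features[[k]] <- n_features
  }

  sidecar <- list(
    seed = cfg$seed,
    interactions = side,
    distinct_interactors = length(used),
    matrix_rows = sum(ifelse(side$arity >= 2L, side$arity * (side$arity - 1L) / 2L, 1L)),
    spoke_rows = sum(ifelse(side$arity <= 2L, 1L,
                            ifelse(side$has_bait, side$arity - 1L, 0L))))
  list(entry_set = entry_set(list(mi_entry(
    source = cv_term("rpsimi synthetic generator"),
    interactions = interactions))), sidecar = sidecar)
}

#' Inject corruptions into a generated file
#'
#' Takes a file written by this package and injects a stated number of
#' each corruption kind, returning the new file plus the ground-truth list
#' of injection sites. Kinds for MITAB files: `wrong_column_count`,
#' `unbalanced_quote`, `wrong_location_cv` (a detection-method cell is
#' replaced by an interactor-type term), `unknown_cv` (an interaction-type
#' cell gets the accession MI:9999 absent from the ontology). Kind for
#' PSI-MI XML files: `dangling_ref` (an interactorRef is retargeted at a
#' nonexistent id). Each corruption lands on a distinct record, so the
#' validator must report each exactly once. A kind inapplicable to the
#' file's format is a configuration error; an all-zero spec copies the
#' file unchanged.
#'
#' @param file Input file (MITAB or PSI-MI XML).
#' @param corruption_spec Named integer vector of counts per kind.
#' @param seed Integer seed for site selection.
#' @param out_path Output file; defaults to `<file>.corrupt`.
#' @return `list(path, truth)` where `truth` is a data frame with columns
#'   `kind`, `site`, `detail`.
#' @export
corrupt <- function(file, corruption_spec, seed = 1L,
                    out_path = paste0(file, ".corrupt")) {
  if (!file.exists(file)) mi_stop("mi_io_error", sprintf("cannot read '%s'", file))
  spec <- corruption_spec[corruption_spec > 0L]
  fmt <- sniff_format(file)
  mitab_kinds <- c("wrong_column_count", "unbalanced_quote", "wrong_location_cv", "unknown_cv")
  xml_kinds <- c("dangling_ref")
  valid <- if (fmt == "mitab") mitab_kinds else xml_kinds
  bad <- setdiff(names(spec), valid)
  if (length(bad))
    mi_stop("mi_config_error",
            sprintf("corruption kind%s %s inapplicable to %s files",
                    if (length(bad) == 1L) "" else "s", paste(bad, collapse = ", "), fmt))
  truth <- data.frame(kind = character(0L), site = integer(0L), detail = character(0L),
                      stringsAsFactors = FALSE)
  if (sum(spec) == 0L) {
    file.copy(file, out_path, overwrite = TRUE)
    return(list(path = out_path, truth = truth))
  }
  with_gen_seed(int1(seed, "seed"), corrupt_impl(file, out_path, spec, fmt, truth))
}

corrupt_impl <- function(file, out_path, spec, fmt, truth) {
  if (fmt == "mitab") {
    lines <- readLines(file, warn = FALSE)
    offset <- if (length(lines) && startsWith(lines[[1L]], "#")) 1L else 0L
    data_idx <- which(nzchar(trimws(lines)))
    data_idx <- data_idx[data_idx > offset]
    if (sum(spec) > length(data_idx))
      mi_stop("mi_config_error",
              sprintf("%d corruptions requested but only %d data rows available",
                      sum(spec), length(data_idx)))
    sites <- sample(data_idx, sum(spec))
    assign_kind <- rep(names(spec), times = spec)
    for (s in seq_along(sites)) {
      ln <- sites[[s]]; kind <- assign_kind[[s]]
      cells <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
      detail <- ""
      if (kind == "wrong_column_count") {
        cells <- cells[-length(cells)]
        detail <- sprintf("%d columns", length(cells))
      } else if (kind == "unbalanced_quote") {
        cells[[7L]] <- paste0(cells[[7L]], "\"")
        detail <- "stray quote in detection method"
      } else if (kind == "wrong_location_cv") {
        cells[[7L]] <- "psi-mi:\"MI:0326\"(protein)"
        detail <- "MI:0326 (interactor type) in detection-method slot"
      } else if (kind == "unknown_cv") {
        cells[[12L]] <- "psi-mi:\"MI:9999\"(mystery term)"
        detail <- "MI:9999 absent from ontology"
      }
      lines[[ln]] <- paste(cells, collapse = "\t")
      truth <- rbind(truth, data.frame(kind = kind, site = ln, detail = detail,
                                       stringsAsFactors = FALSE))
    }
    writeLines(lines, out_path, useBytes = TRUE)
  } else {
    doc <- xml2::read_xml(file)
    xml2::xml_ns_strip(doc)
    refs <- xml2::xml_find_all(doc, "//participant/interactorRef")
    # one corruption per interaction so the reader reports each exactly once
    owners <- vapply(refs, function(r)
      xml2::xml_path(xml2::xml_find_first(r, "ancestor::interaction")), character(1L))
    refs <- refs[!duplicated(owners)]
    n <- spec[["dangling_ref"]]
    if (n > length(refs))
      mi_stop("mi_config_error",
              sprintf("%d dangling_ref corruptions requested but only %d interactions with references",
                      n, length(refs)))
    sites <- sample.int(length(refs), n)
    for (s in seq_along(sites)) {
      bad_id <- as.character(9000L + s)
      xml2::xml_text(refs[[sites[[s]]]]) <- bad_id
      truth <- rbind(truth, data.frame(kind = "dangling_ref", site = sites[[s]],
                                       detail = bad_id, stringsAsFactors = FALSE))
    }
    xml2::write_xml(doc, out_path, options = "format")
  }
  list(path = out_path, truth = truth)
}
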