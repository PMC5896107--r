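---
title: "One model, many dialects: interoperating PSI-MI interaction formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One model, many dialects: interoperating PSI-MI interaction formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsimi)
```

## The problem

Molecular interaction data is published in a family of dialects maintained
by the HUPO Proteomics Standards Initiative: the full-fidelity PSI-MI XML
interchange format (2.5 for experimental evidences, 3.0 adding abstract
interactions — curated complexes — and richer publication handling), the
tab-delimited MITAB family (2.5 with 15 columns, 2.6 with 36, 2.7 with 42,
one binary evidence per row), and newer JSON renderings for web viewers.
All of them carry the same biology at different resolutions, annotated
with one shared controlled vocabulary (the MI ontology, `MI:NNNN`
accessions). Every tool that hard-codes one dialect breaks when the
dialect moves.

`rpsimi` puts a single abstract data model in the middle. Readers populate
it, writers consume it, and a conversion is always one read plus one
write — never a chain of format-to-format transformations. The registry
enforces the support matrix: XML 2.5/3.0 and MITAB 2.5/2.6/2.7 read and
write; MI-JSON and HTML write-only.

## The data model and its comparator

The model's central unit is the interaction evidence: one or more
participants (each an interactor — protein, small molecule, nucleic
acid — plus biological and experimental roles, features with 1-based
inclusive ranges, and stoichiometry), an interaction type, an experiment
(detection method, host organism, publication), confidences, parameters
and a negative flag. Two invariants are applied at construction rather
than left to callers: a participant always has a biological role
("unspecified role", MI:0499, when none is given) and an experiment
always has a detection method ("unspecified method", MI:0686).
Unknown or accession-less CV terms are retained as bare short names,
never dropped: the library is a carrier, not a censor.

Because files are ordered but semantics are not, collections preserve
order on read/write while `semantic_equals()` compares them as multisets.
It offers three nested stringencies:

* **identity** — the participants' preferred identifiers as an unordered
  multiset;
* **default** — adds interaction type, the negative flag, and roles;
* **exact** — further adds features, stoichiometry, confidences and
  annotations.

Exact equality implies default implies identity; the experiment block
(publication, host, detection method) is deliberately outside all three,
since evidence provenance does not change *what* interacts. The exact
level is the round-trip oracle used throughout the tests.

```{r}
a <- interaction(list(participant(interactor(xref(cv_term("uniprotkb"), "P1"))),
                      participant(interactor(xref(cv_term("uniprotkb"), "P2")))),
                 interaction_type = cv_term("direct interaction",
                                            mi_identifier = "MI:0407"))
b <- interaction(rev(a$participants))
c(identity = semantic_equals(a, b, "identity"),
  default = semantic_equals(a, b, "default"))
```

## Dialect expressibility

Writing a lower MITAB version silently truncates to its columns, and the
field sets nest monotonically (2.5 ⊆ 2.6 ⊆ 2.7). A round trip can only be
exact for records the dialect can express: MITAB 2.5 has no slots for
roles, features, stoichiometry, annotations or the negative flag (the
negative flag is dropped with a warning), 2.6 adds everything except
features/stoichiometry/identification methods, and 2.7 carries the full
binary model. The tests therefore pair each dialect with a generator
configuration restricted to its expressible world, and assert only
identity-level equality across truncating writes.

Three deliberate dialect choices are worth knowing:

* The MITAB 2.7 feature column (`type:start-end(text)`) has no slot for
  the feature type's accession; when a feature has no display name, the
  writer places the accession in the free-text slot and the reader
  recognises it, keeping 2.7 round trips exact. A feature with both a
  name and an accession keeps the name and loses the accession, as any
  MITAB consumer would.
* Values containing tab or newline cannot survive the row structure even
  quoted; writers degrade them to spaces. The quoting machinery otherwise
  escapes all reserved characters (`| ( ) : "` and backslash) strictly on
  write and accepts quoted or bare forms on read.
* MITAB columns with no model slot (creation/update dates, per-interactor
  checksums) are written as `-` and ignored on read.

On the XML side, both reference styles are supported and re-read to
identical models: compact (each distinct experiment/interactor defined
once at entry level, referenced by dense, deterministically assigned
numeric ids) and expanded (definitions inlined). PSI-MI XML 2.5 has no
stoichiometry element; the writer emits `<stoichiometry value="..."/>` at
both versions rather than lose data — a conscious extension, since this
package validates structure and CV usage, not schemas. The XML 3.0
additions in scope are exactly two: the publication duality (an
experiment's `bibref` may carry a bibliographic cross-reference *and*
inline author/journal/title attributes; 2.5 allows only one, and the
cross-reference wins on a 2.5 write) and abstract interactions
(complexes), which refuse to serialize at 2.5 with a capability error.
Cooperative effects, causal statements and variable parameters are out of
scope and are *reported* as unsupported elements on read, never silently
dropped.

## Expansion

Most downstream tools want binaries, so n-ary evidences are expanded:

* **spoke** — the unique bait (experimental role MI:0496, matched
  case-insensitively by short name as a fallback so plain fixtures work
  without an ontology) becomes the hub; one bait–prey binary per other
  participant, `n - 1` in total.
* **matrix** — all unordered pairs, `n(n-1)/2`.

Products are tagged with the expansion CV term (MI:1060 / MI:1061) and
inherit every interaction-level field verbatim; natively binary records
(arity ≤ 2, including self-interactions) pass through untagged. The
behaviour without a unique bait is not defined by any public convention,
so both policies are exposed on `spoke_expand()`: fail
(`fallback = "error"`) or take the lexicographically smallest preferred
identifier as hub (`"first_participant"`, recorded in the result).
Conversion pipelines add a third policy, `skip`, the default for
`mi_convert(expansion = "spoke")`: records with no unambiguous hub are
dropped with a report entry, so a spoke conversion's row count is the sum
of `n - 1` over hub-bearing interactions plus the natively binary rows.
Participants with stoichiometry above one are expanded as single slots —
copy multiplication would invent evidence the binary formats cannot
attribute.

## Enrichment

Sparsely annotated interactors are filled from fetchers: pure
identifier-to-record lookups behind a fixed contract, so enrichment
policy is independent of the data source. The shipped fetchers are
file-backed — a TSV table for molecules and the packaged OBO graph for CV
terms; live UniProtKB/ChEBI/OLS clients are deliberately out of scope,
keeping the architecture while staying offline. `fill_only` sets only
absent scalar fields and records disagreements as conflicts without
touching the data; `overwrite` applies the fetched value and still
records the conflict. List fields merge set-wise under both policies.
Enrichment never removes information and is idempotent at fixed fetcher
and policy — the second pass fills nothing.

## Validation

`validate_file()` layers two checks. Syntax reuses the readers' parse
reports: wrong column counts and malformed fields for MITAB (one report
entry per bad row; the reader continues), well-formedness, unsupported
elements and dangling numeric references for XML. CV usage is rule-driven
data, not code: each packaged rule names a model slot, a required
ancestor accession and a severity, and a term fails either by absence
from the ontology (term-not-found) or by not descending from the required
ancestor (wrong-location). The descendant test uses the transitive
`is_a` closure only — the MI ontology does not use `part_of` for these
slots. Terms without accessions cannot be checked and are skipped. The
packaged default rules cover detection method, interaction type, both
roles and interactor type; the mechanism accepts any rule table.

## The synthetic world

The generator's defaults describe a small experimental interactome as the
public databases hold them: 20 molecules, 30 evidences, 70/20/10% arity
2/3/4 (most deposited evidences are binary; pull-down style records
supply the n-ary tail), a bait present in 90% of evidences, sequences on
80% of proteins, binding-region features on 30% of sequenced
participants, stated stoichiometry on 20%, free-text comments on 30% and
a 5% negative-evidence rate — ballpark figures for curated resources,
chosen once and not tuned. All CV terms come from a packaged ~50-term
miniature of the MI ontology that mirrors its `is_a` structure, so
generator output always validates cleanly and every test is hermetic.
Identical configuration and seed give byte-identical serializations, and
the generator restores the caller's RNG stream.

What the generator does *not* emulate: realistic network topology
(no scale-free degree structure), real accessions or sequences,
multi-entry documents, or curation noise. A green round-trip test
therefore establishes carrier fidelity, not biological plausibility; the
corruption injector exists precisely to test the validator against known
ground truth (each injected site lands on a distinct record, so "reported
exactly once" is a meaningful assertion).

## Numerical and degenerate-input choices

* Feature coordinates are 1-based and inclusive at both ends; an
  undetermined position is `NA` with an "undetermined" status term, and
  `start <= end` is enforced only when both are determinate.
* MITAB dialect detection uses the first row whose width is 15, 36 or 42;
  other rows become report entries, and reading is fatal only when no row
  is decidable. A `#` header line is consumed when present, tolerated
  when absent.
* Empty inputs are legal everywhere: an empty MITAB stream reads to an
  empty sequence with an empty report, an empty binary list writes a bare
  header, MI-JSON and HTML render empty documents. An empty entry set is
  the one thing that refuses to serialize, since an XML document needs an
  entry.
* Writer-assigned interaction ids are sequential integers; XML element
  ids are dense and deterministic so diffs are stable.
* The MITAB first-author column carries the publication's first author
  only; further authors survive in XML but not in MITAB (the column is
  single-valued in practice).

## Limitations

No streaming: documents are read whole, so multi-gigabyte release files
are out of scope. No XML schema validation. MITAB 2.8 and draft dialects
are not recognised. MI-JSON and HTML are write-only by design, and the
MI-JSON field set is this package's own documented dialect (shipped as a
JSON-schema file and enforced by `mijson_conforms()`), since viewer
dialects vary.
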