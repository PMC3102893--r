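---
title: "Stand-off annotation of web documents: model, anchoring and semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand-off annotation of web documents: model, anchoring and semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(aotk)
```

`aotk` implements *stand-off* annotation: annotations live outside the
documents they describe and point back into them through selectors.
This vignette walks through the methods behind each layer — the domain
model, text anchoring, RDF serialization, graded semantic linking, and
the append-only lifecycle store — and ends with the robustness
experiment used to validate the anchoring design.

## The domain model

An annotation is a typed record connecting a *body* (free text) and/or
*topics* (ontology terms) to one or more *targets*, with full creation
provenance. Four content types (`Note`, `Errata`, `Example`,
`Definition`) require a body; the qualifier family (`Qualifier` and
its `Exact`/`Close`/`Broad`/`Narrow` refinements) links topics at a
graded meaning level, and a body-only `Qualifier` is the equivalent of
a plain tag.

```{r model}
curator <- ao_agent("http://ex.org/people/ada", "person", "Ada")
page <- ao_document_ref(
  "http://ex.org/articles/bace1",
  versions = list(ao_source_version(
    "http://ex.org/articles/bace1?rev=2024-01-15",
    "2024-01-15T09:00:00Z",
    content_digest("<html>...</html>"))))

pro_term <- ao_term("http://purl.org/obo/owl/PRO#PRO_000013562",
                    "Beta-Secretase 1")
ann <- new_annotation("ExactQualifier", curator, list(page),
                      topics = list(pro_term), seed = 1)
ann
```

Every constructor validates eagerly, and `ao_validate()` re-checks the
same invariants on objects assembled by hand or parsed from RDF,
returning violations as a data frame rather than raising them:

```{r validate}
broken <- ann
broken$topics <- list()
broken$body <- NULL
ao_validate(broken)
```

## Anchoring: normalization and two-tier resolution

Selectors for text live in a canonical *normalized* space: markup is
removed (including `<script>`/`<style>` content and comments) and every
whitespace run collapses to a single space. An offset map ties each
normalized character back to its raw position, so resolved spans can be
highlighted in the original markup:

```{r normalize}
raw <- "<p>the <b>quick</b> brown  fox</p>"
norm <- normalize_document(raw)
norm$text
norm$offset_map
```

A text-quote selector records the exact annotated string plus
surrounding context. Resolution is two-tier: first the full
`prefix + exact + postfix` window, then — flagged for curator review —
the exact string alone; no match at either tier means the anchor is an
orphan. All overlapping occurrences count, so a repeated string
honestly reports `ambiguous` rather than silently picking the first
hit.

```{r anchor}
sel <- make_text_selector(norm, 4, 9, context_len = 10)
c(prefix = sel$prefix, exact = sel$exact, postfix = sel$postfix)

res <- resolve_text_selector(sel, norm)
res$status
substr(raw, res$matches$raw_start + 1, res$matches$raw_end)
```

When the document changes, `reanchor_report()` re-resolves every
selector of a set of annotations against the new version and reports
per-selector status (`unique` / `ambiguous` / `orphan`) with the tier
that produced it. Offset-range selectors resolve by position alone
(precise but brittle), XPointer expressions are stored verbatim for
interoperability and never evaluated, and image bounding boxes
validate against pixel dimensions.

## RDF serialization

`ao_serialize()` turns entities into RDF in four syntaxes (Turtle,
RDF/XML, N-Triples, JSON-LD); `ao_parse()` inverts it up to graph
isomorphism, collecting structural violations and unknown predicates
as data instead of failing. Turtle output always binds the nine core
namespace prefixes byte-exact.

```{r rdf}
cat(substr(ao_serialize(list(ann), "turtle"), 1, 520))
```

Round trips are checked with a true blank-node-aware graph isomorphism
test:

```{r roundtrip}
g <- ao_to_graph(list(ann))
back <- ao_parse(ao_serialize(list(ann), "jsonld"), "jsonld")
graphs_isomorphic(g, back$graph)
```

`to_annotea()` down-converts to the older Annotea model (losing
anything but XPointer localization, and saying so via a `lossy`
attribute), and `moat_to_ao()` / `ao_to_moat()` exchange annotations
with MOAT-style tag/meaning structures.

## Graded semantics and cross-ontology inference

The five qualifier grades parallel the SKOS mapping vocabulary
(`related` → `skos:relatedMatch`, `exact` → `exactMatch`, `close` →
`closeMatch`, `broad` → `broadMatch`, `narrow` → `narrowMatch`). When
two qualifiers share an anchor, their grades compose into a mapping
between the terms themselves — an exact member passes the other
member's grade through, while pairs without an exact member only
support the weakest claim:

```{r infer}
frag <- ao_text_quote_selector("BACE1", "the protein ", " cleaves",
                               on_document = page$page_uri, seed = 2)
q_exact <- new_annotation("ExactQualifier", curator, list(frag),
                          topics = list(pro_term), seed = 3)
q_narrow <- new_annotation(
  "NarrowQualifier", curator, list(frag),
  topics = list(ao_term(
    "http://bioontology.org/projects/ontologies/birnlex#birnlex_23",
    "protein")), seed = 4)

infer_cross_ontology(list(q_exact, q_narrow))[
  , c("subject_term", "skos_property", "object_term")]
```

The inference is deduplicated (including symmetric duplicates of the
symmetric properties) and invariant under permutation of its input;
mappings involving instance-level terms are emitted but flagged.

## Lifecycle: curation, versioning, branching

`ao_store()` is append-only: records are added, never overwritten, so
the knowledge base only ever grows. Curator judgments chain through
`previous` pointers; the timeline reconstructs from the chain, or from
dates when pointers are absent.

```{r lifecycle}
st <- ao_store()
store_add(st, ann)
add_curation(st, ann$uri, "rejected", curator, "2024-02-01T10:00:00Z")
add_curation(st, ann$uri, "discussed", curator, "2024-02-02T10:00:00Z")
add_curation(st, ann$uri, "accepted", curator, "2024-02-03T10:00:00Z")
effective_status(st, ann$uri)

v2 <- new_annotation_version(st, ann$uri, edits = list(body = "BACE-1"))
c(version = v2$version_number, previous = v2$previous_version)
```

Sets version the same way, and `derive_set()` branches one curator's
collection into another's with fresh attribution. `supersede()`
replaces an annotation while keeping the superseded record
retrievable.

## Validating anchor robustness

The fixtures module generates synthetic HTML articles with planted
entity mentions, applies structurally-controlled mutations, and checks
how selectors fare. Because mutations act on the document structure,
the expected outcome of each class is known by construction and serves
as an oracle:

```{r robustness}
robustness_experiment(n_docs = 4, seed = 42)
```

The pattern matches the design intent: markup churn and edits far from
anchors never break them; edits inside a context window degrade
gracefully to the exact-only tier; duplicated content is reported
ambiguous unless context disambiguates it; deleted content orphans its
anchors rather than silently re-anchoring elsewhere.
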