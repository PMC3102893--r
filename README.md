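# aotk

Stand-off annotation of web documents in R: a domain model for typed
annotations with provenance, robust fragment selectors that survive
document change, lossless RDF serialization in four syntaxes,
SKOS-graded semantic linking with cross-ontology inference, and an
append-only lifecycle store for curation, versioning and branching.

Annotations are *stand-off*: they live outside the documents they
describe and point back into them. That makes it possible to annotate
pages you do not control — and makes the hard problem *anchoring*:
finding the annotated fragment again after the page changes. `aotk`
anchors text through prefix/exact/postfix quotes in a normalized text
space and resolves them in two tiers (full context, then exact string
only), reporting `unique`, `ambiguous` or `orphan` honestly instead of
guessing.

## A worked example

Annotate the protein mention "BACE1" in a snippet of markup:

```r
library(aotk)

raw <- "<p>the protein <b>BACE1</b> cleaves APP at the beta site</p>"
norm <- normalize_document(raw)
norm$text
#> [1] "the protein BACE1 cleaves APP at the beta site"

sel <- make_text_selector(norm, 12, 17, context_len = 12,
                          on_document = "http://ex.org/articles/42", seed = 1)
c(sel$prefix, sel$exact, sel$postfix)
#> [1] "the protein " "BACE1"        " cleaves APP"

curator <- ao_agent("http://ex.org/people/ada", "person", "Ada")
ann <- new_annotation("ExactQualifier", curator, list(sel),
  topics = list(ao_term("http://purl.org/obo/owl/PRO#PRO_000013562",
                        "Beta-Secretase 1")),
  created_on = "2024-02-01T09:30:00Z", seed = 2)
ann
#> <ao_annotation> http://example.org/ao/annotation/seed-2
#>   type:    aot:ExactQualifier
#>   topic:   http://purl.org/obo/owl/PRO#PRO_000013562 [exact]
#>   targets: 1
```

Serialize it to Turtle (the nine core prefixes are always bound):

```r
cat(ao_serialize(list(ann), "turtle"))
#> @prefix ao: <http://purl.org/ao/> .
#> @prefix aos: <http://purl.org/ao/selectors/> .
#> @prefix aot: <http://purl.org/ao/types/> .
#> ...
#> <http://example.org/ao/annotation/seed-2>
#>     a ao:Annotation, aot:ExactQualifier ;
#>     ao:hasTopic PRO:PRO_000013562 ;
#>     ao:hasExactMeaning PRO:PRO_000013562 ;
#>     ao:context <http://example.org/ao/selector/seed-1> ;
#>     pav:createdBy <http://ex.org/people/ada> ;
#>     pav:createdOn "2024-02-01T09:30:00Z"^^xsd:dateTime .
#>
#> <http://example.org/ao/selector/seed-1>
#>     a ao:Selector, aos:PrefixPostfixTextSelector ;
#>     aos:prefix "the protein " ;
#>     aos:exact "BACE1" ;
#>     aos:postfix " cleaves APP" ;
#>     ao:onDocument <http://ex.org/articles/42> .
```

The selector still resolves after the page's markup is rewritten:

```r
resolve_text_selector(sel, normalize_document(
  "<div>the protein <em>BACE1</em> cleaves APP at the beta site</div>"))
#> <ao_resolution> unique (tier full_context, 1 match)
```

## What else is in the box

- **Selectors**: text quotes, offset ranges, XPointer pass-through,
  image bounding boxes; `reanchor_report()` re-resolves a whole
  annotation set against a new document version.
- **RDF I/O**: `ao_serialize()` / `ao_parse()` / `ao_convert()` across
  Turtle, RDF/XML, N-Triples and JSON-LD, lossless up to graph
  isomorphism (`graphs_isomorphic()`); Annotea down-conversion and
  MOAT tagging interop.
- **Semantics**: the five qualifier grades map onto SKOS
  (`qualifier_skos_property()`), and `infer_cross_ontology()` derives
  term-to-term mappings from qualifiers that share an anchor — e.g. an
  exact PRO term plus a narrow BIRNLex term yields
  `PRO:... skos:narrowMatch birnlex_23`.
- **Lifecycle**: `ao_store()` is append-only; curation judgments chain
  and reconstruct in order (`curation_timeline()`), annotations and
  sets version without losing history, sets branch with fresh
  attribution, and `supersede()` retains what it replaces.
- **Fixtures**: `generate_document()` / `mutate_document()` /
  `robustness_experiment()` benchmark anchor survival under markup
  churn, rewording, duplication and deletion — no external data
  needed.
- **CLI**: a thin wrapper in `inst/cli/ao.R`
  (`Rscript ao.R generate|resolve|convert|validate|infer|bench ...`).

See the vignette (`vignettes/annotation-toolkit.Rmd`) for the methods
behind each layer.

## Development

```r
# run the test suite (includes the acceptance criteria)
testthat::test_dir("tests/testthat", package = "aotk",
                   load_package = "installed")
```

```sh
# recompute acceptance metrics as JSON
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
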