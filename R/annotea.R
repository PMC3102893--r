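# Annotea interoperability. Annotea (the W3C predecessor model)
# attaches annotations to documents via the `ann:annotates` property
# and localizes them with an XPointer string in `ann:context`. Only
# XPointer expressions survive the down-conversion; selectors with no
# stored XPointer cannot be expressed in Annotea and mark the output
# lossy.

ANN <- function(local) paste0("http://www.w3.org/2000/10/annotation-ns#", local)

#' Down-convert an annotation to the Annotea model
#'
#' Emits `ann` namespace triples: `ann:annotates` for each annotated
#' document, `ann:context` carrying the stored XPointer expression of
#' each XPointer selector, `ann:body` and `ann:created`. Provenance is
#' retained through `pav:createdBy`. Text-quote, offset and image
#' selectors have no Annotea encoding: their presence (without a
#' companion XPointer selector) sets the `lossy` attribute on the
#' returned graph.
#'
#' @param annotation a valid `ao_annotation`.
#' @return an `ao_graph` with a logical `lossy` attribute.
#' @export
to_annotea <- function(annotation) {
  stopifnot(inherits(annotation, "ao_annotation"))
  rep <- ao_validate(annotation)
  if (nrow(rep)) ao_stop("annotation is invalid: ", rep$message[[1L]],
                         class = "aotk_validation_error")
  g <- ao_graph()
  u <- annotation$uri
  g <- res(g, u, V("rdf:type"), ANN("Annotation"))
  g <- res(g, u, V("rdf:type"), ann_type_class(annotation$ann_type))
  lossy <- FALSE
  has_xpointer <- any(vapply(annotation$targets, inherits, logical(1L),
                             "ao_xpointer_selector"))
  for (tg in annotation$targets) {
    if (inherits(tg, "ao_document_ref")) {
      g <- res(g, u, ANN("annotates"), tg$page_uri)
    } else if (inherits(tg, "ao_xpointer_selector")) {
      g <- res(g, u, ANN("annotates"), tg$on_document)
      g <- lit(g, u, ANN("context"), tg$expression)
    } else {
      g <- res(g, u, ANN("annotates"), tg$on_document)
      if (!has_xpointer) lossy <- TRUE
    }
  }
  if (!is.null(annotation$body)) g <- lit(g, u, ANN("body"), annotation$body)
  g <- lit(g, u, ANN("created"), annotation$created_on)
  g <- res(g, u, V("pav:createdBy"), annotation$created_by$uri)
  g <- emit_agent(g, annotation$created_by, foaf = TRUE)
  attr(g, "lossy") <- lossy
  g
}

#' Reconstruct annotations from an Annotea graph
#'
#' Inverse of [to_annotea()] for the fields Annotea can carry: body,
#' annotated document, stored XPointer context and creation
#' provenance.
#'
#' @param g an `ao_graph` with Annotea-style triples.
#' @return a list of `ao_annotation` objects.
#' @export
from_annotea <- function(g) {
  stopifnot(inherits(g, "ao_graph"))
  t <- g$triples
  ann_uris <- unique(t$s[t$p == V("rdf:type") & t$o == ANN("Annotation")])
  aot_iris <- AOT_CLASS_IRIS()
  lapply(ann_uris, function(u) {
    types <- subject_types(g, u)
    hit <- names(aot_iris)[aot_iris %in% types]
    ann_type <- if (length(hit)) hit[[1L]] else "Note"
    docs <- all_resources(g, u, ANN("annotates"))
    ctx_rows <- graph_objects(g, s = u, p = ANN("context"))
    contexts <- ctx_rows$o[ctx_rows$o_type == "literal"]
    targets <- c(
      lapply(docs, function(d) ao_document_ref(d)),
      lapply(seq_along(contexts), function(i) {
        ao_xpointer_selector(contexts[[i]],
                             on_document = if (length(docs)) docs[[1L]]
                                           else "http://example.org/document")
      })
    )
    by <- first_resource(g, u, V("pav:createdBy"))
    structure(list(
      uri = u,
      ann_type = ann_type,
      composed_types = character(0),
      body = first_literal(g, u, ANN("body")),
      topics = list(),
      targets = targets,
      created_by = if (!is.null(by)) parse_agent_node(g, by)
                   else ao_agent("http://example.org/ao/agent/unknown"),
      created_on = first_literal(g, u, ANN("created")) %||% "",
      curation_head = NULL,
      previous_version = NULL,
      version_number = NULL,
      supersedes = NULL,
      tagging = NULL
    ), class = "ao_annotation")
  })
}
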