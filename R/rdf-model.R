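# Mapping between the domain model and RDF triples, in the Annotation
# Ontology vocabulary. All AO-namespace terms emitted here come from
# ao_vocabulary(); parsing inverts serialize() up to graph isomorphism.

V <- function(curie) ns_expand(curie, ao_namespaces())

agent_kind_class <- function(kind, foaf = TRUE) {
  if (foaf) {
    switch(kind,
      person = V("foaf:Person"),
      software = V("swan-agent:Software"),
      group = V("foaf:Group"),
      organization = V("foaf:Organization"))
  } else {
    switch(kind,
      person = V("aof:Agent"),
      software = V("swan-agent:Software"),
      group = V("aof:Group"),
      organization = V("aof:Organization"))
  }
}

class_to_agent_kind <- function(class_iris) {
  lut <- c(
    stats::setNames("person", V("foaf:Person")),
    stats::setNames("software", V("swan-agent:Software")),
    stats::setNames("group", V("foaf:Group")),
    stats::setNames("organization", V("foaf:Organization")),
    stats::setNames("person", V("aof:Agent")),
    stats::setNames("group", V("aof:Group")),
    stats::setNames("organization", V("aof:Organization"))
  )
  hit <- lut[intersect(class_iris, names(lut))]
  if (length(hit)) hit[[1L]] else "person"
}

ann_type_class <- function(ann_type) V(paste0("aot:", ann_type))

#' Map a meaning level to its annotation-side meaning property
#'
#' The five graded meaning properties express, from the annotation's
#' point of view, how a linked term relates to the annotated content:
#' a term broader than the content is linked with
#' `ao:hasNarrowerMeaningThan` (the content means something narrower
#' than the term), and a narrower term with
#' `ao:hasBroaderMeaningThan`.
#'
#' @param level one of `"related"`, `"exact"`, `"close"`, `"broad"`,
#'   `"narrow"` (the level of the term relative to the content).
#' @return the property IRI.
#' @export
meaning_property <- function(level) {
  switch(level,
    related = V("ao:hasRelatedMeaning"),
    exact = V("ao:hasExactMeaning"),
    close = V("ao:hasCloseMeaning"),
    broad = V("ao:hasNarrowerMeaningThan"),
    narrow = V("ao:hasBroaderMeaningThan"),
    ao_stop("unknown meaning level '", level, "'"))
}

meaning_property_to_level <- function(iri) {
  lut <- c(
    stats::setNames("related", V("ao:hasRelatedMeaning")),
    stats::setNames("exact", V("ao:hasExactMeaning")),
    stats::setNames("close", V("ao:hasCloseMeaning")),
    stats::setNames("broad", V("ao:hasNarrowerMeaningThan")),
    stats::setNames("narrow", V("ao:hasBroaderMeaningThan"))
  )
  unname(lut[iri])
}

selector_class <- function(sel) {
  if (inherits(sel, "ao_text_quote_selector")) V("aos:PrefixPostfixTextSelector")
  else if (inherits(sel, "ao_offset_selector")) V("aos:OffsetRangeTextSelector")
  else if (inherits(sel, "ao_xpointer_selector")) V("aos:XPointerSelector")
  else if (inherits(sel, "ao_image_box_selector")) V("aos:InitEndCornerSelector")
  else ao_stop("unknown selector class")
}

xsd <- function(local) paste0("http://www.w3.org/2001/XMLSchema#", local)

lit <- function(g, s, p, value, dt = NA_character_, lang = NA_character_) {
  graph_add(g, s, p, as.character(value), o_type = "literal", dt = dt,
            lang = lang)
}

res <- function(g, s, p, o) graph_add(g, s, p, o, o_type = "iri")

# ---------------------------------------------------------------------------
# Entities -> graph

emit_agent <- function(g, agent, foaf) {
  g <- res(g, agent$uri, V("rdf:type"), agent_kind_class(agent$kind, foaf))
  if (nzchar(agent$name)) {
    name_prop <- if (foaf) V("foaf:name") else V("rdfs:label")
    g <- lit(g, agent$uri, name_prop, agent$name)
  }
  g
}

emit_document <- function(g, doc, foaf) {
  g <- res(g, doc$page_uri, V("rdf:type"), V("ao:AnnotationDocument"))
  if (foaf) g <- res(g, doc$page_uri, V("rdf:type"), V("foaf:Document"))
  for (sv in doc$versions) {
    g <- res(g, doc$page_uri, V("ao:hasSourceDocument"), sv$uri)
    g <- res(g, sv$uri, V("rdf:type"), V("pav:SourceDocument"))
    g <- lit(g, sv$uri, V("pav:accessedOn"), sv$accessed_on,
             dt = xsd("dateTime"))
    if (!is.null(sv$content_digest)) {
      g <- lit(g, sv$uri, V("ao:contentDigest"), sv$content_digest)
    }
  }
  g
}

emit_selector <- function(g, sel) {
  u <- sel$uri
  g <- res(g, u, V("rdf:type"), V("ao:Selector"))
  g <- res(g, u, V("rdf:type"), selector_class(sel))
  if (inherits(sel, "ao_text_quote_selector")) {
    g <- lit(g, u, V("aos:prefix"), sel$prefix)
    g <- lit(g, u, V("aos:exact"), sel$exact)
    g <- lit(g, u, V("aos:postfix"), sel$postfix)
  } else if (inherits(sel, "ao_offset_selector")) {
    g <- lit(g, u, V("aos:offset"), sel$start, dt = xsd("integer"))
    g <- lit(g, u, V("aos:range"), sel$length, dt = xsd("integer"))
  } else if (inherits(sel, "ao_xpointer_selector")) {
    g <- lit(g, u, V("aos:expression"), sel$expression)
  } else if (inherits(sel, "ao_image_box_selector")) {
    g <- lit(g, u, V("aos:xinit"), sel$x_init, dt = xsd("integer"))
    g <- lit(g, u, V("aos:yinit"), sel$y_init, dt = xsd("integer"))
    g <- lit(g, u, V("aos:xend"), sel$x_end, dt = xsd("integer"))
    g <- lit(g, u, V("aos:yend"), sel$y_end, dt = xsd("integer"))
  }
  g <- res(g, u, V("ao:onDocument"), sel$on_document)
  if (!is.null(sel$on_version)) {
    g <- res(g, u, V("ao:onSourceVersion"), sel$on_version)
  }
  g
}

emit_token <- function(g, tok, foaf) {
  g <- res(g, tok$uri, V("rdf:type"), V("pav:Curation"))
  g <- lit(g, tok$uri, V("ao:curationStatus"), tok$status)
  g <- res(g, tok$uri, V("pav:curatedBy"), tok$curated_by$uri)
  g <- emit_agent(g, tok$curated_by, foaf)
  g <- lit(g, tok$uri, V("pav:curatedOn"), tok$curated_on,
           dt = xsd("dateTime"))
  if (!is.null(tok$previous)) {
    g <- res(g, tok$uri, V("pav:previousCuration"), tok$previous)
  }
  g
}

emit_tagging <- function(g, ann_uri, tagging, blank_counter) {
  tag_node <- sprintf("_:tag%d", blank_counter$n)
  blank_counter$n <- blank_counter$n + 1L
  g <- graph_add(g, ann_uri, V("ao:hasTagging"), tag_node, o_type = "blank")
  g <- graph_add(g, tag_node, V("rdf:type"), V("moat:Tag"))
  g <- lit(g, tag_node, V("moat:name"), tagging$tag_label)
  for (m in tagging$meanings) {
    mn <- sprintf("_:meaning%d", blank_counter$n)
    blank_counter$n <- blank_counter$n + 1L
    g <- graph_add(g, ann_uri, meaning_property(m$level), mn, o_type = "blank")
    g <- graph_add(g, mn, V("rdf:type"), V("moat:Meaning"))
    g <- res(g, mn, V("moat:meaningURI"), m$term$uri)
  }
  g
}

emit_term <- function(g, term) {
  if (!is.null(term$label)) {
    g <- lit(g, term$uri, V("rdfs:label"), term$label)
  }
  if (isTRUE(term$is_class)) {
    g <- res(g, term$uri, V("rdf:type"), V("owl:Class"))
  } else if (identical(term$is_class, FALSE)) {
    g <- res(g, term$uri, V("rdf:type"), V("owl:NamedIndividual"))
  }
  g
}

emit_annotation <- function(g, ann, foaf, topics_as_restrictions,
                            blank_counter) {
  u <- ann$uri
  g <- res(g, u, V("rdf:type"), V("ao:Annotation"))
  g <- res(g, u, V("rdf:type"), ann_type_class(ann$ann_type))
  for (ct in ann$composed_types) g <- res(g, u, V("rdf:type"), ct)
  if (!is.null(ann$body)) g <- lit(g, u, V("ann:body"), ann$body)
  for (tp in ann$topics) {
    if (topics_as_restrictions && isTRUE(tp$term$is_class)) {
      r <- sprintf("_:restr%d", blank_counter$n)
      blank_counter$n <- blank_counter$n + 1L
      g <- graph_add(g, u, V("rdf:type"), r, o_type = "blank")
      g <- graph_add(g, r, V("rdf:type"), V("owl:Restriction"))
      g <- res(g, r, V("owl:onProperty"), V("ao:hasTopic"))
      g <- res(g, r, V("owl:someValuesFrom"), tp$term$uri)
    } else {
      g <- res(g, u, V("ao:hasTopic"), tp$term$uri)
      g <- res(g, u, meaning_property(tp$level), tp$term$uri)
    }
    g <- emit_term(g, tp$term)
  }
  for (tg in ann$targets) {
    if (inherits(tg, "ao_document_ref")) {
      g <- res(g, u, V("aof:annotatesDocument"), tg$page_uri)
      g <- emit_document(g, tg, foaf)
    } else {
      g <- res(g, u, V("ao:context"), tg$uri)
      g <- emit_selector(g, tg)
    }
  }
  g <- res(g, u, V("pav:createdBy"), ann$created_by$uri)
  g <- emit_agent(g, ann$created_by, foaf)
  g <- lit(g, u, V("pav:createdOn"), ann$created_on, dt = xsd("dateTime"))
  if (!is.null(ann$curation_head)) {
    g <- res(g, u, V("ao:hasCuration"), ann$curation_head$uri)
    g <- emit_token(g, ann$curation_head, foaf)
  }
  if (!is.null(ann$previous_version)) {
    g <- res(g, u, V("pav:previousVersion"), ann$previous_version)
  }
  if (!is.null(ann$version_number)) {
    g <- lit(g, u, V("pav:versionNumber"), ann$version_number,
             dt = xsd("integer"))
  }
  if (!is.null(ann$supersedes)) {
    g <- res(g, u, V("pav:supersedes"), ann$supersedes)
  }
  if (!is.null(ann$tagging)) {
    g <- emit_tagging(g, u, ann$tagging, blank_counter)
  }
  g
}

emit_set <- function(g, set, foaf) {
  u <- set$uri
  g <- res(g, u, V("rdf:type"), V("ao:AnnotationSet"))
  for (it in set$item_uris) g <- res(g, u, V("ao:item"), it)
  g <- res(g, u, V("pav:createdBy"), set$created_by$uri)
  g <- emit_agent(g, set$created_by, foaf)
  g <- lit(g, u, V("pav:createdOn"), set$created_on, dt = xsd("dateTime"))
  if (!is.null(set$previous_version)) {
    g <- res(g, u, V("pav:previousVersion"), set$previous_version)
  }
  if (!is.null(set$version_number)) {
    g <- lit(g, u, V("pav:versionNumber"), set$version_number,
             dt = xsd("integer"))
  }
  if (!is.null(set$derived_from)) {
    g <- res(g, u, V("pav:derivedFrom"), set$derived_from)
  }
  g
}

#' Convert domain objects to a triple graph
#'
#' Entities are validated first; an invalid entity aborts the
#' conversion with the validation report attached to the condition.
#' Output includes the SIOC alignment triples (`ao:Annotation
#' rdfs:subClassOf sioc:Item`, and — behind `sioc_set_compat` —
#' `ao:AnnotationSet rdfs:subClassOf sioc:AnnotationSet`, emitted as
#' printed in the source vocabulary even though SIOC itself does not
#' define that class).
#'
#' @param entities a single domain object or a (possibly mixed) list of
#'   annotations, sets, curation tokens, agents and document refs.
#' @param foaf emit FOAF typing for agents and documents (default
#'   `TRUE`); when `FALSE`, agents are typed with the FOAF-independent
#'   local classes only.
#' @param sioc emit the SIOC alignment triples (default `TRUE` when any
#'   annotation or set is present).
#' @param sioc_set_compat also emit the `sioc:AnnotationSet` alignment
#'   (default `TRUE`).
#' @param topics_as_restrictions emit class-valued topics as an OWL
#'   someValuesFrom restriction instead of a direct `ao:hasTopic`
#'   triple (an OWL-DL-friendly encoding; default `FALSE`, and not
#'   reconstructed by parsing).
#' @return an `ao_graph`.
#' @export
ao_to_graph <- function(entities, foaf = TRUE, sioc = TRUE,
                        sioc_set_compat = TRUE,
                        topics_as_restrictions = FALSE) {
  if (!is.list(entities) || !is.null(attr(entities, "class"))) {
    entities <- list(entities)
  }
  reports <- lapply(entities, ao_validate)
  bad <- which(vapply(reports, nrow, integer(1L)) > 0L)
  if (length(bad)) {
    rep1 <- reports[[bad[[1L]]]]
    cond <- structure(
      class = c("aotk_validation_error", "error", "condition"),
      list(message = paste0(
        "entity ", bad[[1L]], " fails validation: ",
        paste(rep1$field, rep1$rule, collapse = "; ")),
        call = sys.call(), report = rep1))
    stop(cond)
  }
  g <- ao_graph()
  blank_counter <- new.env(parent = emptyenv())
  blank_counter$n <- 1L
  any_ann <- FALSE
  any_set <- FALSE
  for (e in entities) {
    if (inherits(e, "ao_annotation")) {
      any_ann <- TRUE
      g <- emit_annotation(g, e, foaf, topics_as_restrictions, blank_counter)
    } else if (inherits(e, "ao_annotation_set")) {
      any_set <- TRUE
      g <- emit_set(g, e, foaf)
    } else if (inherits(e, "ao_curation_token")) {
      g <- emit_token(g, e, foaf)
    } else if (inherits(e, "ao_agent")) {
      g <- emit_agent(g, e, foaf)
    } else if (inherits(e, "ao_document_ref")) {
      g <- emit_document(g, e, foaf)
    } else if (inherits(e, "ao_selector")) {
      g <- emit_selector(g, e)
    } else {
      ao_stop("cannot serialize object of class ",
              paste(class(e), collapse = "/"))
    }
  }
  if (sioc && (any_ann || any_set)) {
    g <- res(g, V("ao:Annotation"), V("rdfs:subClassOf"), V("sioc:Item"))
    if (sioc_set_compat && any_set) {
      g <- res(g, V("ao:AnnotationSet"), V("rdfs:subClassOf"),
               V("sioc:AnnotationSet"))
    }
  }
  g$triples <- unique(g$triples)
  check_ao_vocabulary(g)
  g
}

# Enforce the TripleGraph invariant: AO-namespace predicates/classes are
# drawn from the fixed vocabulary only.
check_ao_vocabulary <- function(g) {
  ns <- ao_namespaces()
  ao_spaces <- unname(ns[c("ao", "aos", "aot", "aof")])
  vocab <- ao_vocabulary()$iri
  in_ao <- function(x) {
    Reduce(`|`, lapply(ao_spaces, function(b) startsWith(x, b)))
  }
  used <- unique(c(
    g$triples$p[in_ao(g$triples$p)],
    g$triples$o[g$triples$o_type == "iri" & in_ao(g$triples$o)],
    g$triples$s[in_ao(g$triples$s)]
  ))
  stray <- setdiff(used, vocab)
  if (length(stray)) {
    ao_stop("stray AO-namespace terms emitted: ",
            paste(stray, collapse = ", "))
  }
  invisible(TRUE)
}
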