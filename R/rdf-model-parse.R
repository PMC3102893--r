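# Graph -> domain objects: the inverse of ao_to_graph() up to graph
# isomorphism. Structural violations surface as entries in `warnings`
# (and in per-entity ao_validate reports), not as errors, so imperfect
# third-party graphs can still be inspected.

subject_types <- function(g, s) {
  rows <- graph_objects(g, s = s, p = V("rdf:type"))
  rows$o[rows$o_type != "literal"]
}

first_literal <- function(g, s, p) {
  rows <- graph_objects(g, s = s, p = p)
  rows <- rows[rows$o_type == "literal", , drop = FALSE]
  if (nrow(rows) == 0L) NULL else rows$o[[1L]]
}

first_resource <- function(g, s, p) {
  rows <- graph_objects(g, s = s, p = p)
  rows <- rows[rows$o_type != "literal", , drop = FALSE]
  if (nrow(rows) == 0L) NULL else rows$o[[1L]]
}

all_resources <- function(g, s, p) {
  rows <- graph_objects(g, s = s, p = p)
  rows$o[rows$o_type != "literal"]
}

parse_agent_node <- function(g, uri) {
  types <- subject_types(g, uri)
  name <- first_literal(g, uri, V("foaf:name")) %||%
    first_literal(g, uri, V("rdfs:label")) %||% ""
  structure(list(uri = uri, kind = class_to_agent_kind(types), name = name),
            class = "ao_agent")
}

parse_document_node <- function(g, page_uri) {
  vuris <- all_resources(g, page_uri, V("ao:hasSourceDocument"))
  versions <- lapply(vuris, function(vu) {
    structure(list(
      uri = vu,
      accessed_on = first_literal(g, vu, V("pav:accessedOn")) %||% "",
      content_digest = first_literal(g, vu, V("ao:contentDigest"))
    ), class = "ao_source_version")
  })
  if (length(versions) > 1L) {
    ord <- order(vapply(versions, `[[`, character(1L), "accessed_on"))
    versions <- versions[ord]
  }
  structure(list(page_uri = page_uri, versions = versions),
            class = "ao_document_ref")
}

parse_selector_node <- function(g, uri) {
  types <- subject_types(g, uri)
  on_document <- first_resource(g, uri, V("ao:onDocument")) %||%
    "http://example.org/document"
  on_version <- first_resource(g, uri, V("ao:onSourceVersion"))
  base <- list(uri = uri, on_document = on_document, on_version = on_version)
  int_of <- function(p) {
    v <- first_literal(g, uri, p)
    if (is.null(v)) NA_integer_ else as.integer(v)
  }
  if (V("aos:PrefixPostfixTextSelector") %in% types) {
    structure(c(list(uri = uri,
                     prefix = first_literal(g, uri, V("aos:prefix")) %||% "",
                     exact = first_literal(g, uri, V("aos:exact")) %||% "",
                     postfix = first_literal(g, uri, V("aos:postfix")) %||% ""),
                base[c("on_document", "on_version")]),
              class = c("ao_text_quote_selector", "ao_selector"))
  } else if (V("aos:OffsetRangeTextSelector") %in% types) {
    structure(c(list(uri = uri,
                     start = int_of(V("aos:offset")),
                     length = int_of(V("aos:range"))),
                base[c("on_document", "on_version")]),
              class = c("ao_offset_selector", "ao_selector"))
  } else if (V("aos:XPointerSelector") %in% types) {
    structure(c(list(uri = uri,
                     expression = first_literal(g, uri, V("aos:expression")) %||% ""),
                base[c("on_document", "on_version")]),
              class = c("ao_xpointer_selector", "ao_selector"))
  } else if (V("aos:InitEndCornerSelector") %in% types) {
    structure(c(list(uri = uri,
                     x_init = int_of(V("aos:xinit")),
                     y_init = int_of(V("aos:yinit")),
                     x_end = int_of(V("aos:xend")),
                     y_end = int_of(V("aos:yend"))),
                base[c("on_document", "on_version")]),
              class = c("ao_image_box_selector", "ao_selector"))
  } else {
    NULL
  }
}

parse_term_node <- function(g, uri) {
  types <- subject_types(g, uri)
  is_class <- if (V("owl:Class") %in% types) TRUE
              else if (V("owl:NamedIndividual") %in% types) FALSE
              else NA
  structure(list(uri = uri,
                 label = first_literal(g, uri, V("rdfs:label")),
                 is_class = is_class),
            class = "ao_term")
}

parse_token_node <- function(g, uri) {
  by <- first_resource(g, uri, V("pav:curatedBy"))
  structure(list(
    uri = uri,
    status = first_literal(g, uri, V("ao:curationStatus")) %||% "created",
    curated_by = if (!is.null(by)) parse_agent_node(g, by) else NULL,
    curated_on = first_literal(g, uri, V("pav:curatedOn")) %||% "",
    previous = first_resource(g, uri, V("pav:previousCuration"))
  ), class = "ao_curation_token")
}

AOT_CLASS_IRIS <- function() {
  stats::setNames(ns_expand(paste0("aot:", AO_ANNOTATION_TYPES)),
                  AO_ANNOTATION_TYPES)
}

parse_annotation_node <- function(g, uri, warnings) {
  types <- subject_types(g, uri)
  aot_iris <- AOT_CLASS_IRIS()
  hit <- names(aot_iris)[aot_iris %in% types]
  ann_type <- if (length(hit)) hit[[1L]] else "Qualifier"
  # composition typing: every additional named class
  reserved <- c(unname(aot_iris), V("ao:Annotation"))
  composed <- setdiff(types[!is_blank_node(types)], reserved)

  # topics with levels
  topic_uris <- all_resources(g, uri, V("ao:hasTopic"))
  default_level <- qualifier_type_to_level(ann_type) %||% "related"
  meaning_props <- vapply(AO_MEANING_LEVELS, meaning_property, character(1L))
  topics <- lapply(topic_uris, function(tu) {
    lvl <- default_level
    for (lv in AO_MEANING_LEVELS) {
      if (tu %in% all_resources(g, uri, meaning_props[[lv]])) {
        lvl <- lv
        break
      }
    }
    list(term = parse_term_node(g, tu), level = lvl)
  })

  # tagging via blank moat:Tag / moat:Meaning structure
  tag_node <- first_resource(g, uri, V("ao:hasTagging"))
  tagging <- NULL
  if (!is.null(tag_node)) {
    meanings <- list()
    for (lv in AO_MEANING_LEVELS) {
      for (mn in all_resources(g, uri, meaning_props[[lv]])) {
        if (V("moat:Meaning") %in% subject_types(g, mn)) {
          mu <- first_resource(g, mn, V("moat:meaningURI"))
          if (!is.null(mu)) {
            meanings[[length(meanings) + 1L]] <-
              list(level = lv, term = parse_term_node(g, mu))
          }
        }
      }
    }
    tagging <- structure(
      list(tag_label = first_literal(g, tag_node, V("moat:name")) %||% "",
           meanings = meanings),
      class = "ao_tagging")
  }

  targets <- c(
    lapply(all_resources(g, uri, V("aof:annotatesDocument")),
           function(d) parse_document_node(g, d)),
    lapply(all_resources(g, uri, V("ao:context")), function(su) {
      sel <- parse_selector_node(g, su)
      if (is.null(sel)) {
        warnings$add(paste0("selector ", su, " has no recognizable type"))
      }
      sel
    })
  )
  targets <- Filter(Negate(is.null), targets)

  by <- first_resource(g, uri, V("pav:createdBy"))
  head_uri <- first_resource(g, uri, V("ao:hasCuration"))
  vn <- first_literal(g, uri, V("pav:versionNumber"))
  structure(list(
    uri = uri,
    ann_type = ann_type,
    composed_types = composed,
    body = first_literal(g, uri, V("ann:body")),
    topics = topics,
    targets = targets,
    created_by = if (!is.null(by)) parse_agent_node(g, by) else NULL,
    created_on = first_literal(g, uri, V("pav:createdOn")) %||% "",
    curation_head = if (!is.null(head_uri)) parse_token_node(g, head_uri) else NULL,
    previous_version = first_resource(g, uri, V("pav:previousVersion")),
    version_number = if (!is.null(vn)) as.integer(vn) else NULL,
    supersedes = first_resource(g, uri, V("pav:supersedes")),
    tagging = tagging
  ), class = "ao_annotation")
}

parse_set_node <- function(g, uri) {
  by <- first_resource(g, uri, V("pav:createdBy"))
  vn <- first_literal(g, uri, V("pav:versionNumber"))
  structure(list(
    uri = uri,
    item_uris = all_resources(g, uri, V("ao:item")),
    created_by = if (!is.null(by)) parse_agent_node(g, by) else NULL,
    created_on = first_literal(g, uri, V("pav:createdOn")) %||% "",
    previous_version = first_resource(g, uri, V("pav:previousVersion")),
    version_number = if (!is.null(vn)) as.integer(vn) else NULL,
    derived_from = first_resource(g, uri, V("pav:derivedFrom"))
  ), class = "ao_annotation_set")
}

#' Reconstruct domain objects from a triple graph
#'
#' Inverts [ao_to_graph()]. Unknown predicates and structural
#' violations are collected as warning strings, never raised.
#'
#' @param g an `ao_graph`.
#' @return a list with components `annotations`, `sets`, `tokens`,
#'   `documents`, `agents`, `selectors` (each a list of domain
#'   objects), `violations` (combined [ao_validate()] reports) and
#'   `warnings` (character vector).
#' @export
graph_to_entities <- function(g) {
  stopifnot(inherits(g, "ao_graph"))
  warn_store <- new.env(parent = emptyenv())
  warn_store$msgs <- character(0)
  warnings <- list(add = function(msg) {
    warn_store$msgs <- c(warn_store$msgs, msg)
  })

  t <- g$triples
  type_rows <- t[t$p == V("rdf:type") & t$o_type != "literal", , drop = FALSE]
  typed <- function(class_iri) unique(type_rows$s[type_rows$o == class_iri])

  aot_iris <- AOT_CLASS_IRIS()
  ann_uris <- unique(c(typed(V("ao:Annotation")),
                       type_rows$s[type_rows$o %in% aot_iris]))
  ann_uris <- ann_uris[!is_blank_node(ann_uris)]
  set_uris <- typed(V("ao:AnnotationSet"))
  set_uris <- setdiff(set_uris, V("ao:AnnotationSet"))
  token_uris <- typed(V("pav:Curation"))
  doc_uris <- typed(V("ao:AnnotationDocument"))
  sel_uris <- typed(V("ao:Selector"))
  agent_classes <- c(V("foaf:Person"), V("swan-agent:Software"),
                     V("foaf:Group"), V("foaf:Organization"),
                     V("aof:Agent"), V("aof:Group"), V("aof:Organization"))
  agent_uris <- unique(type_rows$s[type_rows$o %in% agent_classes])

  annotations <- lapply(ann_uris, function(u)
    parse_annotation_node(g, u, warnings))
  sets <- lapply(set_uris, parse_set_node, g = g)
  tokens <- lapply(token_uris, parse_token_node, g = g)
  documents <- lapply(doc_uris, parse_document_node, g = g)
  agents <- lapply(agent_uris, parse_agent_node, g = g)
  selectors <- Filter(Negate(is.null), lapply(sel_uris, parse_selector_node,
                                              g = g))

  # structural validation of everything reconstructed
  violations <- do.call(rbind, c(
    list(no_violations()),
    lapply(c(annotations, sets, tokens), ao_validate)
  ))
  if (nrow(violations)) {
    for (i in seq_len(nrow(violations))) {
      warnings$add(paste0("validation: ", violations$field[[i]], " ",
                          violations$rule[[i]], " - ",
                          violations$message[[i]]))
    }
  }

  # unknown-predicate warnings: anything not in the handled vocabulary
  handled <- c(
    V("rdf:type"), V("rdfs:label"), V("rdfs:subClassOf"), V("ann:body"),
    V("foaf:name"),
    V("pav:createdBy"), V("pav:createdOn"), V("pav:curatedBy"),
    V("pav:curatedOn"), V("pav:previousCuration"), V("pav:previousVersion"),
    V("pav:versionNumber"), V("pav:supersedes"), V("pav:derivedFrom"),
    V("pav:accessedOn"),
    V("moat:name"), V("moat:meaningURI"),
    V("owl:onProperty"), V("owl:someValuesFrom"),
    ao_vocabulary()$iri[ao_vocabulary()$role == "property"]
  )
  unknown <- setdiff(unique(t$p), handled)
  for (p in unknown) {
    warnings$add(paste0("unknown predicate preserved: <", p, ">"))
  }
  ao_spaces <- unname(ao_namespaces()[c("ao", "aos", "aot", "aof")])
  stray <- unknown[Reduce(`|`, lapply(ao_spaces, function(b)
    startsWith(unknown, b)), rep(FALSE, length(unknown)))]
  for (p in stray) {
    warnings$add(paste0("ad-hoc AO-namespace term: <", p, ">"))
  }

  list(annotations = annotations, sets = sets, tokens = tokens,
       documents = documents, agents = agents, selectors = selectors,
       violations = violations, warnings = warn_store$msgs)
}
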