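# SKOS-graded qualifier semantics: the correspondence between
# qualifier subtypes and SKOS mapping properties, cross-ontology
# relation inference from co-anchored qualifiers, and MOAT tagging
# interoperability.

SKOS <- function(local) paste0("http://www.w3.org/2004/02/skos/core#", local)

SKOS_SYMMETRIC <- c("relatedMatch", "exactMatch", "closeMatch")

#' SKOS mapping property for a qualifier meaning level
#'
#' The five qualifier grades parallel the SKOS concept-mapping
#' vocabulary: `related` -> `skos:relatedMatch`, `exact` ->
#' `skos:exactMatch`, `close` -> `skos:closeMatch`, `broad` ->
#' `skos:broadMatch`, `narrow` -> `skos:narrowMatch`.
#'
#' @param level one of `"related"`, `"exact"`, `"close"`, `"broad"`,
#'   `"narrow"`; vectorized.
#' @return the SKOS property IRI(s).
#' @examples
#' qualifier_skos_property("exact")
#' @export
qualifier_skos_property <- function(level) {
  vapply(level, function(lv) {
    switch(lv,
      related = SKOS("relatedMatch"),
      exact = SKOS("exactMatch"),
      close = SKOS("closeMatch"),
      broad = SKOS("broadMatch"),
      narrow = SKOS("narrowMatch"),
      ao_stop("unknown meaning level '", lv, "'"))
  }, character(1L), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Cross-ontology inference

# Expand annotations into qualifier units: one record per
# (group key, annotation, topic term, level).
qualifier_units <- function(annotations) {
  rows <- list()
  for (ann in annotations) {
    if (!ann$ann_type %in% AO_QUALIFIER_TYPES) next
    for (tg in ann$targets) {
      key <- if (inherits(tg, "ao_document_ref")) {
        paste0("doc:", tg$page_uri)
      } else {
        paste0("sel:", tg$uri)
      }
      for (tp in ann$topics) {
        rows[[length(rows) + 1L]] <- data.frame(
          key = key, ann = ann$uri, term = tp$term$uri, level = tp$level,
          is_class = if (is.na(tp$term$is_class)) NA else tp$term$is_class,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(list(data.frame(key = character(0), ann = character(0),
                                   term = character(0), level = character(0),
                                   is_class = logical(0))), rows))
}

#' Infer cross-ontology term mappings from co-anchored qualifiers
#'
#' When two qualifier annotations share an anchor (the same selector,
#' or the same whole document) and link different terms, the grades
#' compose into a SKOS mapping between the terms: if one side is an
#' exact representation of the anchored content, the other side's
#' grade carries over (`exact` + `narrow` -> the exact term
#' `skos:narrowMatch` the other term, and so on for `broad`, `close`,
#' `related`, `exact`); pairs with no exact member only support the
#' weakest claim, `skos:relatedMatch`. Duplicate conclusions —
#' including symmetric duplicates of the symmetric properties — are
#' collapsed, so the result is invariant under permutation of the
#' input.
#'
#' Mappings derived from instance-level topics (terms known to be
#' individuals, not classes) are emitted but flagged in the
#' `instance_level` column, since whether such inferences are wanted
#' is application-dependent.
#'
#' @param annotations list of `ao_annotation` objects.
#' @return a data.frame of derived mappings with columns
#'   `subject_term`, `skos_property`, `object_term`, `instance_level`,
#'   and an `evidence` list-column of contributing annotation URIs.
#' @examples
#' doc <- ao_document_ref("http://ex.org/doc")
#' alice <- ao_agent("http://ex.org/alice")
#' sel <- ao_text_quote_selector("BACE1", "the protein ", " is",
#'                               on_document = doc$page_uri, seed = 1)
#' q1 <- new_annotation("ExactQualifier", alice, list(sel),
#'   topics = list(ao_term("http://purl.org/obo/owl/PRO#PRO_000013562")))
#' q2 <- new_annotation("NarrowQualifier", alice, list(sel),
#'   topics = list(ao_term(
#'     "http://bioontology.org/projects/ontologies/birnlex#birnlex_23")))
#' infer_cross_ontology(list(q1, q2))
#' @export
infer_cross_ontology <- function(annotations) {
  if (inherits(annotations, "ao_annotation")) annotations <- list(annotations)
  units <- qualifier_units(annotations)
  out <- list()
  add <- function(a, prop_local, b, evidence, instance_level) {
    symmetric <- prop_local %in% SKOS_SYMMETRIC
    if (symmetric && a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, prop_local, b, sep = "\r")
    if (is.null(out[[key]])) {
      out[[key]] <<- list(subject_term = a, skos_property = SKOS(prop_local),
                          object_term = b, evidence = character(0),
                          instance_level = FALSE)
    }
    out[[key]]$evidence <<- union(out[[key]]$evidence, evidence)
    out[[key]]$instance_level <<- out[[key]]$instance_level || instance_level
  }
  for (key in unique(units$key)) {
    grp <- units[units$key == key, , drop = FALSE]
    n <- nrow(grp)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        A <- grp[i, ]
        B <- grp[j, ]
        if (A$term == B$term) next
        ev <- c(A$ann, B$ann)
        inst <- isTRUE(!A$is_class) || isTRUE(!B$is_class)
        if (A$level == "exact" && B$level == "exact") {
          add(A$term, "exactMatch", B$term, ev, inst)
        } else if (A$level == "exact") {
          add(A$term, sub("^.*#", "",
                          basename_skos(qualifier_skos_property(B$level))),
              B$term, ev, inst)
        } else if (B$level == "exact") {
          add(B$term, sub("^.*#", "",
                          basename_skos(qualifier_skos_property(A$level))),
              A$term, ev, inst)
        } else {
          add(A$term, "relatedMatch", B$term, ev, inst)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(subject_term = character(0),
                      skos_property = character(0),
                      object_term = character(0),
                      instance_level = logical(0),
                      evidence = I(list())))
  }
  out <- out[order(names(out))]
  df <- data.frame(
    subject_term = vapply(out, `[[`, character(1L), "subject_term"),
    skos_property = vapply(out, `[[`, character(1L), "skos_property"),
    object_term = vapply(out, `[[`, character(1L), "object_term"),
    instance_level = vapply(out, `[[`, logical(1L), "instance_level"),
    stringsAsFactors = FALSE, row.names = NULL)
  df$evidence <- I(unname(lapply(out, function(x) sort(x$evidence))))
  df
}

basename_skos <- function(iri) sub("^.*#", "", iri)

#' Serialize derived mappings as SKOS Turtle
#'
#' @param mappings output of [infer_cross_ontology()].
#' @return Turtle text.
#' @export
mappings_to_turtle <- function(mappings) {
  g <- ao_graph()
  for (i in seq_len(nrow(mappings))) {
    g <- res(g, mappings$subject_term[[i]], mappings$skos_property[[i]],
             mappings$object_term[[i]])
  }
  graph_to_turtle(g)
}

# ---------------------------------------------------------------------------
# MOAT tagging interop

#' Create a tagging record (free-text tag with optional meanings)
#'
#' @param tag_label non-empty free-text tag.
#' @param meanings list of `list(level =, term =)` entries grading how
#'   each meaning term relates to the tagged content.
#' @return an `ao_tagging` object.
#' @examples
#' ao_tagging("Linear skull fracture",
#'            list(list(level = "broad",
#'                      term = ao_term("http://ex.org/onto#SkullFracture"))))
#' @export
ao_tagging <- function(tag_label, meanings = list()) {
  if (!is_string(tag_label) || !nzchar(tag_label)) {
    ao_stop("`tag_label` must be a non-empty string")
  }
  meanings <- lapply(meanings, function(m) {
    if (!is.list(m) || !inherits(m$term, "ao_term") ||
        !is_string(m$level) || !m$level %in% AO_MEANING_LEVELS) {
      ao_stop("each meaning must be list(level = <level>, term = <ao_term>)")
    }
    list(level = m$level, term = m$term)
  })
  structure(list(tag_label = tag_label, meanings = meanings),
            class = "ao_tagging")
}

#' Migrate a MOAT-style tagging into pure AO qualifiers
#'
#' Each meaning becomes one qualifier annotation of the subtype
#' matching its level, carrying the tag label as free-text body and
#' the meaning term as topic. A meaning-less tagging yields a single
#' plain `Qualifier` with body only — the AO-native encoding of a bare
#' tag.
#'
#' @param tagging an [ao_tagging()].
#' @param target a target (document ref or selector) the tag applies to.
#' @param creator the tagging [ao_agent()].
#' @param created_on timestamp.
#' @param base_uri,seed minting controls.
#' @return a list of `ao_annotation` objects.
#' @export
moat_to_ao <- function(tagging, target, creator, created_on = ao_now(),
                       base_uri = ao_default_base(), seed = NULL) {
  stopifnot(inherits(tagging, "ao_tagging"))
  if (!is_ao_target(target)) ao_stop("`target` must be a document or selector")
  if (length(tagging$meanings) == 0L) {
    return(list(new_annotation("Qualifier", creator, list(target),
                               created_on = created_on,
                               body = tagging$tag_label,
                               base_uri = base_uri, seed = seed)))
  }
  lapply(seq_along(tagging$meanings), function(i) {
    m <- tagging$meanings[[i]]
    new_annotation(level_to_qualifier_type(m$level), creator, list(target),
                   created_on = created_on, body = tagging$tag_label,
                   topics = list(list(term = m$term, level = m$level)),
                   base_uri = base_uri,
                   seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
}

#' Transpose a qualifier annotation into MOAT restricted-tagging RDF
#'
#' Emits a `tags:RestrictedTagging` structure linking the annotated
#' resource, a `moat:Tag` (labelled with the annotation body), the
#' tagging agent, and one `moat:Meaning` per topic term; the
#' annotation-side graded meaning property records each topic's level
#' so a subsequent [moat_graph_to_tagging()] recovers it.
#'
#' @param annotation a qualifier-family `ao_annotation`.
#' @return an `ao_graph`.
#' @export
ao_to_moat <- function(annotation) {
  stopifnot(inherits(annotation, "ao_annotation"))
  if (!annotation$ann_type %in% AO_QUALIFIER_TYPES) {
    ao_stop("only qualifier-family annotations can be transposed to MOAT",
            class = "aotk_validation_error")
  }
  TAGS <- function(local) {
    paste0("http://www.holygoat.co.uk/owl/redwood/0.1/tags/", local)
  }
  MOAT <- function(local) paste0("http://moat-project.org/ns#", local)
  g <- ao_graph()
  rt <- paste0("_:rt_", gsub("[^A-Za-z0-9]", "", annotation$uri))
  tagn <- paste0(rt, "_tag")
  g <- graph_add(g, rt, V("rdf:type"), TAGS("RestrictedTagging"))
  g <- graph_add(g, rt, TAGS("associatedTag"), tagn, o_type = "blank")
  g <- graph_add(g, tagn, V("rdf:type"), MOAT("Tag"))
  g <- lit(g, tagn, MOAT("name"), annotation$body %||% "")
  g <- res(g, rt, TAGS("taggedBy"), annotation$created_by$uri)
  for (tg in annotation$targets) {
    resource <- if (inherits(tg, "ao_document_ref")) tg$page_uri else tg$uri
    g <- res(g, rt, TAGS("taggedResource"), resource)
  }
  for (k in seq_along(annotation$topics)) {
    tp <- annotation$topics[[k]]
    mn <- sprintf("%s_m%d", rt, k)
    g <- graph_add(g, mn, V("rdf:type"), MOAT("Meaning"))
    g <- res(g, mn, MOAT("meaningURI"), tp$term$uri)
    if (!is.null(tp$term$label)) {
      g <- lit(g, tp$term$uri, V("rdfs:label"), tp$term$label)
    }
    g <- graph_add(g, tagn, MOAT("hasMeaning"), mn, o_type = "blank")
    g <- graph_add(g, tagn, meaning_property(tp$level), mn, o_type = "blank")
  }
  g
}

#' Recover tagging records from a MOAT graph
#'
#' Groups `moat:Tag` nodes by label and reads each meaning's level
#' from the graded meaning property linking the tag to the
#' `moat:Meaning` node. Closes the round trip
#' tagging -> [moat_to_ao()] -> [ao_to_moat()] -> tagging.
#'
#' @param g an `ao_graph` containing MOAT-style triples.
#' @return a list of `ao_tagging` objects, one per distinct tag label.
#' @export
moat_graph_to_tagging <- function(g) {
  stopifnot(inherits(g, "ao_graph"))
  MOAT <- function(local) paste0("http://moat-project.org/ns#", local)
  t <- g$triples
  tag_nodes <- unique(t$s[t$p == V("rdf:type") & t$o == MOAT("Tag")])
  by_label <- list()
  for (tn in tag_nodes) {
    label <- first_literal(g, tn, MOAT("name")) %||% ""
    meanings <- list()
    for (lv in AO_MEANING_LEVELS) {
      mrows <- graph_objects(g, s = tn, p = meaning_property(lv))
      for (mn in mrows$o) {
        mu <- first_resource(g, mn, MOAT("meaningURI"))
        if (!is.null(mu)) {
          meanings[[length(meanings) + 1L]] <-
            list(level = lv, term = parse_term_node(g, mu))
        }
      }
    }
    if (is.null(by_label[[label]])) {
      by_label[[label]] <- meanings
    } else {
      by_label[[label]] <- c(by_label[[label]], meanings)
    }
  }
  lapply(names(by_label), function(lb) {
    ms <- by_label[[lb]]
    # stable order: by level then term URI
    if (length(ms)) {
      ord <- order(vapply(ms, `[[`, character(1L), "level"),
                   vapply(ms, function(m) m$term$uri, character(1L)))
      ms <- ms[ord]
    }
    structure(list(tag_label = lb, meanings = ms), class = "ao_tagging")
  })
}
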