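# Domain model: annotations, agents, documents, terms, curation tokens,
# annotation sets. All objects are plain lists with S3 classes;
# constructors validate eagerly and never mutate their inputs.

AO_ANNOTATION_TYPES <- c(
  "Note", "Errata", "Example", "Definition",
  "Qualifier", "ExactQualifier", "CloseQualifier",
  "BroadQualifier", "NarrowQualifier"
)

AO_QUALIFIER_TYPES <- c(
  "Qualifier", "ExactQualifier", "CloseQualifier",
  "BroadQualifier", "NarrowQualifier"
)

AO_AGENT_KINDS <- c("person", "software", "group", "organization")

AO_MEANING_LEVELS <- c("related", "exact", "close", "broad", "narrow")

AO_CORE_CURATION_STATUSES <- c("created", "accepted", "rejected", "discussed")

# level <-> qualifier subtype correspondence
level_to_qualifier_type <- function(level) {
  switch(level,
    related = "Qualifier",
    exact = "ExactQualifier",
    close = "CloseQualifier",
    broad = "BroadQualifier",
    narrow = "NarrowQualifier",
    ao_stop("unknown meaning level '", level, "'")
  )
}

qualifier_type_to_level <- function(ann_type) {
  switch(ann_type,
    Qualifier = "related",
    ExactQualifier = "exact",
    CloseQualifier = "close",
    BroadQualifier = "broad",
    NarrowQualifier = "narrow",
    NULL
  )
}

# ---------------------------------------------------------------------------
# URI minting

.mint_state <- new.env(parent = emptyenv())
.mint_state$counter <- 0L

#' Mint a fresh IRI under a base namespace
#'
#' Tokens are unique within and across sessions (a process-scoped counter
#' combined with the process id and wall-clock time, formatted as a
#' UUID-like string). When `seed` is given the token is a pure function
#' of the seed, so repeated calls with identical arguments return
#' identical IRIs — the deterministic mode used by tests and fixtures.
#'
#' @param base_namespace absolute IRI ending in `/` or `#`.
#' @param entity_kind short path segment naming the kind of entity, e.g.
#'   `"annotation"`, `"selector"`.
#' @param seed optional integer for deterministic minting.
#' @return an absolute IRI of the form `base_namespace` +
#'   `entity_kind` + `/` + token.
#' @examples
#' mint_uri("http://ex.org/ao/", "annotation", seed = 1)
#' @export
mint_uri <- function(base_namespace, entity_kind, seed = NULL) {
  if (!is_string(base_namespace) || !is_absolute_iri(base_namespace) ||
      !grepl("[/#]$", base_namespace)) {
    ao_stop("`base_namespace` must be an absolute IRI ending with '/' or '#'",
            class = "aotk_config_error")
  }
  if (!is_string(entity_kind) || !nzchar(entity_kind)) {
    ao_stop("`entity_kind` must be a non-empty string",
            class = "aotk_config_error")
  }
  if (!is.null(seed)) {
    if (!is_count(seed)) ao_stop("`seed` must be a single integer",
                                 class = "aotk_config_error")
    token <- sprintf("seed-%d", as.integer(seed))
  } else {
    .mint_state$counter <- .mint_state$counter + 1L
    token <- sprintf(
      "%s-%04x-%08x",
      format(as.numeric(Sys.time()) * 1000, scientific = FALSE, trim = TRUE),
      Sys.getpid() %% 65536L,
      .mint_state$counter
    )
  }
  paste0(base_namespace, entity_kind, "/", token)
}

#' Default base namespace for minted IRIs
#'
#' @return the base IRI used when constructors mint URIs and no
#'   `base_uri` argument is supplied.
#' @export
ao_default_base <- function() "http://example.org/ao/"

# ---------------------------------------------------------------------------
# Agents, documents, terms

#' Create an agent (annotator) record
#'
#' Agents create annotations and curation tokens. A `person` maps to
#' `foaf:Person`, `software` to `swan-agent:Software`, `group` to
#' `foaf:Group` and `organization` to `foaf:Organization` in RDF output.
#'
#' @param uri absolute IRI identifying the agent.
#' @param kind one of `"person"`, `"software"`, `"group"`,
#'   `"organization"`.
#' @param name display name.
#' @return an `ao_agent` object.
#' @examples
#' ao_agent("http://ex.org/people/curator-1", "person", "A. Curator")
#' @export
ao_agent <- function(uri, kind = "person", name = "") {
  if (!is_string(uri) || !is_absolute_iri(uri)) {
    ao_stop("agent `uri` must be an absolute IRI")
  }
  kind <- match.arg(kind, AO_AGENT_KINDS)
  if (!is_string(name)) ao_stop("agent `name` must be a string")
  structure(
    list(uri = uri, kind = kind, name = name),
    class = "ao_agent"
  )
}

#' Create a source-version record for a document
#'
#' A version-specific URI with the timestamp at which that version of
#' the page was accessed, housing `pav:SourceDocument` /
#' `pav:accessedOn` provenance. The optional `content_digest` (a hex
#' string, e.g. from [content_digest()]) supports change detection.
#'
#' @param uri absolute, version-specific IRI (must differ from the
#'   page's stable URI).
#' @param accessed_on ISO-8601 UTC timestamp string.
#' @param content_digest optional hex digest of the retrieved content.
#' @return an `ao_source_version` object.
#' @export
ao_source_version <- function(uri, accessed_on = ao_now(),
                              content_digest = NULL) {
  if (!is_string(uri) || !is_absolute_iri(uri)) {
    ao_stop("source-version `uri` must be an absolute IRI")
  }
  if (!is_iso8601(accessed_on)) {
    ao_stop("`accessed_on` must be an ISO-8601 timestamp, got '",
            accessed_on, "'")
  }
  if (!is.null(content_digest) &&
      (!is_string(content_digest) ||
       !grepl("^[0-9a-fA-F]+$", content_digest))) {
    ao_stop("`content_digest` must be a hex string")
  }
  structure(
    list(uri = uri, accessed_on = accessed_on,
         content_digest = content_digest),
    class = "ao_source_version"
  )
}

#' MD5 digest of a character string
#'
#' Convenience helper for filling `content_digest` on a source version.
#'
#' @param text a single string (e.g. a retrieved document body).
#' @return lowercase hex MD5 digest.
#' @export
content_digest <- function(text) {
  stopifnot(is_string(text))
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeChar(text, tf, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

#' Create a document reference
#'
#' The stable identity of an annotated web page, together with the
#' ordered list of versions in which it was observed. Versions must be
#' ordered by access time (non-decreasing).
#'
#' @param page_uri absolute IRI: the stable web-page identity.
#' @param versions list of [ao_source_version()] objects, oldest first.
#' @return an `ao_document_ref` object.
#' @examples
#' doc <- ao_document_ref(
#'   "http://ex.org/paper1",
#'   versions = list(ao_source_version("http://ex.org/paper1?v=1",
#'                                     "2024-01-01T00:00:00Z"))
#' )
#' @export
ao_document_ref <- function(page_uri, versions = list()) {
  if (!is_string(page_uri) || !is_absolute_iri(page_uri)) {
    ao_stop("`page_uri` must be an absolute IRI")
  }
  if (!is.list(versions) ||
      !all(vapply(versions, inherits, logical(1L), "ao_source_version"))) {
    ao_stop("`versions` must be a list of ao_source_version objects")
  }
  for (v in versions) {
    if (identical(v$uri, page_uri)) {
      ao_stop("version URI must differ from the stable page URI ('",
              page_uri, "')")
    }
  }
  if (length(versions) > 1L) {
    times <- vapply(versions, `[[`, character(1L), "accessed_on")
    if (is.unsorted(times)) {
      ao_stop("`versions` must be sorted by accessed_on (non-decreasing)")
    }
  }
  structure(
    list(page_uri = page_uri, versions = versions),
    class = "ao_document_ref"
  )
}

#' Reference an ontology term (class or individual)
#'
#' @param uri absolute IRI of the term.
#' @param label optional human-readable label.
#' @param is_class optional logical; `NA` (default) when unknown —
#'   topic linking deliberately admits both classes and individuals.
#' @return an `ao_term` object.
#' @examples
#' ao_term("http://purl.org/obo/owl/PRO#PRO_000013562", "Beta-Secretase 1")
#' @export
ao_term <- function(uri, label = NULL, is_class = NA) {
  if (!is_string(uri) || !is_absolute_iri(uri)) {
    ao_stop("term `uri` must be an absolute IRI")
  }
  if (!is.null(label) && !is_string(label)) ao_stop("`label` must be a string")
  if (!is.logical(is_class) || length(is_class) != 1L) {
    ao_stop("`is_class` must be TRUE, FALSE or NA")
  }
  structure(
    list(uri = uri, label = label, is_class = is_class),
    class = "ao_term"
  )
}

# Normalize a topics argument into a list of entries
# list(term = <ao_term>, level = <level>).
as_topic_entries <- function(topics, default_level = "related") {
  if (is.null(topics)) return(list())
  if (inherits(topics, "ao_term")) topics <- list(topics)
  lapply(topics, function(t) {
    if (inherits(t, "ao_term")) {
      list(term = t, level = default_level)
    } else if (is.list(t) && inherits(t$term, "ao_term")) {
      lvl <- t$level %||% default_level
      if (!lvl %in% AO_MEANING_LEVELS) {
        ao_stop("unknown meaning level '", lvl, "'")
      }
      list(term = t$term, level = lvl)
    } else {
      ao_stop("topics must be ao_term objects or list(term=, level=) entries")
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Annotations

is_ao_target <- function(x) {
  inherits(x, "ao_document_ref") || inherits(x, "ao_selector")
}

#' Create an annotation
#'
#' The central stand-off record: a typed body of content and/or topic
#' terms attached to one or more targets (whole documents or selector
#' fragments) with full creation provenance. Type rules follow the
#' model's tables: `Note`, `Errata`, `Example` and `Definition` require
#' a non-empty body; qualifier-family annotations require at least one
#' topic or a free-text body (a body-only qualifier is equivalent to a
#' tag).
#'
#' @param ann_type one of the nine annotation types (see
#'   `AO_ANNOTATION_TYPES` in the package source): `"Note"`,
#'   `"Errata"`, `"Example"`, `"Definition"`, `"Qualifier"`,
#'   `"ExactQualifier"`, `"CloseQualifier"`, `"BroadQualifier"`,
#'   `"NarrowQualifier"`.
#' @param created_by an [ao_agent()].
#' @param targets non-empty list of targets: [ao_document_ref()] objects
#'   (whole-document annotation) and/or selector objects.
#' @param created_on ISO-8601 UTC timestamp.
#' @param body optional annotation body text; markup is preserved
#'   verbatim as a plain literal.
#' @param topics optional list of [ao_term()] objects or
#'   `list(term =, level =)` entries; for a bare `ao_term` the level
#'   defaults to the level implied by `ann_type` (or `"related"`).
#' @param composed_types character vector of external class IRIs the
#'   annotation is additionally typed with (composition typing, e.g. a
#'   SWAN discourse class).
#' @param uri optional explicit IRI; minted when absent.
#' @param base_uri base namespace for minting.
#' @param seed optional integer for deterministic minting.
#' @param tagging optional [ao_tagging()] attached via the tagging hook.
#' @return an `ao_annotation` object whose invariants all hold.
#' @examples
#' doc <- ao_document_ref("http://ex.org/doc")
#' alice <- ao_agent("http://ex.org/alice", "person", "Alice")
#' new_annotation("Qualifier", alice, list(doc),
#'                topics = list(ao_term("http://purl.org/obo/owl/PRO#PRO_000013562")))
#' @export
new_annotation <- function(ann_type, created_by, targets,
                           created_on = ao_now(),
                           body = NULL, topics = NULL,
                           composed_types = character(0),
                           uri = NULL, base_uri = ao_default_base(),
                           seed = NULL, tagging = NULL) {
  ann_type <- match.arg(ann_type, AO_ANNOTATION_TYPES)
  if (!inherits(created_by, "ao_agent")) {
    ao_stop("`created_by` must be an ao_agent", class = "aotk_validation_error")
  }
  if (!is.list(targets) || length(targets) == 0L ||
      !all(vapply(targets, is_ao_target, logical(1L)))) {
    ao_stop("`targets` must be a non-empty list of document refs or selectors",
            class = "aotk_validation_error")
  }
  if (!is_iso8601(created_on)) {
    ao_stop("`created_on` must be ISO-8601", class = "aotk_validation_error")
  }
  if (!is.null(body) && !is_string(body)) {
    ao_stop("`body` must be a single string", class = "aotk_validation_error")
  }
  default_level <- qualifier_type_to_level(ann_type) %||% "related"
  topic_entries <- as_topic_entries(topics, default_level)
  if (ann_type %in% c("Note", "Errata", "Example", "Definition")) {
    if (is.null(body) || !nzchar(body)) {
      ao_stop(ann_type, " annotations require a non-empty body",
              class = "aotk_validation_error")
    }
  } else {
    has_body <- !is.null(body) && nzchar(body)
    if (length(topic_entries) == 0L && !has_body) {
      ao_stop("qualifier annotations need at least one topic or a free-text ",
              "body", class = "aotk_validation_error")
    }
  }
  if (!is.character(composed_types) ||
      (length(composed_types) > 0L && !all(is_absolute_iri(composed_types)))) {
    ao_stop("`composed_types` must be absolute IRIs",
            class = "aotk_validation_error")
  }
  if (!is.null(tagging) && !inherits(tagging, "ao_tagging")) {
    ao_stop("`tagging` must be an ao_tagging object",
            class = "aotk_validation_error")
  }
  if (is.null(uri)) uri <- mint_uri(base_uri, "annotation", seed = seed)
  ann <- structure(
    list(
      uri = uri,
      ann_type = ann_type,
      composed_types = composed_types,
      body = body,
      topics = topic_entries,
      targets = targets,
      created_by = created_by,
      created_on = created_on,
      curation_head = NULL,
      previous_version = NULL,
      version_number = NULL,
      supersedes = NULL,
      tagging = tagging
    ),
    class = "ao_annotation"
  )
  ann
}

#' Attach a topic term to an annotation at a graded meaning level
#'
#' Appends the term and refines the annotation's type to the qualifier
#' subtype matching `level` (`related` -> `Qualifier`, `exact` ->
#' `ExactQualifier`, `close` -> `CloseQualifier`, `broad` ->
#' `BroadQualifier`, `narrow` -> `NarrowQualifier`). When the annotation
#' already carries topics at another level, each topic keeps its own
#' level and the annotation's type reflects the newest addition.
#'
#' Non-qualifier annotations (e.g. a `Note`) refuse topics unless
#' `promote = TRUE`, in which case the annotation is re-typed into the
#' qualifier family.
#'
#' @param annotation an `ao_annotation`.
#' @param term an [ao_term()].
#' @param level one of `"related"`, `"exact"`, `"close"`, `"broad"`,
#'   `"narrow"`.
#' @param promote allow promoting a non-qualifier annotation.
#' @return a new `ao_annotation`; the input is not modified.
#' @export
add_topic <- function(annotation, term, level = "related", promote = FALSE) {
  stopifnot(inherits(annotation, "ao_annotation"))
  if (!inherits(term, "ao_term")) ao_stop("`term` must be an ao_term")
  if (!is_string(level) || !level %in% AO_MEANING_LEVELS) {
    ao_stop("unknown meaning level '", paste(level, collapse = ","), "'")
  }
  if (!annotation$ann_type %in% AO_QUALIFIER_TYPES) {
    if (!promote) {
      ao_stop("cannot add a topic to a ", annotation$ann_type,
              " annotation; set promote = TRUE to re-type it",
              class = "aotk_validation_error")
    }
  }
  out <- annotation
  out$topics <- c(out$topics, list(list(term = term, level = level)))
  out$ann_type <- level_to_qualifier_type(level)
  out
}

# ---------------------------------------------------------------------------
# Curation tokens

#' Create a curation token
#'
#' One curator judgment on an annotation: a status, the judging agent
#' and the judgment date, chained to the prior token (if any) via
#' `previous` — the RDF `pav:previousCuration` link. Status is an open
#' string; the core workflow statuses are `"created"`, `"accepted"`,
#' `"rejected"` and `"discussed"` (spelled exactly).
#'
#' @param status status string.
#' @param curated_by an [ao_agent()].
#' @param curated_on ISO-8601 UTC timestamp.
#' @param previous optional IRI of the prior token in the chain.
#' @param uri optional explicit IRI; minted when absent.
#' @param base_uri,seed minting controls as in [new_annotation()].
#' @return an `ao_curation_token` object.
#' @export
ao_curation_token <- function(status, curated_by, curated_on = ao_now(),
                              previous = NULL, uri = NULL,
                              base_uri = ao_default_base(), seed = NULL) {
  if (!is_string(status) || !nzchar(status)) {
    ao_stop("`status` must be a non-empty string")
  }
  if (!inherits(curated_by, "ao_agent")) {
    ao_stop("`curated_by` must be an ao_agent")
  }
  if (!is_iso8601(curated_on)) ao_stop("`curated_on` must be ISO-8601")
  if (!is.null(previous) && (!is_string(previous) || !is_absolute_iri(previous))) {
    ao_stop("`previous` must be an absolute IRI")
  }
  if (is.null(uri)) uri <- mint_uri(base_uri, "curation", seed = seed)
  structure(
    list(uri = uri, status = status, curated_by = curated_by,
         curated_on = curated_on, previous = previous),
    class = "ao_curation_token"
  )
}

# ---------------------------------------------------------------------------
# Annotation sets

#' Create an annotation set
#'
#' A versionable, branchable container of annotation URIs used to group
#' annotations by a criterion (topic, provenance, publication status).
#'
#' @param item_uris character vector of annotation IRIs; duplicates are
#'   rejected.
#' @param created_by an [ao_agent()].
#' @param created_on ISO-8601 UTC timestamp.
#' @param previous_version optional IRI of the prior version of this set.
#' @param version_number optional integer >= 1; required when
#'   `previous_version` is given.
#' @param derived_from optional IRI of the set this one was branched
#'   from (`pav:derivedFrom`).
#' @param uri,base_uri,seed minting controls as in [new_annotation()].
#' @return an `ao_annotation_set` object.
#' @export
ao_annotation_set <- function(item_uris = character(0), created_by,
                              created_on = ao_now(),
                              previous_version = NULL, version_number = NULL,
                              derived_from = NULL, uri = NULL,
                              base_uri = ao_default_base(), seed = NULL) {
  if (!is.character(item_uris)) ao_stop("`item_uris` must be character")
  if (anyDuplicated(item_uris)) {
    ao_stop("`item_uris` contains duplicates", class = "aotk_validation_error")
  }
  if (!inherits(created_by, "ao_agent")) {
    ao_stop("`created_by` must be an ao_agent")
  }
  if (!is_iso8601(created_on)) ao_stop("`created_on` must be ISO-8601")
  if (!is.null(version_number) &&
      (!is_count(version_number) || version_number < 1)) {
    ao_stop("`version_number` must be an integer >= 1")
  }
  if (is.null(uri)) uri <- mint_uri(base_uri, "set", seed = seed)
  structure(
    list(uri = uri, item_uris = item_uris, created_by = created_by,
         created_on = created_on, previous_version = previous_version,
         version_number = version_number, derived_from = derived_from),
    class = "ao_annotation_set"
  )
}

# ---------------------------------------------------------------------------
# Validation

violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(0), rule = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Validate a domain object against its structural invariants
#'
#' Violations are returned as data, not raised: each row names the
#' offending field and the rule it breaks. An empty data frame means the
#' object is valid. Constructors enforce the same rules eagerly, so this
#' is chiefly useful on objects assembled by hand, parsed from RDF, or
#' mutated in place.
#'
#' @param entity an `ao_annotation`, `ao_annotation_set`,
#'   `ao_curation_token`, `ao_agent`, `ao_document_ref` or selector
#'   object.
#' @param ... passed to methods.
#' @return a data.frame with columns `field`, `rule`, `message`; zero
#'   rows iff the entity is valid.
#' @export
ao_validate <- function(entity, ...) UseMethod("ao_validate")

#' @export
ao_validate.default <- function(entity, ...) {
  violation("entity", "known_type",
            paste0("cannot validate object of class ",
                   paste(class(entity), collapse = "/")))
}

#' @export
ao_validate.ao_agent <- function(entity, ...) {
  v <- no_violations()
  if (!is_absolute_iri(entity$uri)) {
    v <- rbind(v, violation("uri", "absolute_iri", "agent uri not absolute"))
  }
  if (!entity$kind %in% AO_AGENT_KINDS) {
    v <- rbind(v, violation("kind", "enum", paste0("unknown agent kind '",
                                                   entity$kind, "'")))
  }
  v
}

#' @export
ao_validate.ao_document_ref <- function(entity, ...) {
  v <- no_violations()
  if (!is_absolute_iri(entity$page_uri)) {
    v <- rbind(v, violation("page_uri", "absolute_iri", "page uri not absolute"))
  }
  if (length(entity$versions) > 0L) {
    times <- vapply(entity$versions, `[[`, character(1L), "accessed_on")
    if (is.unsorted(times)) {
      v <- rbind(v, violation("versions", "sorted_by_accessed_on",
                              "versions not in non-decreasing access order"))
    }
    for (sv in entity$versions) {
      if (identical(sv$uri, entity$page_uri)) {
        v <- rbind(v, violation("versions", "distinct_version_uri",
                                "version uri equals stable page uri"))
      }
    }
  }
  v
}

#' @export
ao_validate.ao_annotation <- function(entity, ...) {
  v <- no_violations()
  if (!is_absolute_iri(entity$uri)) {
    v <- rbind(v, violation("uri", "absolute_iri", "annotation uri not absolute"))
  }
  if (!entity$ann_type %in% AO_ANNOTATION_TYPES) {
    v <- rbind(v, violation("ann_type", "enum",
                            paste0("unknown annotation type '",
                                   entity$ann_type, "'")))
  }
  if (length(entity$targets) == 0L) {
    v <- rbind(v, violation("targets", "non_empty",
                            "annotation has no target"))
  } else if (!all(vapply(entity$targets, is_ao_target, logical(1L)))) {
    v <- rbind(v, violation("targets", "target_type",
                            "targets must be document refs or selectors"))
  }
  has_body <- !is.null(entity$body) && nzchar(entity$body)
  if (entity$ann_type %in% c("Note", "Errata", "Example", "Definition") &&
      !has_body) {
    v <- rbind(v, violation("body", "non_empty_body",
                            paste0(entity$ann_type, " requires a body")))
  }
  if (entity$ann_type %in% AO_QUALIFIER_TYPES &&
      length(entity$topics) == 0L && !has_body) {
    v <- rbind(v, violation("topics", "topic_or_body",
                            "qualifier needs a topic or a free-text body"))
  }
  if (!is.null(entity$previous_version) && is.null(entity$version_number)) {
    v <- rbind(v, violation("version_number", "versioned_with_number",
                            "previous_version set but version_number absent"))
  }
  if (!is.null(entity$version_number) &&
      (!is_count(entity$version_number) || entity$version_number < 1)) {
    v <- rbind(v, violation("version_number", "positive_integer",
                            "version_number must be an integer >= 1"))
  }
  if (!is.null(entity$created_by)) {
    v <- rbind(v, ao_validate(entity$created_by))
  }
  if (!is.null(entity$curation_head)) {
    v <- rbind(v, ao_validate(entity$curation_head))
  }
  v
}

#' @export
ao_validate.ao_curation_token <- function(entity, ..., chain = NULL) {
  v <- no_violations()
  if (!is_absolute_iri(entity$uri)) {
    v <- rbind(v, violation("uri", "absolute_iri", "token uri not absolute"))
  }
  if (!is_string(entity$status) || !nzchar(entity$status)) {
    v <- rbind(v, violation("status", "non_empty", "status must be non-empty"))
  } else if (tolower(entity$status) %in% AO_CORE_CURATION_STATUSES &&
             !entity$status %in% AO_CORE_CURATION_STATUSES) {
    v <- rbind(v, violation("status", "core_spelling",
                            paste0("core status must be spelled exactly: '",
                                   tolower(entity$status), "'")))
  }
  if (!is_iso8601(entity$curated_on)) {
    v <- rbind(v, violation("curated_on", "iso8601",
                            "curated_on is not ISO-8601"))
  }
  # cycle detection over a supplied chain context (uri -> token)
  if (!is.null(chain)) {
    seen <- character(0)
    cur <- entity
    while (!is.null(cur)) {
      if (cur$uri %in% seen) {
        v <- rbind(v, violation("previous", "acyclic",
                                paste0("curation chain cycle at ", cur$uri)))
        break
      }
      seen <- c(seen, cur$uri)
      cur <- if (!is.null(cur$previous)) chain[[cur$previous]] else NULL
    }
  }
  v
}

#' @export
ao_validate.ao_annotation_set <- function(entity, ...) {
  v <- no_violations()
  if (!is_absolute_iri(entity$uri)) {
    v <- rbind(v, violation("uri", "absolute_iri", "set uri not absolute"))
  }
  if (anyDuplicated(entity$item_uris)) {
    v <- rbind(v, violation("item_uris", "no_duplicates",
                            "duplicate annotation URIs in set"))
  }
  if (!is.null(entity$previous_version) && is.null(entity$version_number)) {
    v <- rbind(v, violation("version_number", "versioned_with_number",
                            "previous_version set but version_number absent"))
  }
  v
}

#' @export
ao_validate.ao_selector <- function(entity, ...) {
  validate_selector(entity)
}

#' @export
print.ao_annotation <- function(x, ...) {
  cat("<ao_annotation> ", x$uri, "\n", sep = "")
  cat("  type:    aot:", x$ann_type, "\n", sep = "")
  if (!is.null(x$body)) cat("  body:    ", substr(x$body, 1, 60), "\n", sep = "")
  if (length(x$topics)) {
    for (t in x$topics) {
      cat("  topic:   ", t$term$uri, " [", t$level, "]\n", sep = "")
    }
  }
  cat("  targets: ", length(x$targets), "\n", sep = "")
  invisible(x)
}
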