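#' Namespace registry for Annotation Ontology graphs
#'
#' The registry seeds the nine prefix bindings the vocabulary is built on
#' (core `ao`, selectors `aos`, types `aot`, Annotea integration `aoa`,
#' FOAF integration `aof`, provenance `pav`, SWAN agents `swan-agent`,
#' SWAN `swan`, and the original Annotea namespace `ann`), plus
#' well-known convenience prefixes (`rdf`, `rdfs`, `owl`, `skos`, `foaf`,
#' `sioc`, `moat`, `tags`, `PRO`, `xsd`).
#'
#' @param extra named character vector of additional prefix -> IRI
#'   bindings; may not override a seeded binding with a different IRI.
#' @return a named character vector of class `ao_namespaces`, prefix ->
#'   namespace IRI.
#' @examples
#' ns <- ao_namespaces()
#' ns[["ao"]]
#' @export
ao_namespaces <- function(extra = NULL) {
  ns <- c(
    "ao"         = "http://purl.org/ao/",
    "aos"        = "http://purl.org/ao/selectors/",
    "aot"        = "http://purl.org/ao/types/",
    "aoa"        = "http://purl.org/ao/annotea/",
    "aof"        = "http://purl.org/ao/foaf/",
    "pav"        = "http://purl.org/pav/2.0/",
    "swan-agent" = "http://purl.org/swan/2.0/agents/",
    "swan"       = "http://purl.org/swan/2.0/",
    "ann"        = "http://www.w3.org/2000/10/annotation-ns#",
    "PRO"        = "http://purl.org/obo/owl/PRO#",
    "rdf"        = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "rdfs"       = "http://www.w3.org/2000/01/rdf-schema#",
    "owl"        = "http://www.w3.org/2002/07/owl#",
    "xsd"        = "http://www.w3.org/2001/XMLSchema#",
    "skos"       = "http://www.w3.org/2004/02/skos/core#",
    "foaf"       = "http://xmlns.com/foaf/0.1/",
    "sioc"       = "http://rdfs.org/sioc/ns#",
    "moat"       = "http://moat-project.org/ns#",
    "tags"       = "http://www.holygoat.co.uk/owl/redwood/0.1/tags/"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      ao_stop("`extra` namespace bindings must be named")
    }
    for (p in names(extra)) {
      if (p %in% names(ns) && !identical(unname(ns[[p]]), unname(extra[[p]]))) {
        ao_stop("cannot rebind seeded prefix '", p, "'")
      }
    }
    ns <- c(ns, extra[setdiff(names(extra), names(ns))])
  }
  class(ns) <- c("ao_namespaces", class(ns))
  ns
}

# The nine seeded bindings that must always be present, byte-exact.
ao_core_prefixes <- function() {
  c("ao", "aos", "aot", "aoa", "aof", "pav", "swan-agent", "swan", "ann")
}

# Expand a CURIE such as "ao:hasTopic" against the registry.
ns_expand <- function(curie, ns = ao_namespaces()) {
  vapply(curie, function(x) {
    m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", x))[[1]]
    if (length(m) == 3L && m[[2]] %in% names(ns)) {
      paste0(ns[[m[[2]]]], m[[3]])
    } else {
      x
    }
  }, character(1L), USE.NAMES = FALSE)
}

# Compact an absolute IRI to a CURIE when a registered prefix matches;
# longest namespace wins. Returns the IRI unchanged when none matches or
# the local part is not a valid prefixed-name local part.
ns_compact <- function(iri, ns = ao_namespaces()) {
  ord <- order(nchar(ns), decreasing = TRUE)
  pres <- names(ns)[ord]
  bases <- unname(ns)[ord]
  vapply(iri, function(x) {
    for (i in seq_along(bases)) {
      if (startsWith(x, bases[[i]])) {
        local <- substring(x, nchar(bases[[i]]) + 1L)
        if (grepl("^[A-Za-z0-9_]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", local) ||
            local == "") {
          return(paste0(pres[[i]], ":", local))
        }
      }
    }
    x
  }, character(1L), USE.NAMES = FALSE)
}

#' The fixed AO vocabulary emitted by this package
#'
#' Every class and property in the `ao`, `aos`, `aot` and `aof`
#' namespaces that serialization may emit. Output in those namespaces is
#' restricted to this table; parsing warns about any stray term.
#'
#' @return a data.frame with columns `term` (CURIE), `iri`, and `role`
#'   (`"class"` or `"property"`).
#' @export
ao_vocabulary <- function() {
  ns <- ao_namespaces()
  rows <- rbind(
    c("ao:Annotation", "class"),
    c("ao:AnnotationSet", "class"),
    c("ao:AnnotationDocument", "class"),
    c("ao:Selector", "class"),
    c("ao:hasTopic", "property"),
    c("ao:context", "property"),
    c("ao:item", "property"),
    c("ao:onDocument", "property"),
    c("ao:onSourceVersion", "property"),
    c("ao:hasSourceDocument", "property"),
    c("ao:hasCuration", "property"),
    c("ao:curationStatus", "property"),
    c("ao:contentDigest", "property"),
    c("ao:body", "property"),
    c("ao:hasTagging", "property"),
    c("ao:hasRelatedMeaning", "property"),
    c("ao:hasExactMeaning", "property"),
    c("ao:hasCloseMeaning", "property"),
    c("ao:hasNarrowerMeaningThan", "property"),
    c("ao:hasBroaderMeaningThan", "property"),
    c("aos:TextSelector", "class"),
    c("aos:PrefixPostfixTextSelector", "class"),
    c("aos:OffsetRangeTextSelector", "class"),
    c("aos:XPointerSelector", "class"),
    c("aos:ImageSelector", "class"),
    c("aos:InitEndCornerSelector", "class"),
    c("aos:prefix", "property"),
    c("aos:exact", "property"),
    c("aos:postfix", "property"),
    c("aos:offset", "property"),
    c("aos:range", "property"),
    c("aos:expression", "property"),
    c("aos:xinit", "property"),
    c("aos:yinit", "property"),
    c("aos:xend", "property"),
    c("aos:yend", "property"),
    c("aot:Note", "class"),
    c("aot:Errata", "class"),
    c("aot:Example", "class"),
    c("aot:Definition", "class"),
    c("aot:Qualifier", "class"),
    c("aot:ExactQualifier", "class"),
    c("aot:CloseQualifier", "class"),
    c("aot:BroadQualifier", "class"),
    c("aot:NarrowQualifier", "class"),
    c("aof:annotatesDocument", "property"),
    c("aof:Agent", "class"),
    c("aof:Group", "class"),
    c("aof:Organization", "class")
  )
  data.frame(
    term = rows[, 1L],
    iri = ns_expand(rows[, 1L], ns),
    role = rows[, 2L],
    stringsAsFactors = FALSE
  )
}
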