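# Shared generators and independent brute-force oracles. The oracles
# deliberately avoid the package's own resolution / inference code
# paths: they are naive re-implementations used to cross-check results.

`%||%` <- function(a, b) if (is.null(a)) b else a

t_agent <- function(n = 1L, kind = "person") {
  ao_agent(paste0("http://test.org/agent/", n), kind, paste0("Agent ", n))
}

t_doc <- function(n = 1L, n_versions = 0L) {
  versions <- lapply(seq_len(n_versions), function(i) {
    ao_source_version(
      sprintf("http://test.org/doc/%d?v=%d", n, i),
      sprintf("2024-01-%02dT00:00:00Z", i),
      content_digest(sprintf("content %d.%d", n, i)))
  })
  ao_document_ref(paste0("http://test.org/doc/", n), versions)
}

t_term <- function(n = 1L) {
  ao_term(paste0("http://test.org/vocab#T", n), paste0("Term ", n))
}

# One annotation with every selector type plus a whole-document target.
t_full_annotation <- function(seed) {
  doc <- t_doc(seed, n_versions = 2L)
  sels <- list(
    ao_text_quote_selector("exact text", "some ", " after",
                           on_document = doc$page_uri,
                           on_version = doc$versions[[1L]]$uri,
                           seed = seed * 10L + 1L),
    ao_offset_selector(5L + seed %% 7L, 4L, on_document = doc$page_uri,
                       seed = seed * 10L + 2L),
    ao_xpointer_selector(sprintf("xpointer(string-range(/html[1], %d, 5))",
                                 seed),
                         on_document = doc$page_uri, seed = seed * 10L + 3L),
    ao_image_box_selector(0L, 0L, 10L + seed %% 5L, 20L,
                          on_document = doc$page_uri, seed = seed * 10L + 4L)
  )
  lvl <- aotk:::AO_MEANING_LEVELS[[1L + seed %% 5L]]
  new_annotation(
    aotk:::level_to_qualifier_type(lvl), t_agent(seed), c(list(doc), sels),
    created_on = "2024-02-01T12:00:00Z",
    body = paste("body", seed),
    topics = list(list(term = t_term(seed), level = lvl)),
    seed = seed * 10L + 5L)
}

# A randomized entity bundle: annotations (all selector types), a
# curation chain of length <= 5, and a branched pair of sets.
t_entity_bundle <- function(seed) {
  set.seed(seed)
  anns <- lapply(seed * 100L + seq_len(1L + seed %% 3L), t_full_annotation)
  chain_len <- sample.int(5L, 1L)
  tokens <- list()
  prev <- NULL
  for (i in seq_len(chain_len)) {
    tk <- ao_curation_token(
      sample(c("created", "accepted", "rejected", "discussed"), 1L),
      t_agent(seed), sprintf("2024-03-%02dT00:00:00Z", i),
      previous = prev, seed = seed * 100L + 50L + i)
    tokens[[i]] <- tk
    prev <- tk$uri
  }
  set1 <- ao_annotation_set(vapply(anns, `[[`, character(1L), "uri"),
                            t_agent(seed), "2024-04-01T00:00:00Z",
                            seed = seed * 100L + 80L)
  set2 <- ao_annotation_set(set1$item_uris, t_agent(seed + 1L),
                            "2024-04-02T00:00:00Z",
                            derived_from = set1$uri,
                            seed = seed * 100L + 81L)
  c(anns, tokens, list(set1, set2))
}

# Brute-force occurrence scan: all 1-based positions where `needle`
# occurs in `hay`, by direct substring comparison at every position.
brute_occurrences <- function(hay, needle) {
  nh <- nchar(hay)
  nn <- nchar(needle)
  if (nn == 0L || nn > nh) return(integer(0))
  which(vapply(seq_len(nh - nn + 1L), function(i) {
    substr(hay, i, i + nn - 1L) == needle
  }, logical(1L)))
}

# Brute-force cross-ontology oracle: enumerate all unordered pairs of
# (term, level) units per anchor key and derive the expected mapping
# set, independently of infer_cross_ontology's implementation.
brute_mappings <- function(annotations) {
  skos <- function(l) paste0("http://www.w3.org/2004/02/skos/core#", l)
  lv2p <- c(related = "relatedMatch", exact = "exactMatch",
            close = "closeMatch", broad = "broadMatch",
            narrow = "narrowMatch")
  units <- list()
  for (ann in annotations) {
    if (!ann$ann_type %in% c("Qualifier", "ExactQualifier", "CloseQualifier",
                             "BroadQualifier", "NarrowQualifier")) next
    for (tg in ann$targets) {
      key <- if (inherits(tg, "ao_document_ref")) paste0("doc:", tg$page_uri)
             else paste0("sel:", tg$uri)
      for (tp in ann$topics) {
        units[[length(units) + 1L]] <-
          list(key = key, term = tp$term$uri, level = tp$level)
      }
    }
  }
  found <- character(0)
  for (i in seq_along(units)) {
    for (j in seq_along(units)) {
      if (i == j) next
      A <- units[[i]]; B <- units[[j]]
      if (A$key != B$key || A$term == B$term) next
      trip <- if (A$level == "exact" && B$level == "exact") {
        c(min(A$term, B$term), skos("exactMatch"), max(A$term, B$term))
      } else if (A$level == "exact") {
        p <- lv2p[[B$level]]
        if (p %in% c("relatedMatch", "closeMatch")) {
          c(min(A$term, B$term), skos(p), max(A$term, B$term))
        } else c(A$term, skos(p), B$term)
      } else if (B$level == "exact") {
        next  # covered when the loop visits (j, i)
      } else {
        c(min(A$term, B$term), skos("relatedMatch"), max(A$term, B$term))
      }
      found <- union(found, paste(trip, collapse = " "))
    }
  }
  sort(found)
}

mapping_keys <- function(m) {
  sort(paste(m$subject_term, m$skos_property, m$object_term))
}

# Random qualifier group sharing one anchor: n annotations, each with
# one topic at a random level over a small term pool (collisions on
# purpose).
t_qualifier_group <- function(seed) {
  set.seed(seed)
  doc <- t_doc(seed)
  n <- sample(2:5, 1L)
  use_sel <- runif(1) < 0.5
  anchor <- if (use_sel) {
    ao_text_quote_selector(paste0("anchor", seed), on_document = doc$page_uri,
                           seed = seed * 7L)
  } else doc
  lapply(seq_len(n), function(i) {
    lvl <- sample(c("related", "exact", "close", "broad", "narrow"), 1L)
    term <- t_term(sample.int(4L, 1L))
    new_annotation(aotk:::level_to_qualifier_type(lvl), t_agent(i),
                   list(anchor),
                   topics = list(list(term = term, level = lvl)),
                   seed = seed * 1000L + i)
  })
}
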