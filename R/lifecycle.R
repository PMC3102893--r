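# Append-only annotation store with curation chains, versioning,
# branching and supersession. The store is an environment (reference
# semantics): records are only ever added, never overwritten or
# removed — new versions get new URIs, and the record multiset grows
# monotonically under every operation.

#' Create an empty annotation store
#'
#' @param version_on_curation when `TRUE`, [add_curation()] also mints
#'   a new annotation version whose `curation_head` points at the new
#'   token; by default curation heads are tracked store-side and the
#'   annotation record is left untouched.
#' @param base_uri base namespace for URIs minted by lifecycle
#'   operations.
#' @return an `ao_store` object.
#' @export
ao_store <- function(version_on_curation = FALSE,
                     base_uri = ao_default_base()) {
  e <- new.env(parent = emptyenv())
  e$records <- list()          # uri -> entity
  e$heads <- list()            # annotation uri -> head token uri
  e$tokens_by_ann <- list()    # annotation uri -> character vector, in order
  e$config <- list(version_on_curation = isTRUE(version_on_curation),
                   base_uri = base_uri)
  class(e) <- "ao_store"
  e
}

#' @export
print.ao_store <- function(x, ...) {
  cat("<ao_store> ", length(x$records), " records\n", sep = "")
  invisible(x)
}

#' Number of records in a store
#' @param store an `ao_store`.
#' @return integer record count.
#' @export
store_size <- function(store) length(store$records)

#' All URIs currently retrievable from a store
#' @param store an `ao_store`.
#' @return character vector of URIs.
#' @export
store_uris <- function(store) names(store$records)

#' Add an entity to a store
#'
#' Append-only: adding a URI that already exists is an error; records
#' are never overwritten.
#'
#' @param store an `ao_store`.
#' @param entity a domain object with a `uri` field.
#' @return the entity, invisibly.
#' @export
store_add <- function(store, entity) {
  stopifnot(inherits(store, "ao_store"))
  uri <- entity$uri
  if (!is_string(uri)) ao_stop("entity has no uri")
  if (uri %in% names(store$records)) {
    ao_stop("store is append-only: '", uri, "' already exists",
            class = "aotk_store_error")
  }
  store$records[[uri]] <- entity
  invisible(entity)
}

#' Retrieve a record by URI
#' @param store an `ao_store`.
#' @param uri record URI.
#' @return the stored entity, or error if absent.
#' @export
store_get <- function(store, uri) {
  rec <- store$records[[uri]]
  if (is.null(rec)) ao_stop("no record '", uri, "' in store",
                            class = "aotk_store_error")
  rec
}

require_annotation <- function(store, uri) {
  rec <- store_get(store, uri)
  if (!inherits(rec, "ao_annotation")) {
    ao_stop("'", uri, "' is not an annotation", class = "aotk_store_error")
  }
  rec
}

# ---------------------------------------------------------------------------
# Curation

#' Record a curator judgment on an annotation
#'
#' Appends a new curation token whose `previous` pointer links to the
#' current head of the annotation's chain. A judgment dated earlier
#' than the current head is accepted but triggers a warning (the
#' curation story is assumed linear in time). Existing token records
#' are never modified.
#'
#' @param store an `ao_store`.
#' @param annotation_uri URI of an annotation in the store.
#' @param status judgment string; core workflow values are
#'   `"created"`, `"accepted"`, `"rejected"`, `"discussed"`.
#' @param curator the judging [ao_agent()].
#' @param date ISO-8601 timestamp of the judgment.
#' @param link_previous set `FALSE` to omit the `previous` pointer
#'   (chain order then relies on dates).
#' @return the new `ao_curation_token`.
#' @export
add_curation <- function(store, annotation_uri, status, curator,
                         date = ao_now(), link_previous = TRUE) {
  stopifnot(inherits(store, "ao_store"))
  require_annotation(store, annotation_uri)
  head_uri <- store$heads[[annotation_uri]]
  if (!is.null(head_uri)) {
    head_tok <- store_get(store, head_uri)
    if (date < head_tok$curated_on) {
      ao_warn("curation dated '", date, "' precedes current head ('",
              head_tok$curated_on, "'); appending anyway")
    }
  }
  tok <- ao_curation_token(
    status = status, curated_by = curator, curated_on = date,
    previous = if (link_previous) head_uri else NULL,
    base_uri = store$config$base_uri)
  store_add(store, tok)
  store$heads[[annotation_uri]] <- tok$uri
  store$tokens_by_ann[[annotation_uri]] <-
    c(store$tokens_by_ann[[annotation_uri]], tok$uri)
  if (store$config$version_on_curation) {
    nv <- new_annotation_version(store, annotation_uri, edits = list())
    nv$curation_head <- tok
    store$records[[nv$uri]] <- nv
    store$heads[[nv$uri]] <- tok$uri
    store$tokens_by_ann[[nv$uri]] <- store$tokens_by_ann[[annotation_uri]]
  }
  tok
}

#' Curation timeline of an annotation, oldest judgment first
#'
#' When every token carries a `previous` pointer the chain itself
#' fixes the order; when pointers are absent the order falls back to
#' the curation dates, with ties broken by token URI. A cyclic chain
#' is an error.
#'
#' @param store an `ao_store`.
#' @param annotation_uri annotation URI.
#' @return list of `ao_curation_token`, oldest first (empty when
#'   uncurated).
#' @export
curation_timeline <- function(store, annotation_uri) {
  stopifnot(inherits(store, "ao_store"))
  tok_uris <- store$tokens_by_ann[[annotation_uri]]
  if (is.null(tok_uris) || length(tok_uris) == 0L) return(list())
  tokens <- lapply(tok_uris, store_get, store = store)
  names(tokens) <- tok_uris
  prevs <- lapply(tokens, `[[`, "previous")
  n_with_prev <- sum(!vapply(prevs, is.null, logical(1L)))
  head_uri <- store$heads[[annotation_uri]]
  if (n_with_prev == length(tokens) - 1L && !is.null(head_uri)) {
    # complete chain: walk previous pointers from the head
    chain <- list()
    seen <- character(0)
    cur <- head_uri
    while (!is.null(cur)) {
      if (cur %in% seen) {
        ao_stop("cyclic curation chain at '", cur, "'",
                class = "aotk_cycle_error")
      }
      seen <- c(seen, cur)
      tk <- store_get(store, cur)
      chain <- c(chain, list(tk))
      cur <- tk$previous
    }
    if (length(chain) == length(tokens)) return(rev(chain))
  }
  # fallback: date order, ties by URI
  ord <- order(vapply(tokens, `[[`, character(1L), "curated_on"),
               vapply(tokens, `[[`, character(1L), "uri"))
  unname(tokens[ord])
}

#' Effective curation status of an annotation
#'
#' The status of the newest curation token, or `"uncurated"` when the
#' annotation has no tokens.
#'
#' @param store an `ao_store`.
#' @param annotation_uri annotation URI.
#' @return status string.
#' @export
effective_status <- function(store, annotation_uri) {
  tl <- curation_timeline(store, annotation_uri)
  if (length(tl) == 0L) return("uncurated")
  tl[[length(tl)]]$status
}

# ---------------------------------------------------------------------------
# Versioning

MUTABLE_ANNOTATION_FIELDS <- c("body", "topics", "targets", "ann_type")

#' Create a new version of an annotation
#'
#' The new record gets a fresh URI, `previous_version` pointing at the
#' old one, and `version_number` incremented (an unversioned original
#' counts as version 1). Only content fields (`body`, `topics`,
#' `targets`, `ann_type`) may be edited; provenance is immutable.
#'
#' @param store an `ao_store`.
#' @param annotation_uri URI of the annotation to version.
#' @param edits named list of replacement values for mutable fields.
#' @return the new `ao_annotation` (already stored).
#' @export
new_annotation_version <- function(store, annotation_uri, edits = list()) {
  old <- require_annotation(store, annotation_uri)
  if (length(edits)) {
    bad <- setdiff(names(edits), MUTABLE_ANNOTATION_FIELDS)
    if (length(bad)) {
      ao_stop("cannot edit provenance or identity field(s): ",
              paste(bad, collapse = ", "), class = "aotk_store_error")
    }
  }
  new <- old
  for (f in names(edits)) new[[f]] <- edits[[f]]
  if ("topics" %in% names(edits)) {
    new$topics <- as_topic_entries(edits$topics,
                                   qualifier_type_to_level(new$ann_type) %||%
                                     "related")
  }
  new$uri <- mint_uri(store$config$base_uri, "annotation")
  new$previous_version <- old$uri
  new$version_number <- as.integer(old$version_number %||% 1L) + 1L
  rep <- ao_validate(new)
  if (nrow(rep)) {
    ao_stop("edited annotation is invalid: ", rep$message[[1L]],
            class = "aotk_validation_error")
  }
  store_add(store, new)
  new
}

#' Supersede an annotation with a replacement
#'
#' The replacement records `supersedes = old_uri`; the superseded
#' annotation remains in the store and stays retrievable, keeping the
#' knowledge base monotonic. The canonical use is enriching a bare
#' tag-style qualifier with a semantic topic term.
#'
#' @param store an `ao_store`.
#' @param old_uri URI of the annotation being superseded.
#' @param new_annotation the replacement `ao_annotation` (not yet in
#'   the store).
#' @return the stored replacement annotation.
#' @export
supersede <- function(store, old_uri, new_annotation) {
  stopifnot(inherits(store, "ao_store"),
            inherits(new_annotation, "ao_annotation"))
  require_annotation(store, old_uri)
  if (identical(old_uri, new_annotation$uri)) {
    ao_stop("an annotation cannot supersede itself",
            class = "aotk_store_error")
  }
  rep <- ao_validate(new_annotation)
  if (nrow(rep)) {
    ao_stop("replacement annotation is invalid: ", rep$message[[1L]],
            class = "aotk_validation_error")
  }
  new_annotation$supersedes <- old_uri
  store_add(store, new_annotation)
  new_annotation
}

#' Version an annotation set by changing its membership
#'
#' A new set record is minted with `previous_version` pointing to the
#' old one and `version_number` incremented; the old version keeps its
#' membership. Removing items is permitted but warned against — the
#' recommended practice is to reject an item through curation rather
#' than delete it, keeping the set's history monotonic.
#'
#' @param store an `ao_store`.
#' @param set_uri URI of the set to version.
#' @param add_items annotation URIs to add.
#' @param remove_items annotation URIs to remove (must be members).
#' @return the new `ao_annotation_set` (already stored).
#' @export
version_set <- function(store, set_uri, add_items = character(0),
                        remove_items = character(0)) {
  old <- store_get(store, set_uri)
  if (!inherits(old, "ao_annotation_set")) {
    ao_stop("'", set_uri, "' is not an annotation set",
            class = "aotk_store_error")
  }
  missing_items <- setdiff(remove_items, old$item_uris)
  if (length(missing_items)) {
    ao_stop("cannot remove non-member item(s): ",
            paste(missing_items, collapse = ", "),
            class = "aotk_store_error")
  }
  if (length(remove_items)) {
    ao_warn("removing items from a set; prefer rejecting them through ",
            "curation so the history stays monotonic")
  }
  items <- union(setdiff(old$item_uris, remove_items), add_items)
  new <- old
  new$uri <- mint_uri(store$config$base_uri, "set")
  new$item_uris <- items
  new$previous_version <- old$uri
  new$version_number <- as.integer(old$version_number %||% 1L) + 1L
  store_add(store, new)
  new
}

#' Branch (derive) an annotation set
#'
#' Creates a new set with identical membership, `derived_from`
#' pointing at the source, a fresh version lineage (no
#' `previous_version`, `version_number` 1) and the new owner as
#' creator — so contributions on the branch are attributed correctly
#' and evolve independently of the source lineage.
#'
#' @param store an `ao_store`.
#' @param set_uri URI of the set to branch.
#' @param new_owner the branching [ao_agent()].
#' @param created_on timestamp for the branch.
#' @return the new `ao_annotation_set` (already stored).
#' @export
derive_set <- function(store, set_uri, new_owner, created_on = ao_now()) {
  old <- store_get(store, set_uri)
  if (!inherits(old, "ao_annotation_set")) {
    ao_stop("'", set_uri, "' is not an annotation set",
            class = "aotk_store_error")
  }
  stopifnot(inherits(new_owner, "ao_agent"))
  new <- ao_annotation_set(
    item_uris = old$item_uris, created_by = new_owner,
    created_on = created_on, previous_version = NULL, version_number = 1L,
    derived_from = old$uri, base_uri = store$config$base_uri)
  store_add(store, new)
  new
}

#' Walk a version lineage, newest first
#'
#' Follows `previous_version` pointers from `uri` until they run out
#' or leave the store; a cycle is an error.
#'
#' @param store an `ao_store`.
#' @param uri starting record URI.
#' @return list of records, newest first.
#' @export
version_lineage <- function(store, uri) {
  chain <- list()
  seen <- character(0)
  cur <- uri
  while (!is.null(cur) && cur %in% names(store$records)) {
    if (cur %in% seen) {
      ao_stop("cyclic version lineage at '", cur, "'",
              class = "aotk_cycle_error")
    }
    seen <- c(seen, cur)
    rec <- store$records[[cur]]
    chain <- c(chain, list(rec))
    cur <- rec$previous_version
  }
  chain
}

#' Validate store-wide referential integrity
#'
#' Dangling `previous_version` / `derived_from` / `supersedes` /
#' `previous` references (e.g. from partially imported graphs) are
#' reported as warnings rows, not errors.
#'
#' @param store an `ao_store`.
#' @return data.frame with columns `uri`, `field`, `target` listing
#'   dangling references (zero rows when fully resolvable).
#' @export
store_dangling_refs <- function(store) {
  rows <- list()
  for (uri in names(store$records)) {
    rec <- store$records[[uri]]
    for (f in c("previous_version", "derived_from", "supersedes", "previous")) {
      tgt <- rec[[f]]
      if (!is.null(tgt) && is_string(tgt) && !tgt %in% names(store$records)) {
        rows[[length(rows) + 1L]] <- data.frame(
          uri = uri, field = f, target = tgt, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(list(data.frame(uri = character(0), field = character(0),
                                   target = character(0))), rows))
}
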