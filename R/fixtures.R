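# Synthetic fixture documents for anchoring experiments. A fixture is a
# structural representation (paragraphs of words with planted entity
# mentions) from which raw markup is rendered; mutations operate on the
# structure, so the expected anchoring outcome of each mutation class is
# known by construction rather than re-derived from string matching.

FILLER_WORDS <- c(
  "the", "protein", "pathway", "expression", "of", "in", "cells",
  "signal", "binding", "results", "cleaves", "substrate", "membrane",
  "analysis", "suggests", "that", "activity", "was", "observed",
  "during", "response", "to", "stress", "levels", "were", "measured",
  "and", "compared", "with", "control", "samples", "under", "varied",
  "conditions", "a", "significant", "increase", "neuronal", "tissue",
  "model", "data", "indicate", "role", "for", "regulation", "process",
  "between", "domain", "complex", "study", "shows", "enzyme", "function"
)

MENTION_STEMS <- c("BACE", "APP", "PSEN", "TAU", "SNCA", "GRN", "TREM",
                   "ADAM", "MAPT", "NCT")

AO_MUTATION_CLASSES <- c("markup_churn", "distant_edit", "context_edit",
                         "duplicate_paragraph", "delete_paragraph")

rand_words <- function(n) sample(FILLER_WORDS, n, replace = TRUE)

#' Generate a synthetic fixture document
#'
#' Builds a small HTML article: a title, `n_paragraphs` paragraphs of
#' filler prose, a `<style>` block and an HTML comment (so markup
#' stripping is exercised), with `n_mentions` entity-like tokens (e.g.
#' `BACE1`) planted at random word positions. Mention tokens contain
#' digits and never collide with filler words, so their occurrences in
#' the normalized text are exactly the planted ones.
#'
#' @param n_paragraphs number of paragraphs (>= 1).
#' @param n_mentions number of planted mentions (>= 1).
#' @param seed optional integer; given the same seed the document is
#'   byte-identical.
#' @param duplicate_rate fraction of mentions (approximately) that reuse
#'   an already-planted token, creating genuinely ambiguous anchors.
#' @return an `ao_fixture_doc` with fields `title` (word vector),
#'   `paragraphs` (list of word vectors), `mentions` (data.frame `id`,
#'   `token`, `paragraph`, `word_index`), and `page_uri`.
#' @examples
#' doc <- generate_document(seed = 1)
#' substr(fixture_raw(doc), 1, 60)
#' @export
generate_document <- function(n_paragraphs = 6, n_mentions = 8, seed = NULL,
                              duplicate_rate = 0) {
  if (!is_count(n_paragraphs) || n_paragraphs < 1) {
    ao_stop("`n_paragraphs` must be a positive integer")
  }
  if (!is_count(n_mentions) || n_mentions < 1) {
    ao_stop("`n_mentions` must be a positive integer")
  }
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate > 1) {
    ao_stop("`duplicate_rate` must be in [0, 1]")
  }
  with_ao_seed(seed, {
    paragraphs <- lapply(seq_len(n_paragraphs), function(i) {
      rand_words(sample(18:36, 1L))
    })
    tokens <- character(n_mentions)
    for (i in seq_len(n_mentions)) {
      if (i > 1L && stats::runif(1) < duplicate_rate) {
        tokens[[i]] <- tokens[[sample.int(i - 1L, 1L)]]
      } else {
        # two-digit suffix: no token can be a substring of another
        tokens[[i]] <- paste0(sample(MENTION_STEMS, 1L),
                              sample(10:99, 1L))
      }
    }
    mentions <- data.frame(
      id = sprintf("m%02d", seq_len(n_mentions)),
      token = tokens,
      paragraph = sample.int(n_paragraphs, n_mentions, replace = TRUE),
      word_index = NA_integer_,
      stringsAsFactors = FALSE
    )
    # plant each mention by replacing a word; avoid the same slot twice
    for (i in seq_len(n_mentions)) {
      p <- mentions$paragraph[[i]]
      words <- paragraphs[[p]]
      taken <- mentions$word_index[mentions$paragraph == p &
                                     !is.na(mentions$word_index)]
      free <- setdiff(seq_along(words), taken)
      if (length(free) == 0L) {
        # paragraph saturated: grow it
        paragraphs[[p]] <- c(words, rand_words(5L))
        free <- setdiff(seq_along(paragraphs[[p]]), taken)
      }
      w <- free[[sample.int(length(free), 1L)]]
      paragraphs[[p]][[w]] <- mentions$token[[i]]
      mentions$word_index[[i]] <- w
    }
    structure(
      list(title = rand_words(4L),
           paragraphs = paragraphs,
           mentions = mentions,
           page_uri = paste0("http://example.org/fixture/doc-",
                             if (is.null(seed)) "x" else seed)),
      class = "ao_fixture_doc"
    )
  })
}

#' @export
print.ao_fixture_doc <- function(x, ...) {
  cat("<ao_fixture_doc> ", length(x$paragraphs), " paragraphs, ",
      nrow(x$mentions), " mentions\n", sep = "")
  invisible(x)
}

#' Render a fixture document to raw HTML
#'
#' @param doc an `ao_fixture_doc`.
#' @return a single HTML string.
#' @export
fixture_raw <- function(doc) {
  stopifnot(inherits(doc, "ao_fixture_doc"))
  paras <- vapply(doc$paragraphs, function(w) {
    paste0("<p class=\"body\">", paste(w, collapse = " "), "</p>")
  }, character(1L))
  paste0(
    "<html><head><title>", paste(doc$title, collapse = " "),
    "</title>\n<style>p { margin: 0; }</style></head>\n",
    "<body>\n<!-- synthetic fixture -->\n<h1>",
    paste(doc$title, collapse = " "), "</h1>\n",
    paste(paras, collapse = "\n"),
    "\n</body></html>\n"
  )
}

# Normalized [start, end) span of each surviving mention, found by
# occurrence counting: planted instances of a token appear in document
# order, so the k-th planted instance is the k-th normalized occurrence.
#' Normalized character spans of a fixture's mentions
#'
#' @param doc an `ao_fixture_doc`.
#' @return data.frame `id`, `token`, `norm_start`, `norm_end` (0-based,
#'   half-open, in the normalized text of [fixture_raw()]).
#' @export
fixture_mention_spans <- function(doc) {
  stopifnot(inherits(doc, "ao_fixture_doc"))
  norm <- normalize_document(fixture_raw(doc))
  m <- doc$mentions
  if (nrow(m) == 0L) {
    return(data.frame(id = character(0), token = character(0),
                      norm_start = integer(0), norm_end = integer(0)))
  }
  # document order of planted mentions
  ord <- order(m$paragraph, m$word_index)
  rows <- vector("list", nrow(m))
  occ_seen <- list()
  for (k in ord) {
    tok <- m$token[[k]]
    occ_seen[[tok]] <- (occ_seen[[tok]] %||% 0L) + 1L
    occ <- str_occurrences(norm$text, tok)
    idx <- occ_seen[[tok]]
    if (idx > length(occ)) {
      ao_stop("internal fixture error: mention '", tok, "' not found")
    }
    s0 <- occ[[idx]] - 1L
    rows[[k]] <- data.frame(id = m$id[[k]], token = tok,
                            norm_start = s0, norm_end = s0 + nchar(tok),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build one qualifier annotation per fixture mention
#'
#' Each mention gets a text-quote selector (context window
#' `context_len`) on the fixture's page URI and a `Qualifier`
#' annotation whose topic is a term minted from the mention token.
#'
#' @param doc an `ao_fixture_doc`.
#' @param creator an [ao_agent()]; a default software agent when
#'   omitted.
#' @param context_len selector context window (normalized characters).
#' @param seed deterministic minting seed base; mention `i` uses
#'   `seed + i`.
#' @return list of `ao_annotation` objects, one per mention.
#' @export
fixture_annotations <- function(doc, creator = NULL, context_len = 32,
                                seed = NULL) {
  stopifnot(inherits(doc, "ao_fixture_doc"))
  if (is.null(creator)) {
    creator <- ao_agent("http://example.org/agent/fixture-bot", "software",
                        "Fixture Bot")
  }
  norm <- normalize_document(fixture_raw(doc))
  spans <- fixture_mention_spans(doc)
  lapply(seq_len(nrow(spans)), function(i) {
    sel <- make_text_selector(
      norm, spans$norm_start[[i]], spans$norm_end[[i]],
      context_len = context_len, on_document = doc$page_uri,
      seed = if (is.null(seed)) NULL else seed + 1000L + i)
    term <- ao_term(paste0("http://example.org/vocab/", spans$token[[i]]),
                    spans$token[[i]])
    new_annotation("Qualifier", creator, list(sel),
                   created_on = "2024-01-01T00:00:00Z",
                   topics = list(term),
                   seed = if (is.null(seed)) NULL else seed + 2000L + i)
  })
}

# ---------------------------------------------------------------------------
# Mutations

#' Mutate a fixture document
#'
#' Applies one named mutation and returns the mutated structural
#' document together with an edit log. Classes:
#' \describe{
#'   \item{`markup_churn`}{rewrites tags and whitespace only (extra
#'     indentation, different attributes); normalized text unchanged.}
#'   \item{`distant_edit`}{rewrites filler words of a paragraph that
#'     contains no mention; anchors must survive at full context.}
#'   \item{`context_edit`}{rewrites the filler words immediately around
#'     one mention; the full context breaks but the exact string
#'     survives, exercising the `exact_only` tier.}
#'   \item{`duplicate_paragraph`}{copies a mention-bearing paragraph to
#'     the end of the document, making its mentions ambiguous.}
#'   \item{`delete_paragraph`}{removes a mention-bearing paragraph; its
#'     mentions become orphans (tombstoned in the mention table).}
#' }
#'
#' @param doc an `ao_fixture_doc`.
#' @param op one of the classes above (see `AO_MUTATION_CLASSES`).
#' @param seed optional integer controlling the random choices.
#' @return an `ao_fixture_doc` with an added `edit_log` field (list of
#'   `list(op, detail, affected_ids)`); mentions in deleted paragraphs
#'   get `paragraph = NA` (tombstone).
#' @export
mutate_document <- function(doc, op, seed = NULL) {
  stopifnot(inherits(doc, "ao_fixture_doc"))
  op <- match.arg(op, AO_MUTATION_CLASSES)
  with_ao_seed(seed, {
    out <- doc
    log_entry <- list(op = op, detail = "", affected_ids = character(0))
    live <- !is.na(out$mentions$paragraph)
    mention_paras <- unique(out$mentions$paragraph[live])
    switch(op,
      markup_churn = {
        out$markup_variant <- (doc$markup_variant %||% 0L) + 1L
        log_entry$detail <- "tags and whitespace rewritten"
      },
      distant_edit = {
        candidates <- setdiff(seq_along(out$paragraphs), mention_paras)
        if (length(candidates) == 0L) {
          # no mention-free paragraph: append one and edit it
          out$paragraphs <- c(out$paragraphs, list(rand_words(20L)))
          candidates <- length(out$paragraphs)
        }
        p <- candidates[[sample.int(length(candidates), 1L)]]
        out$paragraphs[[p]] <- rand_words(length(out$paragraphs[[p]]))
        log_entry$detail <- sprintf("paragraph %d reworded", p)
      },
      context_edit = {
        if (!any(live)) ao_stop("no live mentions to edit around")
        i <- which(live)[[sample.int(sum(live), 1L)]]
        p <- out$mentions$paragraph[[i]]
        w <- out$mentions$word_index[[i]]
        words <- out$paragraphs[[p]]
        planted <- out$mentions$word_index[out$mentions$paragraph %in% p &
                                             !is.na(out$mentions$paragraph)]
        for (j in seq_along(words)) {
          if (abs(j - w) <= 6L && !(j %in% planted)) {
            words[[j]] <- paste0("edited", sample.int(999L, 1L))
          }
        }
        out$paragraphs[[p]] <- words
        log_entry$detail <- sprintf("context of %s reworded",
                                    out$mentions$id[[i]])
        log_entry$affected_ids <- out$mentions$id[[i]]
      },
      duplicate_paragraph = {
        if (length(mention_paras) == 0L) ao_stop("no mention-bearing paragraph")
        p <- mention_paras[[sample.int(length(mention_paras), 1L)]]
        out$paragraphs <- c(out$paragraphs, out$paragraphs[p])
        ids <- out$mentions$id[out$mentions$paragraph %in% p &
                                 !is.na(out$mentions$paragraph)]
        log_entry$detail <- sprintf("paragraph %d duplicated", p)
        log_entry$affected_ids <- ids
      },
      delete_paragraph = {
        if (length(mention_paras) == 0L) ao_stop("no mention-bearing paragraph")
        p <- mention_paras[[sample.int(length(mention_paras), 1L)]]
        out$paragraphs <- out$paragraphs[-p]
        hit <- which(out$mentions$paragraph %in% p)
        log_entry$affected_ids <- out$mentions$id[hit]
        out$mentions$paragraph[hit] <- NA_integer_
        out$mentions$word_index[hit] <- NA_integer_
        shift <- !is.na(out$mentions$paragraph) & out$mentions$paragraph > p
        out$mentions$paragraph[shift] <- out$mentions$paragraph[shift] - 1L
        log_entry$detail <- sprintf("paragraph %d deleted", p)
      }
    )
    out$edit_log <- c(doc$edit_log %||% list(), list(log_entry))
    out
  })
}

# Rendered raw for mutated docs: markup churn changes the rendering, so
# fixture_raw consults markup_variant.
fixture_raw_variant <- function(doc) {
  v <- doc$markup_variant %||% 0L
  if (v == 0L) return(fixture_raw(doc))
  paras <- vapply(doc$paragraphs, function(w) {
    paste0("  <p class=\"body text\" data-v=\"", v, "\">\n    ",
           paste(w, collapse = "  "), "\n  </p>")
  }, character(1L))
  paste0(
    "<!DOCTYPE html>\n<html lang=\"en\"><head>\n  <title>",
    paste(doc$title, collapse = " "),
    "</title>\n  <style>\n    p { margin: 1em; }\n  </style>\n",
    "  <script>console.log('v", v, "');</script>\n</head>\n",
    "<body>\n  <!-- churned -->\n  <h1 id=\"t\">",
    paste(doc$title, collapse = " "), "</h1>\n",
    paste(paras, collapse = "\n"),
    "\n</body>\n</html>\n"
  )
}

#' Expected anchoring outcome of a fixture mention
#'
#' Structural oracle at the exact-string tier: tombstoned mentions are
#' `"orphan"`; tokens present exactly once are `"unique"`; duplicated
#' tokens are `"ambiguous"`. Note that the two-tier resolver may still
#' report `unique` for a duplicated token when its full context window
#' crosses into a neighbouring paragraph and disambiguates the copies —
#' [robustness_experiment()] counts that as agreement.
#'
#' @param doc a mutated `ao_fixture_doc`.
#' @param mention_id mention id (e.g. `"m03"`).
#' @return one of `"unique"`, `"ambiguous"`, `"orphan"`.
#' @export
expected_mention_status <- function(doc, mention_id) {
  stopifnot(inherits(doc, "ao_fixture_doc"))
  i <- match(mention_id, doc$mentions$id)
  if (is.na(i)) ao_stop("unknown mention id '", mention_id, "'")
  if (is.na(doc$mentions$paragraph[[i]])) return("orphan")
  tok <- doc$mentions$token[[i]]
  n_tok <- sum(vapply(doc$paragraphs, function(w) sum(w == tok), integer(1L)))
  if (n_tok == 0L) "orphan" else if (n_tok > 1L) "ambiguous" else "unique"
}

# ---------------------------------------------------------------------------
# Robustness experiment

#' Anchoring robustness experiment over mutation classes
#'
#' For `n_docs` generated documents: create one text-quote selector per
#' mention on the pristine document, apply each mutation class in turn
#' (independently, each to a fresh copy), re-resolve every selector
#' against the mutated raw markup and tabulate resolution outcomes.
#'
#' @param n_docs number of fixture documents.
#' @param classes mutation classes to exercise (default: all five).
#' @param seed integer seed; the whole experiment is deterministic given
#'   the seed.
#' @param context_len selector context window.
#' @return a data.frame with one row per mutation class: `mutation`,
#'   `n_anchors`, `unique`, `ambiguous`, `orphan`, `full_context`,
#'   `exact_only`, `unique_rate`, and `oracle_agreement` (fraction of
#'   anchors whose observed status matches [expected_mention_status()]).
#' @examples
#' robustness_experiment(n_docs = 2, seed = 7)
#' @export
robustness_experiment <- function(n_docs = 10,
                                  classes = AO_MUTATION_CLASSES,
                                  seed = 1, context_len = 32) {
  classes <- match.arg(classes, AO_MUTATION_CLASSES, several.ok = TRUE)
  if (!is_count(n_docs) || n_docs < 1) {
    ao_stop("`n_docs` must be a positive integer")
  }
  tallies <- lapply(classes, function(cl) {
    c(n = 0L, unique = 0L, ambiguous = 0L, orphan = 0L,
      full_context = 0L, exact_only = 0L, oracle_ok = 0L)
  })
  names(tallies) <- classes
  for (d in seq_len(n_docs)) {
    doc <- generate_document(seed = seed * 1000L + d)
    norm <- normalize_document(fixture_raw(doc))
    spans <- fixture_mention_spans(doc)
    sels <- lapply(seq_len(nrow(spans)), function(i) {
      make_text_selector(norm, spans$norm_start[[i]], spans$norm_end[[i]],
                         context_len = context_len,
                         on_document = doc$page_uri)
    })
    for (cl in classes) {
      mut <- mutate_document(doc, cl, seed = seed * 1000L + d)
      mnorm <- normalize_document(fixture_raw_variant(mut))
      for (i in seq_along(sels)) {
        res <- resolve_text_selector(sels[[i]], mnorm)
        t <- tallies[[cl]]
        t[["n"]] <- t[["n"]] + 1L
        t[[res$status]] <- t[[res$status]] + 1L
        if (res$tier %in% c("full_context", "exact_only")) {
          t[[res$tier]] <- t[[res$tier]] + 1L
        }
        exp_status <- expected_mention_status(mut, spans$id[[i]])
        agrees <- identical(exp_status, res$status) ||
          # context may legitimately disambiguate a duplicated token
          (exp_status == "ambiguous" && res$status == "unique" &&
             res$tier == "full_context")
        if (agrees) t[["oracle_ok"]] <- t[["oracle_ok"]] + 1L
        tallies[[cl]] <- t
      }
    }
  }
  do.call(rbind, lapply(classes, function(cl) {
    t <- tallies[[cl]]
    data.frame(
      mutation = cl, n_anchors = t[["n"]],
      unique = t[["unique"]], ambiguous = t[["ambiguous"]],
      orphan = t[["orphan"]], full_context = t[["full_context"]],
      exact_only = t[["exact_only"]],
      unique_rate = t[["unique"]] / t[["n"]],
      oracle_agreement = t[["oracle_ok"]] / t[["n"]],
      stringsAsFactors = FALSE
    )
  }))
}
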