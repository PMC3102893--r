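# Text normalization and selector anchoring. Offsets are 0-based and
# half-open throughout: normalized offsets index the normalized string,
# raw offsets index characters of the original markup text.

# ---------------------------------------------------------------------------
# Normalization

# Character positions (1-based, inclusive) of all matches of `pattern`.
match_spans <- function(raw, pattern) {
  m <- gregexpr(pattern, raw, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  cbind(start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Normalize a markup document for anchoring
#'
#' Produces the canonical text space in which text selectors live:
#' HTML/XML markup is ignored, the content of non-displayed containers
#' (`<script>`, `<style>`) and comments is removed, and every run of
#' whitespace collapses to a single space. An offset map records, for
#' each normalized character, the 0-based index of the corresponding
#' character in the raw input (for a collapsed space: the first raw
#' whitespace character of its run), so resolved spans can be mapped
#' back onto the original document.
#'
#' Markup need not be well-formed; plain text passes through with an
#' identity-like map. Normalization is idempotent.
#'
#' @param raw a single string of markup or plain text.
#' @return an `ao_normalized_text` object with fields `text` (the
#'   normalized string) and `offset_map` (integer vector, 0-based raw
#'   indices, same length as `text`).
#' @examples
#' n <- normalize_document("<b>foo</b>  bar")
#' n$text        # "foo bar"
#' n$offset_map  # 3 4 5 10 12 13 14
#' @export
normalize_document <- function(raw) {
  if (!is_string(raw)) ao_stop("`raw` must be a single string")
  n <- nchar(raw)
  if (n == 0L) {
    return(structure(list(text = "", offset_map = integer(0)),
                     class = "ao_normalized_text"))
  }
  mask <- rep(FALSE, n)
  # comments, then script/style elements (content included), then tags
  for (pat in c("(?s)<!--.*?(-->|$)",
                "(?is)<script\\b[^>]*>.*?(</script\\s*>|$)",
                "(?is)<style\\b[^>]*>.*?(</style\\s*>|$)")) {
    sp <- match_spans(raw, pat)
    if (!is.null(sp)) {
      for (i in seq_len(nrow(sp))) mask[sp[i, 1]:sp[i, 2]] <- TRUE
    }
  }
  sp <- match_spans(raw, "<[^>]*(>|$)")
  if (!is.null(sp)) {
    for (i in seq_len(nrow(sp))) {
      if (!mask[sp[i, 1]]) mask[sp[i, 1]:sp[i, 2]] <- TRUE
    }
  }
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  keep <- which(!mask)
  if (length(keep) == 0L) {
    return(structure(list(text = "", offset_map = integer(0)),
                     class = "ao_normalized_text"))
  }
  kc <- chars[keep]
  ws <- grepl("^[\\s\\p{Z}]$", kc, perl = TRUE)
  runs <- rle(ws)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  out_chars <- character(0)
  out_idx <- integer(0)
  nr <- length(runs$values)
  for (r in seq_len(nr)) {
    if (runs$values[[r]]) {
      # whitespace run: one space, unless leading or trailing
      if (r == 1L || r == nr) next
      out_chars <- c(out_chars, " ")
      out_idx <- c(out_idx, keep[run_starts[[r]]])
    } else {
      sel <- run_starts[[r]]:run_ends[[r]]
      out_chars <- c(out_chars, kc[sel])
      out_idx <- c(out_idx, keep[sel])
    }
  }
  structure(
    list(text = paste0(out_chars, collapse = ""),
         offset_map = out_idx - 1L),
    class = "ao_normalized_text"
  )
}

#' @export
print.ao_normalized_text <- function(x, ...) {
  cat("<ao_normalized_text> ", nchar(x$text), " chars\n", sep = "")
  cat("  ", substr(x$text, 1, 70), if (nchar(x$text) > 70) "..." else "",
      "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Selector constructors

new_selector <- function(subclass, fields, uri, base_uri, seed,
                         on_document, on_version) {
  if (is.null(uri)) uri <- mint_uri(base_uri, "selector", seed = seed)
  if (!is_string(on_document) || !is_absolute_iri(on_document)) {
    ao_stop("`on_document` must be an absolute IRI")
  }
  if (!is.null(on_version) &&
      (!is_string(on_version) || !is_absolute_iri(on_version))) {
    ao_stop("`on_version` must be an absolute IRI")
  }
  structure(
    c(list(uri = uri), fields,
      list(on_document = on_document, on_version = on_version)),
    class = c(subclass, "ao_selector")
  )
}

#' Text-quote selector (prefix / exact / postfix)
#'
#' Identifies a chunk of text by the exact string being annotated plus
#' the normalized character sequences immediately preceding and
#' following it. The concatenation `prefix + exact + postfix` locates
#' the fragment; this remains resolvable even when unrelated parts of
#' the document change. All three strings live in normalized space
#' (no markup, no consecutive whitespace).
#'
#' @param exact the annotated string (non-empty).
#' @param prefix,postfix context strings (possibly empty at document
#'   edges).
#' @param on_document IRI of the annotated page.
#' @param on_version optional IRI of the specific source version.
#' @param uri,base_uri,seed minting controls.
#' @return an `ao_text_quote_selector`.
#' @export
ao_text_quote_selector <- function(exact, prefix = "", postfix = "",
                                   on_document = "http://example.org/document",
                                   on_version = NULL, uri = NULL,
                                   base_uri = ao_default_base(), seed = NULL) {
  if (!is_string(exact) || !nzchar(exact)) {
    ao_stop("`exact` must be a non-empty string")
  }
  for (nm in c("prefix", "exact", "postfix")) {
    val <- get(nm)
    if (!is_string(val)) ao_stop("`", nm, "` must be a string")
    if (grepl("[<>]", val)) {
      ao_stop("`", nm, "` contains markup delimiters; selectors live in ",
              "normalized space")
    }
    if (grepl("[\\s\\p{Z}]{2}", val, perl = TRUE) ||
        grepl("[^ \\S]", val, perl = TRUE)) {
      ao_stop("`", nm, "` is not normalized (whitespace runs or non-space ",
              "whitespace)")
    }
  }
  new_selector("ao_text_quote_selector",
               list(prefix = prefix, exact = exact, postfix = postfix),
               uri, base_uri, seed, on_document, on_version)
}

#' Offset-range selector
#'
#' Addresses `length` characters starting at 0-based `start` in the
#' normalized text. Simple and precise for immutable content; brittle
#' under document edits (any insertion before the anchor shifts it).
#'
#' @param start 0-based start offset in normalized space.
#' @param length number of characters (>= 1).
#' @inheritParams ao_text_quote_selector
#' @return an `ao_offset_selector`.
#' @export
ao_offset_selector <- function(start, length,
                               on_document = "http://example.org/document",
                               on_version = NULL, uri = NULL,
                               base_uri = ao_default_base(), seed = NULL) {
  if (!is_count(start) || start < 0) ao_stop("`start` must be an integer >= 0")
  if (!is_count(length) || length < 1) ao_stop("`length` must be an integer >= 1")
  new_selector("ao_offset_selector",
               list(start = as.integer(start), length = as.integer(length)),
               uri, base_uri, seed, on_document, on_version)
}

#' XPointer selector (stored, not evaluated)
#'
#' Carries an XPointer expression for interoperability with
#' Annotea-style tooling. Expressions are stored and round-tripped
#' verbatim; this package does not evaluate XPointer.
#'
#' @param expression non-empty XPointer string.
#' @inheritParams ao_text_quote_selector
#' @return an `ao_xpointer_selector`.
#' @export
ao_xpointer_selector <- function(expression,
                                 on_document = "http://example.org/document",
                                 on_version = NULL, uri = NULL,
                                 base_uri = ao_default_base(), seed = NULL) {
  if (!is_string(expression) || !nzchar(expression)) {
    ao_stop("`expression` must be a non-empty string")
  }
  new_selector("ao_xpointer_selector", list(expression = expression),
               uri, base_uri, seed, on_document, on_version)
}

#' Image bounding-box selector
#'
#' Selects a rectangular region of an image in pixel units. The origin
#' is the top-left corner; (`x_init`, `y_init`) is the upper-left and
#' (`x_end`, `y_end`) the lower-right corner of the box, half-open.
#'
#' @param x_init,y_init,x_end,y_end box corners in pixels;
#'   `0 <= x_init < x_end`, `0 <= y_init < y_end`.
#' @inheritParams ao_text_quote_selector
#' @return an `ao_image_box_selector`.
#' @export
ao_image_box_selector <- function(x_init, y_init, x_end, y_end,
                                  on_document = "http://example.org/document",
                                  on_version = NULL, uri = NULL,
                                  base_uri = ao_default_base(), seed = NULL) {
  for (nm in c("x_init", "y_init", "x_end", "y_end")) {
    if (!is_count(get(nm)) || get(nm) < 0) {
      ao_stop("`", nm, "` must be a non-negative integer")
    }
  }
  if (!(x_init < x_end) || !(y_init < y_end)) {
    ao_stop("box corners must satisfy x_init < x_end and y_init < y_end")
  }
  new_selector("ao_image_box_selector",
               list(x_init = as.integer(x_init), y_init = as.integer(y_init),
                    x_end = as.integer(x_end), y_end = as.integer(y_end)),
               uri, base_uri, seed, on_document, on_version)
}

validate_selector <- function(sel) {
  v <- no_violations()
  if (!is_absolute_iri(sel$uri)) {
    v <- rbind(v, violation("uri", "absolute_iri", "selector uri not absolute"))
  }
  if (inherits(sel, "ao_text_quote_selector") && !nzchar(sel$exact)) {
    v <- rbind(v, violation("exact", "non_empty", "exact must be non-empty"))
  }
  if (inherits(sel, "ao_offset_selector") &&
      (sel$start < 0 || sel$length < 1)) {
    v <- rbind(v, violation("start", "range", "start >= 0 and length >= 1"))
  }
  if (inherits(sel, "ao_image_box_selector") &&
      (sel$x_init >= sel$x_end || sel$y_init >= sel$y_end ||
       sel$x_init < 0 || sel$y_init < 0)) {
    v <- rbind(v, violation("box", "corner_order",
                            "0 <= init < end on both axes"))
  }
  v
}

# ---------------------------------------------------------------------------
# Resolution

ao_resolution <- function(matches, tier, passthrough = FALSE) {
  if (is.null(matches)) {
    matches <- data.frame(norm_start = integer(0), norm_end = integer(0),
                          raw_start = integer(0), raw_end = integer(0))
  }
  status <- if (nrow(matches) == 0L) "orphan"
            else if (nrow(matches) == 1L) "unique"
            else "ambiguous"
  structure(
    list(status = status, matches = matches, tier = tier,
         passthrough = passthrough),
    class = "ao_resolution"
  )
}

#' @export
print.ao_resolution <- function(x, ...) {
  cat("<ao_resolution> ", x$status, " (tier ", x$tier, ", ",
      nrow(x$matches), " match", if (nrow(x$matches) != 1) "es", ")\n",
      sep = "")
  invisible(x)
}

# All occurrences (1-based start positions) of `needle` in `hay`,
# including overlapping ones.
str_occurrences <- function(hay, needle) {
  out <- integer(0)
  from <- 1L
  nh <- nchar(hay)
  nn <- nchar(needle)
  if (nn == 0L || nn > nh) return(out)
  while (from <= nh - nn + 1L) {
    p <- regexpr(needle, substr(hay, from, nh), fixed = TRUE)
    if (p == -1L) break
    pos <- from + as.integer(p) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

# Map a normalized half-open span [start0, end0) to the raw half-open range.
norm_span_to_raw <- function(norm, start0, end0) {
  c(raw_start = norm$offset_map[[start0 + 1L]],
    raw_end = norm$offset_map[[end0]] + 1L)
}

#' Create a text-quote selector for a normalized span
#'
#' Captures the exact string at `[start, end)` of the normalized text
#' together with up to `context_len` characters of preceding and
#' following context (truncated at the document edges).
#'
#' @param norm an `ao_normalized_text` from [normalize_document()].
#' @param start,end 0-based half-open character range in `norm$text`;
#'   `0 <= start < end <= nchar(norm$text)`.
#' @param context_len context window length in normalized characters
#'   (default 32).
#' @param ... passed to [ao_text_quote_selector()] (`on_document`,
#'   `on_version`, `uri`, `base_uri`, `seed`).
#' @return an `ao_text_quote_selector`.
#' @examples
#' n <- normalize_document("<p>the protein BACE1 is cleaved</p>")
#' s <- make_text_selector(n, 12, 17)
#' s$exact
#' @export
make_text_selector <- function(norm, start, end, context_len = 32, ...) {
  stopifnot(inherits(norm, "ao_normalized_text"))
  n <- nchar(norm$text)
  if (!is_count(start) || !is_count(end) ||
      start < 0 || end <= start || end > n) {
    ao_stop("selector range [", start, ", ", end, ") out of bounds for ",
            n, "-char text", class = "aotk_range_error")
  }
  if (!is_count(context_len) || context_len < 0) {
    ao_stop("`context_len` must be a non-negative integer")
  }
  exact <- substr(norm$text, start + 1L, end)
  prefix <- substr(norm$text, max(1L, start - context_len + 1L), start)
  postfix <- substr(norm$text, end + 1L, min(n, end + context_len))
  ao_text_quote_selector(exact = exact, prefix = prefix, postfix = postfix, ...)
}

#' Resolve a text-quote selector against a normalized document
#'
#' Two-tier matching: first all occurrences of the full context
#' `prefix + exact + postfix` as a contiguous normalized substring
#' (tier `"full_context"`); if there are none, all occurrences of
#' `exact` alone (tier `"exact_only"` — flagged so curators can review
#' context loss); if both tiers are empty the annotation is an orphan
#' (tier `"none"`). Reported spans cover the exact string only, in both
#' normalized and raw coordinates. Matching is case-sensitive and
#' includes overlapping occurrences.
#'
#' @param sel an `ao_text_quote_selector`.
#' @param norm an `ao_normalized_text`.
#' @return an `ao_resolution` with fields `status` (`"unique"`,
#'   `"ambiguous"` or `"orphan"`), `tier`, and `matches` (data frame of
#'   half-open spans: `norm_start`, `norm_end`, `raw_start`, `raw_end`).
#' @export
resolve_text_selector <- function(sel, norm) {
  stopifnot(inherits(sel, "ao_text_quote_selector"),
            inherits(norm, "ao_normalized_text"))
  full <- paste0(sel$prefix, sel$exact, sel$postfix)
  npre <- nchar(sel$prefix)
  nex <- nchar(sel$exact)
  hits <- str_occurrences(norm$text, full)
  tier <- "full_context"
  starts0 <- hits - 1L + npre          # 0-based exact start
  if (length(hits) == 0L) {
    hits <- str_occurrences(norm$text, sel$exact)
    tier <- if (length(hits) > 0L) "exact_only" else "none"
    starts0 <- hits - 1L
  }
  if (length(starts0) == 0L) return(ao_resolution(NULL, tier))
  m <- do.call(rbind, lapply(starts0, function(s0) {
    raw <- norm_span_to_raw(norm, s0, s0 + nex)
    data.frame(norm_start = s0, norm_end = s0 + nex,
               raw_start = unname(raw[["raw_start"]]),
               raw_end = unname(raw[["raw_end"]]))
  }))
  ao_resolution(m, tier)
}

#' Resolve an offset-range selector
#'
#' Resolves to the unique span `[start, start + length)` of the
#' normalized text when in bounds, mapped to raw coordinates; out of
#' bounds means the anchor no longer exists (orphan).
#'
#' @param sel an `ao_offset_selector`.
#' @param norm an `ao_normalized_text`.
#' @return an `ao_resolution`.
#' @export
resolve_offset_selector <- function(sel, norm) {
  stopifnot(inherits(sel, "ao_offset_selector"),
            inherits(norm, "ao_normalized_text"))
  n <- nchar(norm$text)
  if (sel$start + sel$length > n) return(ao_resolution(NULL, "none"))
  s0 <- sel$start
  e0 <- sel$start + sel$length
  raw <- norm_span_to_raw(norm, s0, e0)
  ao_resolution(
    data.frame(norm_start = s0, norm_end = e0,
               raw_start = unname(raw[["raw_start"]]),
               raw_end = unname(raw[["raw_end"]])),
    "full_context"
  )
}

#' Check an image bounding box against image dimensions
#'
#' A box is resolvable (`unique`) when it lies entirely within the
#' `width` x `height` pixel grid, and an orphan when it exceeds the
#' bounds — which happens when the image was rescaled or cropped since
#' the selector was created.
#'
#' @param sel an `ao_image_box_selector`.
#' @param width,height image dimensions in pixels (>= 1).
#' @return an `ao_resolution` (matches carry the pixel box in
#'   `raw_start`/`raw_end` as x/y pairs is not meaningful; the box is
#'   echoed via the selector itself).
#' @export
validate_image_box <- function(sel, width, height) {
  stopifnot(inherits(sel, "ao_image_box_selector"))
  if (!is_count(width) || !is_count(height) || width < 1 || height < 1) {
    ao_stop("image `width` and `height` must be positive integers")
  }
  ok <- sel$x_init >= 0 && sel$y_init >= 0 &&
    sel$x_end <= width && sel$y_end <= height
  if (!ok) return(ao_resolution(NULL, "none"))
  ao_resolution(
    data.frame(norm_start = NA_integer_, norm_end = NA_integer_,
               raw_start = NA_integer_, raw_end = NA_integer_),
    "full_context"
  )
}

selectors_of <- function(annotation) {
  Filter(function(t) inherits(t, "ao_selector"), annotation$targets)
}

#' Re-anchor annotations against a new document version
#'
#' Resolves every selector of every annotation against the new raw
#' markup and reports one record per selector. Whole-document targets
#' always re-anchor (`unique`); XPointer expressions are not evaluated
#' and pass through with `tier = "none"` and `passthrough = TRUE`.
#'
#' @param annotations list of `ao_annotation` objects.
#' @param new_version_raw the new document version as markup text.
#' @return a data.frame with one row per target: `annotation_uri`,
#'   `selector_uri` (`NA` for whole-document targets), `status`,
#'   `tier`, `raw_start`, `raw_end` (filled only for unique matches),
#'   plus a `"resolutions"` attribute holding the full `ao_resolution`
#'   objects keyed by selector URI.
#' @export
reanchor_report <- function(annotations, new_version_raw) {
  if (inherits(annotations, "ao_annotation")) annotations <- list(annotations)
  norm <- normalize_document(new_version_raw)
  rows <- list()
  resolutions <- list()
  for (ann in annotations) {
    for (tg in ann$targets) {
      if (inherits(tg, "ao_document_ref")) {
        rows[[length(rows) + 1L]] <- data.frame(
          annotation_uri = ann$uri, selector_uri = NA_character_,
          status = "unique", tier = "full_context",
          raw_start = NA_integer_, raw_end = NA_integer_,
          stringsAsFactors = FALSE)
        next
      }
      res <- if (inherits(tg, "ao_text_quote_selector")) {
        resolve_text_selector(tg, norm)
      } else if (inherits(tg, "ao_offset_selector")) {
        resolve_offset_selector(tg, norm)
      } else {
        ao_resolution(NULL, "none", passthrough = TRUE)
      }
      resolutions[[tg$uri]] <- res
      one <- res$status == "unique"
      rows[[length(rows) + 1L]] <- data.frame(
        annotation_uri = ann$uri, selector_uri = tg$uri,
        status = res$status, tier = res$tier,
        raw_start = if (one) res$matches$raw_start[[1L]] else NA_integer_,
        raw_end = if (one) res$matches$raw_end[[1L]] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    annotation_uri = character(0), selector_uri = character(0),
    status = character(0), tier = character(0),
    raw_start = integer(0), raw_end = integer(0))
  attr(out, "resolutions") <- resolutions
  out
}
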