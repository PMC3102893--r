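# Triple graph container. Nodes are character strings: absolute IRIs,
# or blank-node labels prefixed "_:" . Literals live in the object
# position only, with optional datatype IRI and language tag.

empty_triples <- function() {
  data.frame(s = character(0), p = character(0), o = character(0),
             o_type = character(0), dt = character(0), lang = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a triple graph
#'
#' @param triples data.frame with columns `s`, `p`, `o`, `o_type`
#'   (`"iri"`, `"blank"` or `"literal"`), `dt` (datatype IRI or `NA`),
#'   `lang` (language tag or `NA`). Blank nodes are labelled `_:...`.
#' @param ns an [ao_namespaces()] registry bound to the graph.
#' @return an `ao_graph` object.
#' @export
ao_graph <- function(triples = empty_triples(), ns = ao_namespaces()) {
  stopifnot(is.data.frame(triples),
            all(c("s", "p", "o", "o_type", "dt", "lang") %in% names(triples)))
  structure(list(triples = triples, ns = ns), class = "ao_graph")
}

graph_add <- function(g, s, p, o, o_type = "iri", dt = NA_character_,
                      lang = NA_character_) {
  g$triples <- rbind(g$triples, data.frame(
    s = s, p = p, o = o, o_type = o_type, dt = dt, lang = lang,
    stringsAsFactors = FALSE))
  g
}

is_blank_node <- function(x) startsWith(x, "_:")

#' Number of triples in a graph
#' @param g an `ao_graph`.
#' @return integer triple count.
#' @export
graph_size <- function(g) nrow(g$triples)

#' @export
print.ao_graph <- function(x, ...) {
  cat("<ao_graph> ", nrow(x$triples), " triples\n", sep = "")
  invisible(x)
}

# Objects of triples (s, p, *); subjects of (*, p, o); etc.
graph_objects <- function(g, s = NULL, p = NULL) {
  t <- g$triples
  keep <- rep(TRUE, nrow(t))
  if (!is.null(s)) keep <- keep & t$s == s
  if (!is.null(p)) keep <- keep & t$p == p
  t[keep, , drop = FALSE]
}

# Encode one triple row as a canonical string, with blank nodes either
# kept ("_:x") or substituted via `sub` (named character vector).
encode_term <- function(value, type, dt, lang, sub = NULL) {
  if (type == "literal") {
    out <- paste0("\"", nt_escape(value), "\"")
    if (!is.na(lang) && nzchar(lang)) out <- paste0(out, "@", lang)
    else if (!is.na(dt) && nzchar(dt)) out <- paste0(out, "^^<", dt, ">")
    return(out)
  }
  if (type == "blank" || is_blank_node(value)) {
    if (!is.null(sub) && value %in% names(sub)) return(sub[[value]])
    return(value)
  }
  paste0("<", value, ">")
}

encode_triples <- function(t, sub = NULL) {
  if (nrow(t) == 0L) return(character(0))
  vapply(seq_len(nrow(t)), function(i) {
    paste(
      encode_term(t$s[[i]], if (is_blank_node(t$s[[i]])) "blank" else "iri",
                  NA, NA, sub),
      paste0("<", t$p[[i]], ">"),
      encode_term(t$o[[i]], t$o_type[[i]], t$dt[[i]], t$lang[[i]], sub)
    )
  }, character(1L))
}

graph_blanks <- function(g) {
  t <- g$triples
  unique(c(t$s[is_blank_node(t$s)],
           t$o[t$o_type == "blank" | (t$o_type != "literal" &
                                        is_blank_node(t$o))]))
}

# Iterated colour refinement over blank nodes: a blank's colour is the
# hash of the multiset of its incident triples with neighbouring blanks
# replaced by their current colour.
refine_colors <- function(g, blanks) {
  colors <- stats::setNames(rep("0", length(blanks)), blanks)
  t <- g$triples
  repeat {
    sig <- vapply(blanks, function(b) {
      rows_s <- t[t$s == b, , drop = FALSE]
      rows_o <- t[t$o == b & t$o_type != "literal", , drop = FALSE]
      parts <- c(
        if (nrow(rows_s)) paste0("S|", rows_s$p, "|", vapply(
          seq_len(nrow(rows_s)), function(i) {
            o <- rows_s$o[[i]]
            if (rows_s$o_type[[i]] != "literal" && is_blank_node(o)) {
              paste0("B", colors[[o]])
            } else {
              encode_term(o, rows_s$o_type[[i]], rows_s$dt[[i]],
                          rows_s$lang[[i]])
            }
          }, character(1L))),
        if (nrow(rows_o)) paste0("O|", rows_o$p, "|", vapply(
          rows_o$s, function(s) {
            if (is_blank_node(s)) paste0("B", colors[[s]]) else paste0("<", s, ">")
          }, character(1L)))
      )
      paste(sort(parts), collapse = "##")
    }, character(1L))
    new_colors <- stats::setNames(as.character(match(sig, sort(unique(sig)))),
                                  blanks)
    if (identical(unname(new_colors), unname(colors))) break
    colors <- new_colors
  }
  colors
}

#' Test two triple graphs for isomorphism
#'
#' Graphs are compared as sets of triples, equal up to a consistent
#' relabeling of blank nodes. Ground (blank-free) triples must match
#' exactly; blank nodes are matched by iterated colour refinement
#' followed by a backtracking search within colour classes, so the test
#' is exact (not a heuristic) for the graph sizes this package emits.
#'
#' @param a,b `ao_graph` objects.
#' @return `TRUE` iff the graphs are isomorphic.
#' @export
graphs_isomorphic <- function(a, b) {
  stopifnot(inherits(a, "ao_graph"), inherits(b, "ao_graph"))
  ta <- unique(a$triples)
  tb <- unique(b$triples)
  blanks_a <- graph_blanks(a)
  blanks_b <- graph_blanks(b)
  if (length(blanks_a) != length(blanks_b)) return(FALSE)

  touches_blank <- function(t) {
    is_blank_node(t$s) | (t$o_type != "literal" & is_blank_node(t$o))
  }
  ga <- sort(encode_triples(ta[!touches_blank(ta), , drop = FALSE]))
  gb <- sort(encode_triples(tb[!touches_blank(tb), , drop = FALSE]))
  if (!identical(ga, gb)) return(FALSE)
  if (length(blanks_a) == 0L) return(TRUE)

  ba <- ta[touches_blank(ta), , drop = FALSE]
  bb <- tb[touches_blank(tb), , drop = FALSE]
  if (nrow(ba) != nrow(bb)) return(FALSE)

  col_a <- refine_colors(a, blanks_a)
  col_b <- refine_colors(b, blanks_b)
  if (!identical(sort(table(col_a)), sort(table(col_b)))) {
    # colour class size profiles must agree
    if (!identical(sort(as.vector(table(col_a))),
                   sort(as.vector(table(col_b))))) {
      return(FALSE)
    }
  }

  enc_b <- sort(encode_triples(bb))
  # backtracking over colour-compatible assignments
  assign_next <- function(mapping, remaining_a) {
    if (length(remaining_a) == 0L) {
      sub <- stats::setNames(mapping[blanks_a], blanks_a)
      return(identical(sort(encode_triples(ba, sub)), enc_b))
    }
    x <- remaining_a[[1L]]
    cands <- blanks_b[col_b[blanks_b] == col_a[[x]] &
                        !(blanks_b %in% mapping)]
    for (y in cands) {
      mapping[[x]] <- y
      if (assign_next(mapping, remaining_a[-1L])) return(TRUE)
      mapping[[x]] <- NA_character_
    }
    FALSE
  }
  mapping <- stats::setNames(rep(NA_character_, length(blanks_a)), blanks_a)
  # order by colour-class rarity for better pruning
  ord <- blanks_a[order(table(col_a)[col_a[blanks_a]])]
  assign_next(mapping, ord)
}
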