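# Concrete RDF syntaxes: Turtle, N-Triples, RDF/XML, JSON-LD
# (expanded form). Writers emit the full graph; readers invert them and
# additionally accept the common subset of hand-written documents
# (prefix directives, semicolon/comma lists, [] blank nodes, typed and
# language-tagged literals, numeric abbreviations).

# ---------------------------------------------------------------------------
# N-Triples

nt_term <- function(value, type, dt, lang) {
  encode_term(value, type, dt, lang)
}

graph_to_ntriples <- function(g) {
  t <- g$triples
  if (nrow(t) == 0L) return("")
  lines <- vapply(seq_len(nrow(t)), function(i) {
    paste0(
      nt_term(t$s[[i]], if (is_blank_node(t$s[[i]])) "blank" else "iri", NA, NA),
      " <", t$p[[i]], "> ",
      nt_term(t$o[[i]], t$o_type[[i]], t$dt[[i]], t$lang[[i]]),
      " ."
    )
  }, character(1L))
  paste0(paste(lines, collapse = "\n"), "\n")
}

parse_nt_object <- function(tok) {
  if (startsWith(tok, "<")) {
    list(o = sub("^<(.*)>$", "\\1", tok), o_type = "iri",
         dt = NA_character_, lang = NA_character_)
  } else if (startsWith(tok, "_:")) {
    list(o = tok, o_type = "blank", dt = NA_character_, lang = NA_character_)
  } else {
    m <- regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:@([A-Za-z0-9-]+)|\\^\\^<([^>]*)>)?$',
                 tok)[[1]]
    if (m[1] == -1L) ao_stop("cannot parse N-Triples object: ", tok,
                             class = "aotk_parse_error")
    parts <- regmatches(tok, list(m))[[1]]
    list(o = nt_unescape(parts[[2]]), o_type = "literal",
         dt = if (nzchar(parts[[4]])) parts[[4]] else NA_character_,
         lang = if (nzchar(parts[[3]])) parts[[3]] else NA_character_)
  }
}

ntriples_to_graph <- function(text, ns = ao_namespaces()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    m <- regexec(paste0(
      "^(<[^>]*>|_:[^ \t]+)[ \t]+<([^>]*)>[ \t]+(.*?)[ \t]*\\.[ \t]*$"), ln)[[1]]
    if (m[1] == -1L) {
      ao_stop("N-Triples syntax error at line ", i, ": ", ln,
              class = "aotk_parse_error")
    }
    parts <- regmatches(ln, list(m))[[1]]
    s <- parts[[2]]
    s <- if (startsWith(s, "<")) sub("^<(.*)>$", "\\1", s) else s
    obj <- parse_nt_object(parts[[4]])
    data.frame(s = s, p = parts[[3]], o = obj$o, o_type = obj$o_type,
               dt = obj$dt, lang = obj$lang, stringsAsFactors = FALSE)
  })
  ao_graph(do.call(rbind, c(list(empty_triples()), rows)), ns)
}

# ---------------------------------------------------------------------------
# Turtle

ttl_term_out <- function(value, type, dt, lang, ns) {
  if (type == "literal") {
    out <- paste0("\"", nt_escape(value), "\"")
    if (!is.na(lang) && nzchar(lang)) return(paste0(out, "@", lang))
    if (!is.na(dt) && nzchar(dt)) {
      cd <- ns_compact(dt, ns)
      return(paste0(out, "^^", if (grepl("^[A-Za-z]", cd) && cd != dt) cd
                    else paste0("<", dt, ">")))
    }
    return(out)
  }
  if (is_blank_node(value)) return(value)
  c <- ns_compact(value, ns)
  if (!identical(c, value)) c else paste0("<", value, ">")
}

graph_to_turtle <- function(g) {
  ns <- g$ns
  core <- ao_core_prefixes()
  # prefixes: the nine seeded bindings always, others only when used
  used_pref <- function(iri_vec) {
    cs <- ns_compact(iri_vec, ns)
    hits <- cs[cs != iri_vec]
    unique(sub(":.*$", "", hits))
  }
  t <- g$triples
  iris <- unique(c(t$s[!is_blank_node(t$s)], t$p,
                   t$o[t$o_type == "iri"],
                   t$dt[!is.na(t$dt)]))
  prefixes <- union(core, used_pref(iris))
  prefixes <- prefixes[order(match(prefixes, names(ns)))]
  header <- vapply(prefixes, function(p) {
    sprintf("@prefix %s: <%s> .", p, ns[[p]])
  }, character(1L))

  body <- character(0)
  if (nrow(t)) {
    subjects <- unique(t$s)
    for (s in subjects) {
      rows <- t[t$s == s, , drop = FALSE]
      sterm <- if (is_blank_node(s)) s else ttl_term_out(s, "iri", NA, NA, ns)
      preds <- unique(rows$p)
      plines <- vapply(seq_along(preds), function(k) {
        p <- preds[[k]]
        prow <- rows[rows$p == p, , drop = FALSE]
        pterm <- if (p == ns_expand("rdf:type", ns)) "a"
                 else ttl_term_out(p, "iri", NA, NA, ns)
        objs <- vapply(seq_len(nrow(prow)), function(i) {
          ttl_term_out(prow$o[[i]], prow$o_type[[i]], prow$dt[[i]],
                       prow$lang[[i]], ns)
        }, character(1L))
        paste0("    ", pterm, " ", paste(objs, collapse = ", "),
               if (k < length(preds)) " ;" else " .")
      }, character(1L))
      body <- c(body, sterm, plines, "")
    }
  }
  paste0(paste(c(header, "", body), collapse = "\n"), "\n")
}

# --- Turtle reader: tokenizer + recursive descent ---

ttl_tokenize <- function(text) {
  tokens <- list()
  n <- nchar(text)
  pos <- 1L
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  }
  peek_re <- function(pattern) {
    m <- regexpr(pattern, substr(text, pos, n), perl = TRUE)
    if (m == 1L) attr(m, "match.length") else 0L
  }
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch, perl = TRUE)) { pos <- pos + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, pos, n), fixed = TRUE)
      pos <- if (nl == -1L) n + 1L else pos + nl
      next
    }
    if (ch == "<") {
      len <- peek_re("^<[^>]*>")
      if (!len) ao_stop("unterminated IRI at char ", pos,
                        class = "aotk_parse_error")
      push("iri", substr(text, pos + 1L, pos + len - 2L))
      pos <- pos + len
      next
    }
    if (ch == "\"" || ch == "'") {
      q <- ch
      len <- peek_re(paste0("^", q, "(?:[^", q, "\\\\]|\\\\.)*", q))
      if (!len) ao_stop("unterminated string at char ", pos,
                        class = "aotk_parse_error")
      push("string", nt_unescape(substr(text, pos + 1L, pos + len - 2L)))
      pos <- pos + len
      next
    }
    if (ch == "^" && substr(text, pos, pos + 1L) == "^^") {
      push("dtsep", "^^"); pos <- pos + 2L; next
    }
    if (ch == "@") {
      len <- peek_re("^@[A-Za-z][A-Za-z0-9-]*")
      word <- substr(text, pos + 1L, pos + len - 1L)
      if (word %in% c("prefix", "base")) push(paste0("kw_", word), word)
      else push("lang", word)
      pos <- pos + len
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch); pos <- pos + 1L; next
    }
    len <- peek_re("^_:[A-Za-z0-9][A-Za-z0-9_.-]*")
    if (len) {
      push("blank", substr(text, pos, pos + len - 1L))
      pos <- pos + len
      next
    }
    len <- peek_re("^[+-]?\\d+\\.\\d+(?:[eE][+-]?\\d+)?")
    if (len) {
      push("decimal", substr(text, pos, pos + len - 1L)); pos <- pos + len; next
    }
    len <- peek_re("^[+-]?\\d+")
    if (len) {
      push("integer", substr(text, pos, pos + len - 1L)); pos <- pos + len; next
    }
    len <- peek_re("^[A-Za-z][A-Za-z0-9_-]*(?=\\s*:)|^(?=:)")
    # prefixed name: PREFIX? ':' LOCAL?
    len2 <- peek_re("^(?:[A-Za-z][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_%][A-Za-z0-9_.%-]*)?")
    if (len2) {
      push("pname", substr(text, pos, pos + len2 - 1L)); pos <- pos + len2; next
    }
    len <- peek_re("^[A-Za-z][A-Za-z0-9_]*")
    if (len) {
      word <- substr(text, pos, pos + len - 1L)
      if (word == "a") push("a", "a")
      else if (tolower(word) == "prefix") push("kw_prefix", word)
      else if (tolower(word) == "base") push("kw_base", word)
      else if (word %in% c("true", "false")) push("boolean", word)
      else ao_stop("unexpected token '", word, "' at char ", pos,
                   class = "aotk_parse_error")
      pos <- pos + len
      next
    }
    ao_stop("unexpected character '", ch, "' at char ", pos,
            class = "aotk_parse_error")
  }
  tokens
}

turtle_to_graph <- function(text, ns = ao_namespaces()) {
  tokens <- ttl_tokenize(text)
  prefixes <- stats::setNames(as.list(unname(ns)), names(ns))
  triples <- list()
  i <- 1L
  bcount <- 0L
  ntok <- length(tokens)
  cur <- function() if (i <= ntok) tokens[[i]] else list(type = "eof")
  advance <- function() i <<- i + 1L
  expect <- function(type) {
    tk <- cur()
    if (tk$type != type) {
      ao_stop("Turtle parse error: expected ", type, " got ", tk$type,
              " near token ", i, class = "aotk_parse_error")
    }
    advance()
    tk
  }
  resolve_pname <- function(pn) {
    parts <- regmatches(pn, regexec("^([^:]*):(.*)$", pn))[[1]]
    pre <- parts[[2]]
    if (!pre %in% names(prefixes)) {
      ao_stop("undefined prefix '", pre, ":'", class = "aotk_parse_error")
    }
    paste0(prefixes[[pre]], parts[[3]])
  }
  add_triple <- function(s, p, o, o_type, dt = NA_character_,
                         lang = NA_character_) {
    triples[[length(triples) + 1L]] <<- data.frame(
      s = s, p = p, o = o, o_type = o_type, dt = dt, lang = lang,
      stringsAsFactors = FALSE)
  }
  parse_object <- function(s, p) {
    tk <- cur()
    if (tk$type == "iri") { advance(); add_triple(s, p, tk$value, "iri"); return() }
    if (tk$type == "pname") { advance(); add_triple(s, p, resolve_pname(tk$value), "iri"); return() }
    if (tk$type == "blank") { advance(); add_triple(s, p, tk$value, "blank"); return() }
    if (tk$type == "[") {
      advance()
      bcount <<- bcount + 1L
      b <- sprintf("_:genb%d", bcount)
      add_triple(s, p, b, "blank")
      if (cur()$type != "]") parse_predicate_object_list(b)
      expect("]")
      return()
    }
    if (tk$type == "string") {
      advance()
      nxt <- cur()
      if (nxt$type == "lang") {
        advance()
        add_triple(s, p, tk$value, "literal", lang = nxt$value)
      } else if (nxt$type == "dtsep") {
        advance()
        dtk <- cur()
        dt <- if (dtk$type == "iri") dtk$value
              else if (dtk$type == "pname") resolve_pname(dtk$value)
              else ao_stop("expected datatype IRI", class = "aotk_parse_error")
        advance()
        add_triple(s, p, tk$value, "literal", dt = dt)
      } else {
        add_triple(s, p, tk$value, "literal")
      }
      return()
    }
    if (tk$type == "integer") {
      advance()
      add_triple(s, p, tk$value, "literal", dt = xsd("integer"))
      return()
    }
    if (tk$type == "decimal") {
      advance()
      add_triple(s, p, tk$value, "literal", dt = xsd("decimal"))
      return()
    }
    if (tk$type == "boolean") {
      advance()
      add_triple(s, p, tk$value, "literal", dt = xsd("boolean"))
      return()
    }
    ao_stop("Turtle parse error: unexpected ", tk$type, " in object position",
            class = "aotk_parse_error")
  }
  parse_predicate_object_list <- function(s) {
    repeat {
      tk <- cur()
      p <- if (tk$type == "a") { advance(); ns_expand("rdf:type") }
           else if (tk$type == "iri") { advance(); tk$value }
           else if (tk$type == "pname") { advance(); resolve_pname(tk$value) }
           else ao_stop("Turtle parse error: expected predicate, got ",
                        tk$type, class = "aotk_parse_error")
      repeat {
        parse_object(s, p)
        if (cur()$type == ",") advance() else break
      }
      if (cur()$type == ";") {
        advance()
        # allow trailing ';' before '.' or ']'
        if (cur()$type %in% c(".", "]")) break
        next
      }
      break
    }
  }
  while (i <= ntok) {
    tk <- cur()
    if (tk$type %in% c("kw_prefix")) {
      advance()
      pn <- expect("pname")$value
      pre <- sub(":$", "", pn)
      iri <- expect("iri")$value
      prefixes[[pre]] <- iri
      if (cur()$type == ".") advance()
      next
    }
    if (tk$type %in% c("kw_base")) {
      advance()
      expect("iri")
      if (cur()$type == ".") advance()
      next
    }
    s <- if (tk$type == "iri") { advance(); tk$value }
         else if (tk$type == "pname") { advance(); resolve_pname(tk$value) }
         else if (tk$type == "blank") { advance(); tk$value }
         else if (tk$type == "[") {
           advance()
           bcount <- bcount + 1L
           b <- sprintf("_:genb%d", bcount)
           if (cur()$type != "]") parse_predicate_object_list(b)
           expect("]")
           b
         }
         else ao_stop("Turtle parse error: unexpected ", tk$type,
                      " in subject position", class = "aotk_parse_error")
    parse_predicate_object_list(s)
    expect(".")
  }
  ao_graph(do.call(rbind, c(list(empty_triples()), triples)), ns)
}

# ---------------------------------------------------------------------------
# RDF/XML

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Split an IRI into (namespace, NCName local); NULL when impossible.
split_qname <- function(iri) {
  m <- regmatches(iri, regexec("^(.*[/#])([A-Za-z_][A-Za-z0-9_.-]*)$", iri))[[1]]
  if (length(m) != 3L) return(NULL)
  list(ns = m[[2]], local = m[[3]])
}

graph_to_rdfxml <- function(g) {
  ns <- g$ns
  t <- g$triples
  # collect namespace declarations for all predicates
  extra <- list()
  pred_qname <- function(p) {
    c <- ns_compact(p, ns)
    if (!identical(c, p) && grepl("^[A-Za-z]", c)) {
      parts <- strsplit(c, ":", fixed = TRUE)[[1]]
      # XML prefixes may not contain '-@' issues; swan-agent is a valid
      # XML NCName prefix
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", parts[[1]]) &&
          grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", parts[[2]])) {
        return(list(prefix = parts[[1]], local = parts[[2]],
                    ns = unname(ns[[parts[[1]]]])))
      }
    }
    sq <- split_qname(p)
    if (is.null(sq)) ao_stop("cannot form a QName for predicate <", p, ">")
    key <- sq$ns
    if (is.null(extra[[key]])) {
      extra[[key]] <<- sprintf("ns%d", length(extra) + 1L)
    }
    list(prefix = extra[[key]], local = sq$local, ns = sq$ns)
  }
  body <- character(0)
  decls <- character(0)
  seen_ns <- character(0)
  note_ns <- function(prefix, nsiri) {
    if (!prefix %in% seen_ns) {
      seen_ns <<- c(seen_ns, prefix)
      decls <<- c(decls, sprintf('xmlns:%s="%s"', prefix, xml_escape(nsiri)))
    }
  }
  note_ns("rdf", unname(ns[["rdf"]]))
  if (nrow(t)) {
    for (s in unique(t$s)) {
      rows <- t[t$s == s, , drop = FALSE]
      sattr <- if (is_blank_node(s)) {
        sprintf('rdf:nodeID="%s"', substring(s, 3L))
      } else {
        sprintf('rdf:about="%s"', xml_escape(s))
      }
      body <- c(body, sprintf("  <rdf:Description %s>", sattr))
      for (i in seq_len(nrow(rows))) {
        q <- pred_qname(rows$p[[i]])
        note_ns(q$prefix, q$ns)
        tag <- paste0(q$prefix, ":", q$local)
        o <- rows$o[[i]]
        if (rows$o_type[[i]] == "literal") {
          attrs <- ""
          if (!is.na(rows$lang[[i]]) && nzchar(rows$lang[[i]])) {
            attrs <- sprintf(' xml:lang="%s"', rows$lang[[i]])
          } else if (!is.na(rows$dt[[i]]) && nzchar(rows$dt[[i]])) {
            attrs <- sprintf(' rdf:datatype="%s"', xml_escape(rows$dt[[i]]))
          }
          body <- c(body, sprintf("    <%s%s>%s</%s>", tag, attrs,
                                  xml_escape(o), tag))
        } else if (is_blank_node(o)) {
          body <- c(body, sprintf('    <%s rdf:nodeID="%s"/>', tag,
                                  substring(o, 3L)))
        } else {
          body <- c(body, sprintf('    <%s rdf:resource="%s"/>', tag,
                                  xml_escape(o)))
        }
      }
      body <- c(body, "  </rdf:Description>")
    }
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<rdf:RDF ", paste(decls, collapse = "\n         "), ">\n",
    paste(body, collapse = "\n"),
    if (length(body)) "\n", "</rdf:RDF>\n"
  )
}

rdfxml_to_graph <- function(text, ns = ao_namespaces()) {
  doc <- xml2::read_xml(text)
  nsmap <- xml2::xml_ns(doc)
  rdf_ns <- unname(ns[["rdf"]])
  triples <- list()
  bcount <- new.env(parent = emptyenv())
  bcount$n <- 0L
  add_triple <- function(s, p, o, o_type, dt = NA_character_,
                         lang = NA_character_) {
    triples[[length(triples) + 1L]] <<- data.frame(
      s = s, p = p, o = o, o_type = o_type, dt = dt, lang = lang,
      stringsAsFactors = FALSE)
  }
  attr_of <- function(node, local) {
    at <- xml2::xml_attrs(node)
    hit <- names(at)[names(at) == local |
                       endsWith(names(at), paste0(":", local))]
    if (length(hit)) unname(at[[hit[[1L]]]]) else NA_character_
  }
  node_iri <- function(node) {
    # full IRI of an element (namespace URI + local name)
    nm <- xml2::xml_name(node, nsmap)   # "prefix:local" or "local"
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[[1]] %in% names(nsmap)) {
      paste0(nsmap[[parts[[1]]]], parts[[2]])
    } else {
      nm
    }
  }
  parse_node <- function(node) {
    about <- attr_of(node, "about")
    nodeid <- attr_of(node, "nodeID")
    s <- if (!is.na(about)) about
         else if (!is.na(nodeid)) paste0("_:", nodeid)
         else {
           bcount$n <- bcount$n + 1L
           sprintf("_:xb%d", bcount$n)
         }
    el_iri <- node_iri(node)
    if (!identical(el_iri, paste0(rdf_ns, "Description"))) {
      add_triple(s, paste0(rdf_ns, "type"), el_iri, "iri")
    }
    for (child in xml2::xml_children(node)) {
      p <- node_iri(child)
      resource <- attr_of(child, "resource")
      cnodeid <- attr_of(child, "nodeID")
      if (!is.na(resource)) {
        add_triple(s, p, resource, "iri")
      } else if (!is.na(cnodeid)) {
        add_triple(s, p, paste0("_:", cnodeid), "blank")
      } else {
        grand <- xml2::xml_children(child)
        if (length(grand) > 0L) {
          o <- parse_node(grand[[1L]])
          add_triple(s, p, o, if (is_blank_node(o)) "blank" else "iri")
        } else {
          dt <- attr_of(child, "datatype")
          lang <- attr_of(child, "lang")
          add_triple(s, p, xml2::xml_text(child), "literal",
                     dt = if (is.na(dt)) NA_character_ else dt,
                     lang = if (is.na(lang)) NA_character_ else lang)
        }
      }
    }
    s
  }
  for (node in xml2::xml_children(doc)) parse_node(node)
  ao_graph(do.call(rbind, c(list(empty_triples()), triples)), ns)
}

# ---------------------------------------------------------------------------
# JSON-LD (expanded form)

graph_to_jsonld <- function(g) {
  t <- g$triples
  rdf_type <- ns_expand("rdf:type")
  nodes <- list()
  for (s in unique(t$s)) {
    rows <- t[t$s == s, , drop = FALSE]
    obj <- list("@id" = s)
    types <- rows$o[rows$p == rdf_type & rows$o_type != "literal"]
    if (length(types)) obj[["@type"]] <- as.list(types)
    for (p in unique(rows$p[rows$p != rdf_type])) {
      prow <- rows[rows$p == p, , drop = FALSE]
      vals <- lapply(seq_len(nrow(prow)), function(i) {
        if (prow$o_type[[i]] == "literal") {
          v <- list("@value" = prow$o[[i]])
          if (!is.na(prow$lang[[i]]) && nzchar(prow$lang[[i]])) {
            v[["@language"]] <- prow$lang[[i]]
          } else if (!is.na(prow$dt[[i]]) && nzchar(prow$dt[[i]])) {
            v[["@type"]] <- prow$dt[[i]]
          }
          v
        } else {
          list("@id" = prow$o[[i]])
        }
      })
      obj[[p]] <- vals
    }
    nodes[[length(nodes) + 1L]] <- obj
  }
  jsonlite::toJSON(nodes, auto_unbox = TRUE, pretty = TRUE)
}

jsonld_to_graph <- function(text, ns = ao_namespaces()) {
  nodes <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      ao_stop("invalid JSON-LD: ", conditionMessage(e),
              class = "aotk_parse_error")
    })
  triples <- list()
  add_triple <- function(s, p, o, o_type, dt = NA_character_,
                         lang = NA_character_) {
    triples[[length(triples) + 1L]] <<- data.frame(
      s = s, p = p, o = o, o_type = o_type, dt = dt, lang = lang,
      stringsAsFactors = FALSE)
  }
  rdf_type <- ns_expand("rdf:type")
  for (node in nodes) {
    s <- node[["@id"]]
    if (is.null(s)) ao_stop("JSON-LD node without @id",
                            class = "aotk_parse_error")
    for (ty in node[["@type"]]) add_triple(s, rdf_type, ty, "iri")
    for (p in setdiff(names(node), c("@id", "@type"))) {
      vals <- node[[p]]
      if (!is.null(names(vals))) vals <- list(vals)
      for (v in vals) {
        if (!is.null(v[["@id"]])) {
          o <- v[["@id"]]
          add_triple(s, p, o, if (is_blank_node(o)) "blank" else "iri")
        } else {
          add_triple(s, p, as.character(v[["@value"]]), "literal",
                     dt = v[["@type"]] %||% NA_character_,
                     lang = v[["@language"]] %||% NA_character_)
        }
      }
    }
  }
  ao_graph(do.call(rbind, c(list(empty_triples()), triples)), ns)
}
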