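# User-facing serialization front end.

AO_FORMATS <- c("turtle", "rdfxml", "ntriples", "jsonld")

format_writer <- function(format) {
  switch(format,
    turtle = graph_to_turtle,
    rdfxml = graph_to_rdfxml,
    ntriples = graph_to_ntriples,
    jsonld = function(g) as.character(graph_to_jsonld(g)))
}

format_reader <- function(format) {
  switch(format,
    turtle = turtle_to_graph,
    rdfxml = rdfxml_to_graph,
    ntriples = ntriples_to_graph,
    jsonld = jsonld_to_graph)
}

#' Guess the RDF format from a file extension
#' @param path file path.
#' @return one of `"turtle"`, `"rdfxml"`, `"ntriples"`, `"jsonld"`.
#' @export
ao_format_from_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
    ttl = "turtle", turtle = "turtle",
    rdf = "rdfxml", xml = "rdfxml", owl = "rdfxml",
    nt = "ntriples",
    jsonld = "jsonld", json = "jsonld",
    ao_stop("cannot guess RDF format for '", path, "'"))
}

#' Serialize annotation entities to RDF
#'
#' Converts entities to a triple graph (validating them first; see
#' [ao_to_graph()] for the emission flags) and writes it in one of the
#' four supported syntaxes. Turtle output always binds the nine
#' registry prefixes (`ao`, `aos`, `aot`, `aoa`, `aof`, `pav`,
#' `swan-agent`, `swan`, `ann`) byte-exact.
#'
#' @param entities domain objects (or an already-built `ao_graph`).
#' @param format `"turtle"` (default), `"rdfxml"`, `"ntriples"` or
#'   `"jsonld"`.
#' @param file optional path; when given the serialization is written
#'   there and returned invisibly.
#' @param ... passed to [ao_to_graph()] (`foaf`, `sioc`,
#'   `sioc_set_compat`, `topics_as_restrictions`).
#' @return the serialized document as a single UTF-8 string.
#' @examples
#' doc <- ao_document_ref("http://ex.org/doc")
#' a <- ao_agent("http://ex.org/alice", "person", "Alice")
#' ann <- new_annotation("Note", a, list(doc), body = "interesting")
#' cat(ao_serialize(ann, "turtle"))
#' @export
ao_serialize <- function(entities, format = "turtle", file = NULL, ...) {
  format <- match.arg(format, AO_FORMATS)
  g <- if (inherits(entities, "ao_graph")) entities else ao_to_graph(entities, ...)
  out <- format_writer(format)(g)
  if (!is.null(file)) {
    writeLines(out, file, sep = "", useBytes = FALSE)
    return(invisible(out))
  }
  out
}

#' Parse RDF into annotation entities
#'
#' Reads one of the four supported syntaxes into a triple graph and
#' reconstructs the domain objects; the inverse of [ao_serialize()] up
#' to graph isomorphism. Unknown predicates and structural violations
#' are collected in `$warnings` / `$violations`, not raised; a syntax
#' error raises an `aotk_parse_error`.
#'
#' @param data RDF content as a string, or a path to a file.
#' @param format `"turtle"`, `"rdfxml"`, `"ntriples"` or `"jsonld"`;
#'   guessed from the file extension when `data` is a path and
#'   `format` is missing.
#' @return a list with `annotations`, `sets`, `tokens`, `documents`,
#'   `agents`, `selectors`, `violations`, `warnings` and the raw
#'   `graph`.
#' @export
ao_parse <- function(data, format = NULL) {
  if (is_string(data) && !grepl("[\n<{@]", data) && file.exists(data)) {
    if (is.null(format)) format <- ao_format_from_path(data)
    data <- paste(readLines(data, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  }
  if (is.null(format)) ao_stop("`format` must be given for literal content")
  format <- match.arg(format, AO_FORMATS)
  g <- format_reader(format)(data)
  out <- graph_to_entities(g)
  out$graph <- g
  out
}

#' Convert an RDF document between syntaxes
#'
#' @param input path or content string.
#' @param from,to source and target formats.
#' @param file optional output path.
#' @return serialized string (invisibly when `file` is given).
#' @export
ao_convert <- function(input, from = NULL, to = "turtle", file = NULL) {
  parsed <- ao_parse(input, from)
  to <- match.arg(to, AO_FORMATS)
  out <- format_writer(to)(parsed$graph)
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}
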