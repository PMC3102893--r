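test_that("the namespace registry binds the nine core prefixes exactly", {
  ns <- ao_namespaces()
  expect_identical(ns[["ao"]], "http://purl.org/ao/")
  expect_identical(ns[["aos"]], "http://purl.org/ao/selectors/")
  expect_identical(ns[["aot"]], "http://purl.org/ao/types/")
  expect_identical(ns[["aoa"]], "http://purl.org/ao/annotea/")
  expect_identical(ns[["aof"]], "http://purl.org/ao/foaf/")
  expect_identical(ns[["pav"]], "http://purl.org/pav/2.0/")
  expect_identical(ns[["swan-agent"]], "http://purl.org/swan/2.0/agents/")
  expect_identical(ns[["swan"]], "http://purl.org/swan/2.0/")
  expect_identical(ns[["ann"]], "http://www.w3.org/2000/10/annotation-ns#")
})

test_that("ntriples writer/parser round-trips literals with escapes", {
  g <- ao_graph()
  g <- aotk:::lit(g, "http://ex.org/s", "http://ex.org/p",
                  "line1\nline2\t\"quoted\" \\slash")
  g <- aotk:::lit(g, "http://ex.org/s", "http://ex.org/q", "42",
                  dt = "http://www.w3.org/2001/XMLSchema#integer")
  g <- aotk:::lit(g, "http://ex.org/s", "http://ex.org/r", "chat",
                  lang = "fr")
  nt <- aotk:::graph_to_ntriples(g)
  g2 <- aotk:::ntriples_to_graph(nt)
  expect_true(graphs_isomorphic(g, g2))
  expect_true(grepl("\\\\n", nt))      # newline escaped on the wire
})

test_that("turtle parser handles prefixes, lists of objects and blanks", {
  ttl <- paste0(
    "@prefix ex: <http://ex.org/> .\n",
    "ex:s a ex:T ; ex:p \"a\", \"b\"@en, 5, 2.5, true ;\n",
    "     ex:q [ ex:r ex:s2 ] .\n",
    "_:b0 ex:p ex:s .\n")
  g <- aotk:::turtle_to_graph(ttl)
  expect_equal(aotk:::graph_size(g), 9L)
  again <- aotk:::turtle_to_graph(aotk:::graph_to_turtle(g))
  expect_true(graphs_isomorphic(g, again))
})

test_that("turtle syntax errors raise parse conditions", {
  expect_error(aotk:::turtle_to_graph("ex:s ex:p"),
               class = "aotk_parse_error")
  expect_error(aotk:::turtle_to_graph("@prefix ex <http://x/> ."),
               class = "aotk_parse_error")
  expect_error(ao_parse("{ not json-ld", "jsonld"),
               class = "aotk_parse_error")
})

test_that("all four formats round-trip an entity graph isomorphically", {
  ann <- t_full_annotation(3)
  g <- ao_to_graph(list(ann))
  for (f in c("turtle", "rdfxml", "ntriples", "jsonld")) {
    txt <- ao_serialize(list(ann), f)
    g2 <- aotk:::format_reader(f)(txt)
    expect_true(graphs_isomorphic(g, g2), label = paste("format", f))
  }
})

test_that("parsing reconstructs equivalent domain objects", {
  ann <- t_full_annotation(4)
  ttl <- ao_serialize(list(ann), "turtle")
  p <- ao_parse(ttl, "turtle")
  expect_length(p$annotations, 1L)
  back <- p$annotations[[1]]
  expect_identical(back$uri, ann$uri)
  expect_identical(back$ann_type, ann$ann_type)
  expect_identical(back$body, ann$body)
  expect_identical(back$created_on, ann$created_on)
  expect_identical(back$created_by$uri, ann$created_by$uri)
  expect_identical(
    sort(vapply(back$topics, function(t) t$term$uri, character(1))),
    sort(vapply(ann$topics, function(t) t$term$uri, character(1))))
  expect_identical(
    sort(vapply(back$topics, `[[`, character(1), "level")),
    sort(vapply(ann$topics, `[[`, character(1), "level")))
  expect_length(back$targets, length(ann$targets))
  expect_equal(nrow(p$violations), 0L)
})

test_that("ao_convert translates between syntaxes losslessly", {
  ann <- t_full_annotation(5)
  ttl <- ao_serialize(list(ann), "turtle")
  xml <- ao_convert(ttl, from = "turtle", to = "rdfxml")
  nt <- ao_convert(xml, from = "rdfxml", to = "ntriples")
  g1 <- aotk:::turtle_to_graph(ttl)
  g3 <- aotk:::ntriples_to_graph(nt)
  expect_true(graphs_isomorphic(g1, g3))
})

test_that("serialization goes to and comes back from files", {
  ann <- t_full_annotation(6)
  tf <- tempfile(fileext = ".ttl")
  on.exit(unlink(tf))
  ao_serialize(list(ann), "turtle", file = tf)
  p <- ao_parse(tf)          # format guessed from extension
  expect_length(p$annotations, 1L)
  expect_identical(p$annotations[[1]]$uri, ann$uri)
})

test_that("unknown predicates are warnings-as-data, not errors", {
  ttl <- paste0(
    "@prefix aof: <http://purl.org/ao/foaf/> .\n",
    "@prefix aot: <http://purl.org/ao/types/> .\n",
    "@prefix pav: <http://purl.org/pav/2.0/> .\n",
    "@prefix ann: <http://www.w3.org/2000/10/annotation-ns#> .\n",
    "<http://ex.org/a1> a aot:Note ;\n",
    "  ann:body \"note\" ;\n",
    "  pav:createdOn \"2024-01-01T00:00:00Z\" ;\n",
    "  aof:annotatesDocument <http://ex.org/doc> ;\n",
    "  <http://ex.org/custom#weird> \"extra\" .\n")
  p <- ao_parse(ttl, "turtle")
  expect_length(p$annotations, 1L)
  expect_true(any(grepl("custom#weird", p$warnings)))
})

test_that("graph isomorphism distinguishes non-isomorphic blank graphs", {
  # chain of two blanks vs two disconnected blanks, same triple count
  ttl_a <- paste0("@prefix ex: <http://e/> .\n",
                  "_:x ex:p _:y . _:y ex:p _:x .\n")
  ttl_b <- paste0("@prefix ex: <http://e/> .\n",
                  "_:x ex:p _:x . _:y ex:p _:y .\n")
  ga <- aotk:::turtle_to_graph(ttl_a)
  gb <- aotk:::turtle_to_graph(ttl_b)
  expect_false(graphs_isomorphic(ga, gb))
  expect_true(graphs_isomorphic(ga, ga))
})

test_that("fixed-vocabulary invariant: unknown AO-namespace terms error", {
  g <- ao_graph()
  g <- aotk:::res(g, "http://ex.org/s", "http://purl.org/ao/madeUpProp",
                  "http://ex.org/o")
  expect_error(aotk:::check_ao_vocabulary(g), "madeUpProp")
})

test_that("annotea down-conversion keeps xpointers and flags loss", {
  doc <- t_doc(9)
  xp <- ao_xpointer_selector("xpointer(/p[2])", on_document = doc$page_uri,
                             seed = 91)
  a1 <- new_annotation("Note", t_agent(), list(xp), body = "kept", seed = 92)
  g1 <- to_annotea(a1)
  expect_false(attr(g1, "lossy"))
  back <- from_annotea(g1)[[1]]
  expect_identical(back$body, "kept")
  xps <- Filter(function(s) inherits(s, "ao_xpointer_selector"), back$targets)
  expect_identical(xps[[1]]$expression, "xpointer(/p[2])")
  # text-quote selector alone cannot be expressed -> lossy
  tq <- ao_text_quote_selector("frag", on_document = doc$page_uri, seed = 93)
  a2 <- new_annotation("Note", t_agent(), list(tq), body = "b", seed = 94)
  expect_true(attr(to_annotea(a2), "lossy"))
})
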