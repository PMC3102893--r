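test_that("qualifier grades map onto the SKOS mapping vocabulary", {
  expect_identical(
    qualifier_skos_property(c("related", "exact", "close", "broad",
                              "narrow")),
    paste0("http://www.w3.org/2004/02/skos/core#",
           c("relatedMatch", "exactMatch", "closeMatch", "broadMatch",
             "narrowMatch")))
  expect_error(qualifier_skos_property("fuzzy"))
})

test_that("exact + narrow on one anchor yields a single narrowMatch", {
  sel <- ao_text_quote_selector("BACE1", "the protein ", " cleaves",
                                seed = 11)
  pro <- ao_term("http://purl.org/obo/owl/PRO#PRO_000013562",
                 "Beta-Secretase 1")
  birn <- ao_term(
    "http://bioontology.org/projects/ontologies/birnlex#birnlex_23",
    "protein")
  q1 <- new_annotation("ExactQualifier", t_agent(1), list(sel),
                       topics = list(pro), seed = 12)
  q2 <- new_annotation("NarrowQualifier", t_agent(2), list(sel),
                       topics = list(birn), seed = 13)
  m <- infer_cross_ontology(list(q1, q2))
  expect_equal(nrow(m), 1L)
  expect_identical(m$subject_term, pro$uri)
  expect_identical(m$skos_property,
                   "http://www.w3.org/2004/02/skos/core#narrowMatch")
  expect_identical(m$object_term, birn$uri)
  expect_setequal(m$evidence[[1]], c(q1$uri, q2$uri))
  # order of the inputs must not matter
  expect_identical(mapping_keys(infer_cross_ontology(list(q2, q1))),
                   mapping_keys(m))
})

test_that("two exact qualifiers compose to exactMatch, none to related", {
  doc <- t_doc(20)
  mk <- function(ty, term, lvl, s) {
    new_annotation(ty, t_agent(1), list(doc),
                   topics = list(list(term = term, level = lvl)), seed = s)
  }
  ee <- infer_cross_ontology(list(
    mk("ExactQualifier", t_term(1), "exact", 21),
    mk("ExactQualifier", t_term(2), "exact", 22)))
  expect_identical(ee$skos_property,
                   "http://www.w3.org/2004/02/skos/core#exactMatch")
  bb <- infer_cross_ontology(list(
    mk("BroadQualifier", t_term(1), "broad", 23),
    mk("NarrowQualifier", t_term(2), "narrow", 24)))
  expect_identical(bb$skos_property,
                   "http://www.w3.org/2004/02/skos/core#relatedMatch")
  expect_equal(nrow(bb), 1L)   # symmetric duplicate collapsed
})

test_that("annotations on different anchors never compose", {
  q1 <- new_annotation("ExactQualifier", t_agent(1), list(t_doc(1)),
                       topics = list(t_term(1)), seed = 31)
  q2 <- new_annotation("NarrowQualifier", t_agent(1), list(t_doc(2)),
                       topics = list(t_term(2)), seed = 32)
  expect_equal(nrow(infer_cross_ontology(list(q1, q2))), 0L)
})

test_that("instance-level terms are flagged, not suppressed", {
  doc <- t_doc(3)
  ind <- ao_term("http://test.org/ind#i1", "an individual", is_class = FALSE)
  q1 <- new_annotation("ExactQualifier", t_agent(1), list(doc),
                       topics = list(list(term = ind, level = "exact")),
                       seed = 41)
  q2 <- new_annotation("CloseQualifier", t_agent(1), list(doc),
                       topics = list(list(term = t_term(9), level = "close")),
                       seed = 42)
  m <- infer_cross_ontology(list(q1, q2))
  expect_equal(nrow(m), 1L)
  expect_true(m$instance_level)
})

test_that("mappings serialize to parseable SKOS turtle", {
  sel <- ao_text_quote_selector("x", seed = 51)
  q1 <- new_annotation("ExactQualifier", t_agent(1), list(sel),
                       topics = list(t_term(1)), seed = 52)
  q2 <- new_annotation("BroadQualifier", t_agent(1), list(sel),
                       topics = list(list(term = t_term(2), level = "broad")),
                       seed = 53)
  ttl <- mappings_to_turtle(infer_cross_ontology(list(q1, q2)))
  g <- aotk:::turtle_to_graph(ttl)
  expect_equal(aotk:::graph_size(g), 1L)
  expect_identical(g$triples$p,
                   "http://www.w3.org/2004/02/skos/core#broadMatch")
})

test_that("a MOAT tagging migrates to graded qualifiers and back", {
  # a tag with one broader meaning -> one BroadQualifier
  frac <- ao_term("http://test.org/onto#SkullFracture", "Skull fracture")
  tg <- ao_tagging("Linear skull fracture",
                   list(list(level = "broad", term = frac)))
  doc <- t_doc(30)
  anns <- moat_to_ao(tg, doc, t_agent(5), seed = 61)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$ann_type, "BroadQualifier")
  expect_identical(anns[[1]]$body, "Linear skull fracture")
  expect_identical(anns[[1]]$topics[[1]]$term$uri, frac$uri)
  expect_identical(anns[[1]]$topics[[1]]$level, "broad")
  g <- ao_to_moat(anns[[1]])
  back <- moat_graph_to_tagging(g)
  expect_length(back, 1L)
  expect_identical(back[[1]]$tag_label, tg$tag_label)
  expect_identical(back[[1]]$meanings[[1]]$level, "broad")
  expect_identical(back[[1]]$meanings[[1]]$term$uri, frac$uri)
})

test_that("meaning-less taggings become body-only qualifiers (plain tags)", {
  anns <- moat_to_ao(ao_tagging("just-a-tag"), t_doc(31), t_agent(1),
                     seed = 62)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$ann_type, "Qualifier")
  expect_identical(anns[[1]]$body, "just-a-tag")
  expect_length(anns[[1]]$topics, 0L)
})

test_that("the MOAT graph uses the MOAT/tags vocabulary", {
  tg <- ao_tagging("t", list(list(level = "exact", term = t_term(1))))
  ann <- moat_to_ao(tg, t_doc(32), t_agent(1), seed = 63)[[1]]
  g <- ao_to_moat(ann)
  preds <- unique(g$triples$o[g$triples$p ==
    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"])
  expect_true("http://www.holygoat.co.uk/owl/redwood/0.1/tags/RestrictedTagging"
              %in% preds)
  expect_true("http://moat-project.org/ns#Tag" %in% preds)
  expect_true("http://moat-project.org/ns#Meaning" %in% preds)
})
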