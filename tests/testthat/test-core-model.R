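test_that("mint_uri is deterministic with a seed and unique without", {
  expect_identical(mint_uri("http://ex.org/ao/", "annotation", seed = 7),
                   mint_uri("http://ex.org/ao/", "annotation", seed = 7))
  expect_match(mint_uri("http://ex.org/ao/", "annotation", seed = 7),
               "^http://ex\\.org/ao/annotation/seed-7$")
  u <- replicate(50, mint_uri("http://ex.org/ao/", "annotation"))
  expect_equal(anyDuplicated(u), 0L)
  expect_true(all(is_absolute_iri(u)))
})

test_that("mint_uri rejects bad configuration", {
  expect_error(mint_uri("not-an-iri", "x"), class = "aotk_config_error")
  expect_error(mint_uri("http://ex.org/ao", "x"), class = "aotk_config_error")
  expect_error(mint_uri("http://ex.org/ao/", ""), class = "aotk_config_error")
  expect_error(mint_uri("http://ex.org/ao/", "x", seed = "a"),
               class = "aotk_config_error")
})

test_that("agent constructor validates kind and uri", {
  a <- ao_agent("http://ex.org/a", "software", "Bot")
  expect_s3_class(a, "ao_agent")
  expect_equal(nrow(ao_validate(a)), 0L)
  expect_error(ao_agent("relative/path"), class = "aotk_error")
  expect_error(ao_agent("http://ex.org/a", "robot"))
})

test_that("document refs order versions and reject page-uri collisions", {
  v1 <- ao_source_version("http://ex.org/d?v=1", "2024-01-01T00:00:00Z")
  v2 <- ao_source_version("http://ex.org/d?v=2", "2024-01-02T00:00:00Z")
  d <- ao_document_ref("http://ex.org/d", list(v1, v2))
  expect_equal(nrow(ao_validate(d)), 0L)
  expect_error(ao_document_ref("http://ex.org/d", list(v2, v1)),
               "sorted")
  expect_error(ao_document_ref(
    "http://ex.org/d",
    list(ao_source_version("http://ex.org/d", "2024-01-01T00:00:00Z"))),
    "differ")
  expect_error(ao_source_version("http://ex.org/d?v=1", "yesterday"),
               "ISO-8601")
  expect_error(ao_source_version("http://ex.org/d?v=1",
                                 content_digest = "xyz"), "hex")
})

test_that("content_digest matches a known MD5", {
  # md5("abc") is a published constant
  expect_identical(content_digest("abc"),
                   "900150983cd24fb0d6963f7d28e17f72")
})

test_that("annotation type rules: content types need a body", {
  a <- t_agent()
  d <- t_doc()
  for (ty in c("Note", "Errata", "Example", "Definition")) {
    expect_error(new_annotation(ty, a, list(d)),
                 class = "aotk_validation_error")
    ann <- new_annotation(ty, a, list(d), body = "text")
    expect_equal(ann$ann_type, ty)
    expect_equal(nrow(ao_validate(ann)), 0L)
  }
})

test_that("qualifiers need a topic or a free-text body", {
  a <- t_agent()
  d <- t_doc()
  expect_error(new_annotation("Qualifier", a, list(d)),
               class = "aotk_validation_error")
  tagish <- new_annotation("Qualifier", a, list(d), body = "free tag")
  expect_equal(nrow(ao_validate(tagish)), 0L)
  semantic <- new_annotation("ExactQualifier", a, list(d),
                             topics = list(t_term(1)))
  expect_equal(semantic$topics[[1]]$level, "exact")
})

test_that("annotations require at least one valid target", {
  a <- t_agent()
  expect_error(new_annotation("Note", a, list(), body = "x"),
               class = "aotk_validation_error")
  expect_error(new_annotation("Note", a, list("http://ex.org/d"), body = "x"),
               class = "aotk_validation_error")
})

test_that("add_topic refines the qualifier subtype and is non-mutating", {
  a <- t_agent()
  d <- t_doc()
  q <- new_annotation("Qualifier", a, list(d), body = "tag")
  q2 <- add_topic(q, t_term(1), "narrow")
  expect_equal(q2$ann_type, "NarrowQualifier")
  expect_equal(length(q2$topics), 1L)
  expect_equal(q$ann_type, "Qualifier")   # input untouched
  expect_equal(length(q$topics), 0L)
  # per-topic levels are preserved when mixed
  q3 <- add_topic(q2, t_term(2), "exact")
  expect_equal(q3$ann_type, "ExactQualifier")
  expect_equal(vapply(q3$topics, `[[`, character(1), "level"),
               c("narrow", "exact"))
})

test_that("add_topic on a Note requires promote", {
  n <- new_annotation("Note", t_agent(), list(t_doc()), body = "hm")
  expect_error(add_topic(n, t_term(1), "exact"),
               class = "aotk_validation_error")
  p <- add_topic(n, t_term(1), "exact", promote = TRUE)
  expect_equal(p$ann_type, "ExactQualifier")
})

test_that("curation tokens enforce exact spelling of core statuses", {
  tk <- ao_curation_token("accepted", t_agent(), "2024-01-01T00:00:00Z")
  expect_equal(nrow(ao_validate(tk)), 0L)
  bad <- ao_curation_token("Accepted", t_agent(), "2024-01-01T00:00:00Z")
  v <- ao_validate(bad)
  expect_true("core_spelling" %in% v$rule)
  # non-core statuses are open
  open <- ao_curation_token("needs-evidence", t_agent(),
                            "2024-01-01T00:00:00Z")
  expect_equal(nrow(ao_validate(open)), 0L)
})

test_that("curation chain cycles are detected when context is supplied", {
  a <- t_agent()
  t1 <- ao_curation_token("created", a, "2024-01-01T00:00:00Z",
                          uri = "http://ex.org/c1",
                          previous = "http://ex.org/c2")
  t2 <- ao_curation_token("accepted", a, "2024-01-02T00:00:00Z",
                          uri = "http://ex.org/c2",
                          previous = "http://ex.org/c1")
  chain <- list("http://ex.org/c1" = t1, "http://ex.org/c2" = t2)
  v <- ao_validate(t2, chain = chain)
  expect_true("acyclic" %in% v$rule)
})

test_that("annotation sets reject duplicate members", {
  expect_error(ao_annotation_set(c("http://ex.org/a1", "http://ex.org/a1"),
                                 t_agent()),
               class = "aotk_validation_error")
})

test_that("validation reports violations as data, not conditions", {
  ann <- new_annotation("Note", t_agent(), list(t_doc()), body = "x")
  ann$body <- NULL                      # break it by hand
  ann$uri <- "not absolute"
  v <- ao_validate(ann)
  expect_s3_class(v, "data.frame")
  expect_setequal(v$rule, c("absolute_iri", "non_empty_body"))
})
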