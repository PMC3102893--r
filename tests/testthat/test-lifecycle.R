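mk_store_with_ann <- function(seed = 1) {
  st <- ao_store()
  ann <- new_annotation("Note", t_agent(seed), list(t_doc(seed)),
                        created_on = "2024-01-01T00:00:00Z",
                        body = "note", seed = seed * 100L)
  store_add(st, ann)
  list(store = st, ann = ann)
}

test_that("the store is append-only", {
  x <- mk_store_with_ann()
  expect_error(store_add(x$store, x$ann), class = "aotk_store_error")
  expect_error(store_get(x$store, "http://nowhere/"),
               class = "aotk_store_error")
  expect_equal(store_size(x$store), 1L)
})

test_that("curation tokens chain via previous and report effective status", {
  x <- mk_store_with_ann()
  expect_identical(effective_status(x$store, x$ann$uri), "uncurated")
  a <- t_agent(2)
  t1 <- add_curation(x$store, x$ann$uri, "created", a,
                     "2024-01-02T00:00:00Z")
  t2 <- add_curation(x$store, x$ann$uri, "accepted", a,
                     "2024-01-03T00:00:00Z")
  expect_null(t1$previous)
  expect_identical(t2$previous, t1$uri)
  tl <- curation_timeline(x$store, x$ann$uri)
  expect_identical(vapply(tl, `[[`, character(1), "status"),
                   c("created", "accepted"))
  expect_identical(effective_status(x$store, x$ann$uri), "accepted")
  # existing token records untouched
  expect_null(store_get(x$store, t1$uri)$previous)
})

test_that("curating an unknown annotation errors", {
  x <- mk_store_with_ann()
  expect_error(add_curation(x$store, "http://nowhere/", "accepted",
                            t_agent(1)),
               class = "aotk_store_error")
})

test_that("out-of-order curation dates warn but append", {
  x <- mk_store_with_ann()
  a <- t_agent(1)
  add_curation(x$store, x$ann$uri, "created", a, "2024-01-05T00:00:00Z")
  expect_warning(
    add_curation(x$store, x$ann$uri, "accepted", a, "2024-01-01T00:00:00Z"),
    class = "aotk_warning")
  expect_length(curation_timeline(x$store, x$ann$uri), 2L)
})

test_that("timelines reconstruct from dates when pointers are absent", {
  x <- mk_store_with_ann()
  a <- t_agent(1)
  dates <- c("2024-02-03T00:00:00Z", "2024-02-01T00:00:00Z",
             "2024-02-02T00:00:00Z")
  suppressWarnings(
    for (d in dates) add_curation(x$store, x$ann$uri, paste0("s", d), a,
                                  d, link_previous = FALSE))
  tl <- curation_timeline(x$store, x$ann$uri)
  expect_identical(vapply(tl, `[[`, character(1), "curated_on"),
                   sort(dates))
})

test_that("annotation versioning increments and preserves the original", {
  x <- mk_store_with_ann()
  v2 <- new_annotation_version(x$store, x$ann$uri,
                               edits = list(body = "edited"))
  expect_identical(v2$previous_version, x$ann$uri)
  expect_equal(v2$version_number, 2L)
  expect_identical(store_get(x$store, x$ann$uri)$body, "note")
  v3 <- new_annotation_version(x$store, v2$uri, edits = list(body = "again"))
  expect_equal(v3$version_number, 3L)
  lin <- version_lineage(x$store, v3$uri)
  expect_identical(vapply(lin, `[[`, character(1), "uri"),
                   c(v3$uri, v2$uri, x$ann$uri))
})

test_that("provenance fields are immutable across versions", {
  x <- mk_store_with_ann()
  expect_error(new_annotation_version(x$store, x$ann$uri,
                                      edits = list(created_by = t_agent(9))),
               class = "aotk_store_error")
  expect_error(new_annotation_version(x$store, x$ann$uri,
                                      edits = list(created_on = "2030-01-01")),
               class = "aotk_store_error")
})

test_that("supersession keeps the superseded record retrievable", {
  st <- ao_store()
  tag <- new_annotation("Qualifier", t_agent(1), list(t_doc(1)),
                        body = "bace1", seed = 71)
  store_add(st, tag)
  richer <- new_annotation("ExactQualifier", t_agent(2), list(t_doc(1)),
                           topics = list(t_term(1)), seed = 72)
  out <- supersede(st, tag$uri, richer)
  expect_identical(out$supersedes, tag$uri)
  expect_identical(store_get(st, tag$uri)$body, "bace1")
  expect_error(supersede(st, out$uri, out), class = "aotk_store_error")
})

test_that("set versioning adds items and warns on removal", {
  st <- ao_store()
  anns <- lapply(1:3, function(i) {
    a <- new_annotation("Note", t_agent(i), list(t_doc(i)), body = "x",
                        seed = 80L + i)
    store_add(st, a)
    a
  })
  s1 <- ao_annotation_set(anns[[1]]$uri, t_agent(1),
                          "2024-01-01T00:00:00Z", seed = 85)
  store_add(st, s1)
  s2 <- version_set(st, s1$uri, add_items = anns[[2]]$uri)
  expect_equal(s2$version_number, 2L)
  expect_setequal(s2$item_uris, c(anns[[1]]$uri, anns[[2]]$uri))
  expect_identical(store_get(st, s1$uri)$item_uris, anns[[1]]$uri)
  expect_warning(version_set(st, s2$uri, remove_items = anns[[1]]$uri),
                 class = "aotk_warning")
  expect_error(suppressWarnings(
    version_set(st, s1$uri, remove_items = anns[[3]]$uri)),
    class = "aotk_store_error")
})

test_that("derive_set branches with fresh lineage and new attribution", {
  st <- ao_store()
  s1 <- ao_annotation_set("http://test.org/a/1", t_agent(1),
                          "2024-01-01T00:00:00Z", seed = 90)
  store_add(st, s1)
  s2 <- version_set(st, s1$uri, add_items = "http://test.org/a/2")
  bob <- t_agent(99)
  br <- derive_set(st, s2$uri, bob, "2024-02-01T00:00:00Z")
  expect_identical(br$derived_from, s2$uri)
  expect_null(br$previous_version)
  expect_equal(br$version_number, 1L)
  expect_identical(br$created_by$uri, bob$uri)
  expect_setequal(br$item_uris, s2$item_uris)
  # branch evolves independently of the source lineage
  br2 <- version_set(st, br$uri, add_items = "http://test.org/a/3")
  expect_equal(br2$version_number, 2L)
  expect_identical(store_get(st, s2$uri)$item_uris, s2$item_uris)
})

test_that("dangling references are reported as data", {
  st <- ao_store()
  orphan <- new_annotation("Note", t_agent(1), list(t_doc(1)), body = "x",
                           seed = 95)
  orphan$previous_version <- "http://nowhere/gone"
  orphan$version_number <- 2L
  store_add(st, orphan)
  d <- store_dangling_refs(st)
  expect_equal(nrow(d), 1L)
  expect_identical(d$field, "previous_version")
  expect_identical(d$target, "http://nowhere/gone")
})

test_that("cyclic lineages raise a cycle error", {
  st <- ao_store()
  a <- new_annotation("Note", t_agent(1), list(t_doc(1)), body = "x",
                      uri = "http://test.org/cyc/1")
  b <- new_annotation("Note", t_agent(1), list(t_doc(1)), body = "x",
                      uri = "http://test.org/cyc/2")
  a$previous_version <- b$uri; a$version_number <- 2L
  b$previous_version <- a$uri; b$version_number <- 3L
  store_add(st, a); store_add(st, b)
  expect_error(version_lineage(st, a$uri), class = "aotk_cycle_error")
})
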