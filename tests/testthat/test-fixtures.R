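test_that("document generation is deterministic given a seed", {
  d1 <- generate_document(seed = 42)
  d2 <- generate_document(seed = 42)
  expect_identical(fixture_raw(d1), fixture_raw(d2))
  expect_identical(d1$mentions, d2$mentions)
  d3 <- generate_document(seed = 43)
  expect_false(identical(fixture_raw(d1), fixture_raw(d3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(generate_document(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("mention spans slice the normalized text exactly", {
  doc <- generate_document(n_paragraphs = 4, n_mentions = 6, seed = 5)
  norm <- normalize_document(fixture_raw(doc))
  sp <- fixture_mention_spans(doc)
  expect_equal(nrow(sp), 6L)
  for (i in seq_len(nrow(sp))) {
    expect_identical(
      substr(norm$text, sp$norm_start[[i]] + 1L, sp$norm_end[[i]]),
      sp$token[[i]])
  }
})

test_that("duplicate_rate plants repeated tokens", {
  doc <- generate_document(n_mentions = 12, seed = 9, duplicate_rate = 0.9)
  expect_true(anyDuplicated(doc$mentions$token) > 0L)
  sp <- fixture_mention_spans(doc)
  expect_equal(anyDuplicated(sp$norm_start), 0L)  # distinct positions
})

test_that("fixture annotations re-anchor uniquely on the pristine doc", {
  doc <- generate_document(seed = 11)
  anns <- fixture_annotations(doc, seed = 11)
  rep <- reanchor_report(anns, fixture_raw(doc))
  expect_true(all(rep$status == "unique"))
  expect_true(all(rep$tier == "full_context"))
})

test_that("markup churn changes the raw bytes but not the anchors", {
  doc <- generate_document(seed = 13)
  mut <- mutate_document(doc, "markup_churn", seed = 13)
  raw1 <- fixture_raw(doc)
  raw2 <- aotk:::fixture_raw_variant(mut)
  expect_false(identical(raw1, raw2))
  expect_identical(normalize_document(raw1)$text,
                   normalize_document(raw2)$text)
})

test_that("delete_paragraph tombstones its mentions and logs the edit", {
  doc <- generate_document(seed = 17)
  mut <- mutate_document(doc, "delete_paragraph", seed = 17)
  gone <- mut$edit_log[[1]]$affected_ids
  expect_gt(length(gone), 0L)
  expect_true(all(is.na(mut$mentions$paragraph[mut$mentions$id %in% gone])))
  for (id in gone) expect_identical(expected_mention_status(mut, id),
                                    "orphan")
  expect_identical(mut$edit_log[[1]]$op, "delete_paragraph")
})

test_that("duplicate_paragraph makes its mentions token-ambiguous", {
  doc <- generate_document(seed = 19)
  mut <- mutate_document(doc, "duplicate_paragraph", seed = 19)
  dup <- mut$edit_log[[1]]$affected_ids
  expect_gt(length(dup), 0L)
  for (id in dup) expect_identical(expected_mention_status(mut, id),
                                   "ambiguous")
})

test_that("the robustness experiment is deterministic and well-formed", {
  r1 <- robustness_experiment(n_docs = 2, seed = 23)
  r2 <- robustness_experiment(n_docs = 2, seed = 23)
  expect_identical(r1, r2)
  expect_setequal(r1$mutation, aotk:::AO_MUTATION_CLASSES)
  expect_true(all(r1$unique + r1$ambiguous + r1$orphan == r1$n_anchors))
  expect_true(all(r1$oracle_agreement >= 0 & r1$oracle_agreement <= 1))
  # markup churn must never break an anchor
  churn <- r1[r1$mutation == "markup_churn", ]
  expect_equal(churn$unique_rate, 1)
  expect_equal(churn$full_context, churn$n_anchors)
})
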