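test_that("normalize_document matches the frozen reference example", {
  n <- normalize_document("<b>foo</b>  bar")
  expect_identical(n$text, "foo bar")
  expect_identical(n$offset_map, c(3L, 4L, 5L, 10L, 12L, 13L, 14L))
})

test_that("offset map points back at the raw characters", {
  raw <- "<div class='x'>Hello,\n  <em>world</em>!</div><!-- bye -->"
  n <- normalize_document(raw)
  chars <- strsplit(raw, "")[[1]]
  for (i in seq_len(nchar(n$text))) {
    norm_ch <- substr(n$text, i, i)
    raw_ch <- chars[[n$offset_map[[i]] + 1L]]
    if (norm_ch == " ") {
      expect_match(raw_ch, "^\\s$")
    } else {
      expect_identical(raw_ch, norm_ch)
    }
  }
  expect_false(is.unsorted(n$offset_map, strictly = TRUE))
})

test_that("script, style and comment content is removed", {
  raw <- paste0("<p>keep</p> <script>var x = 'drop';</script>",
                "<style>p{}</style><!-- drop too --> <p>also</p>")
  expect_identical(normalize_document(raw)$text, "keep also")
  # adjacent markup with no raw whitespace introduces no separator
  expect_identical(normalize_document("<p>keep</p><p>also</p>")$text,
                   "keepalso")
})

test_that("normalization handles edge cases", {
  expect_identical(normalize_document("")$text, "")
  expect_identical(normalize_document("<p></p>")$text, "")
  expect_identical(normalize_document("plain text")$text, "plain text")
  expect_identical(normalize_document("  padded  ")$text, "padded")
  # unclosed tag at end of input
  expect_identical(normalize_document("ok <b")$text, "ok")
})

test_that("normalization is idempotent", {
  raws <- c("<b>foo</b>  bar", "a\t\tb\nc", "x<script>s</script>y",
            "<p>one</p> <p>two  three</p>")
  for (raw in raws) {
    once <- normalize_document(raw)
    twice <- normalize_document(once$text)
    expect_identical(twice$text, once$text)
  }
})

test_that("selector constructors validate their inputs", {
  expect_error(ao_text_quote_selector(""), "non-empty")
  expect_error(ao_text_quote_selector("a<b>"), "markup")
  expect_error(ao_text_quote_selector("a  b"), "not normalized")
  expect_error(ao_text_quote_selector("a\tb"), "not normalized")
  expect_error(ao_offset_selector(-1, 5))
  expect_error(ao_offset_selector(0, 0))
  expect_error(ao_image_box_selector(5, 0, 5, 10), "x_init < x_end")
  expect_error(ao_xpointer_selector(""), "non-empty")
  expect_error(ao_text_quote_selector("ok", on_document = "rel/path"),
               "absolute")
})

test_that("make_text_selector captures exact and truncated context", {
  n <- normalize_document("abcdefghij")
  s <- make_text_selector(n, 2, 5, context_len = 3)
  expect_identical(s$prefix, "ab")     # truncated at document start
  expect_identical(s$exact, "cde")
  expect_identical(s$postfix, "fgh")
  expect_error(make_text_selector(n, 5, 20), class = "aotk_range_error")
  expect_error(make_text_selector(n, 3, 3), class = "aotk_range_error")
})

test_that("two-tier resolution: full context, exact only, orphan", {
  n <- normalize_document("<p>cat sat. cat ran. dog sat.</p>")
  # unique via context
  s <- ao_text_quote_selector("cat", prefix = "", postfix = " ran")
  r <- resolve_text_selector(s, n)
  expect_equal(r$status, "unique")
  expect_equal(r$tier, "full_context")
  expect_equal(r$matches$norm_start, 9L)
  # context gone -> exact_only, ambiguous
  s2 <- ao_text_quote_selector("cat", prefix = "xx ", postfix = " yy")
  r2 <- resolve_text_selector(s2, n)
  expect_equal(r2$status, "ambiguous")
  expect_equal(r2$tier, "exact_only")
  expect_equal(nrow(r2$matches), 2L)
  # fully gone -> orphan
  s3 <- ao_text_quote_selector("ferret")
  r3 <- resolve_text_selector(s3, n)
  expect_equal(r3$status, "orphan")
  expect_equal(r3$tier, "none")
  expect_equal(nrow(r3$matches), 0L)
})

test_that("overlapping occurrences are all reported", {
  n <- normalize_document("aaaa")
  s <- ao_text_quote_selector("aa")
  r <- resolve_text_selector(s, n)
  expect_equal(r$status, "ambiguous")
  expect_equal(r$matches$norm_start, c(0L, 1L, 2L))
})

test_that("resolved raw spans slice the original markup correctly", {
  raw <- "<p>the <b>quick</b> brown  fox</p>"
  n <- normalize_document(raw)
  s <- make_text_selector(n, 4, 9)   # "quick"
  r <- resolve_text_selector(s, n)
  expect_equal(r$status, "unique")
  expect_identical(substr(raw, r$matches$raw_start + 1L, r$matches$raw_end),
                   "quick")
})

test_that("offset selectors resolve in bounds and orphan out of bounds", {
  n <- normalize_document("<p>hello world</p>")
  s <- ao_offset_selector(6, 5)
  r <- resolve_offset_selector(s, n)
  expect_equal(r$status, "unique")
  expect_identical(substr(n$text, 7, 11), "world")
  r2 <- resolve_offset_selector(ao_offset_selector(6, 50), n)
  expect_equal(r2$status, "orphan")
})

test_that("image boxes validate against dimensions", {
  s <- ao_image_box_selector(10, 10, 50, 40)
  expect_equal(validate_image_box(s, 100, 100)$status, "unique")
  expect_equal(validate_image_box(s, 45, 100)$status, "orphan")
  expect_error(validate_image_box(s, 0, 100), "positive")
})

test_that("reanchor_report covers all target kinds", {
  raw <- "<p>alpha beta gamma</p>"
  n <- normalize_document(raw)
  doc <- t_doc(1)
  sel <- make_text_selector(n, 6, 10, on_document = doc$page_uri, seed = 1)
  xp <- ao_xpointer_selector("xpointer(/p[1])", on_document = doc$page_uri,
                             seed = 2)
  ann <- new_annotation("Note", t_agent(), list(doc, sel, xp), body = "b",
                        seed = 3)
  rep <- reanchor_report(ann, raw)
  expect_equal(nrow(rep), 3L)
  whole <- rep[is.na(rep$selector_uri), ]
  expect_equal(whole$status, "unique")
  tq <- rep[!is.na(rep$selector_uri) & rep$selector_uri == sel$uri, ]
  expect_equal(tq$status, "unique")
  expect_identical(substr(raw, tq$raw_start + 1L, tq$raw_end), "beta")
  xr <- attr(rep, "resolutions")[[xp$uri]]
  expect_true(xr$passthrough)
  expect_equal(xr$status, "orphan")
})

test_that("xpointer expressions round-trip verbatim (pass-through)", {
  expr <- "xpointer(string-range(/html[1]/body[1], 120, 5))"
  xp <- ao_xpointer_selector(expr, seed = 4)
  ttl <- ao_serialize(
    new_annotation("Note", t_agent(), list(xp), body = "b", seed = 5),
    "turtle")
  back <- ao_parse(ttl, "turtle")
  sels <- back$annotations[[1]]$targets
  xps <- Filter(function(s) inherits(s, "ao_xpointer_selector"), sels)
  expect_identical(xps[[1]]$expression, expr)
})
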