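test_that("tag vocabulary enumerates BIO tags over admissible pairs", {
  v <- build_tag_vocabulary()
  # 2 * (10 categories x 4 attributes + 2 x 1) + 1, counted by brute force
  n_pairs <- sum(vapply(risk_factor_categories()$code,
                        function(cat) length(admissible_attributes(cat)),
                        integer(1)))
  expect_equal(length(v$tags), 2L * n_pairs + 1L)
  expect_equal(length(v$tags), 85L)
  expect_identical(v$tags[1L], "O")
  expect_true(all(c("B-HyC", "I-HyC", "B-HyD") %in% v$tags))
  # bijective tag <-> index map
  expect_identical(unname(v$index[v$tags]), seq_along(v$tags))

  # size formula holds for arbitrary sub-inventories
  v2 <- build_tag_vocabulary(c("Hypertension", "Age"))
  expect_equal(length(v2$tags), 2L * (4L + 1L) + 1L)
  v3 <- build_tag_vocabulary("Age")
  expect_identical(v3$tags, c("O", "B-AgN", "I-AgN"))

  expect_error(build_tag_vocabulary(c("Age", "Age")), "duplicate.*Age")
})

test_that("time-attribute admissibility matches the inventory", {
  for (cat in c("Age", "Gender")) {
    expect_identical(admissible_attributes(cat), "None")
  }
  for (cat in setdiff(risk_factor_categories()$code, c("Age", "Gender"))) {
    expect_identical(admissible_attributes(cat),
                     c("Before", "During", "After", "Continue"))
  }
  expect_error(admissible_attributes("Gout"), "unknown")
  expect_error(entity_mention(0, 2, "Age", "During", "ab"), "inadmissible")
})

test_that("to_bio tags mentions and rejects bad input", {
  v <- build_tag_vocabulary()
  d <- emr_document("d1", "abcde",
                    list(entity_mention(1, 4, "Hypertension", "Continue",
                                        "bcd")))
  expect_identical(to_bio(d, v), c("O", "B-HyC", "I-HyC", "I-HyC", "O"))

  empty <- emr_document("d2", "xyz")
  expect_identical(to_bio(empty, v), rep("O", 3L))

  unann <- emr_document("d3", "xyz", mentions = NULL)
  expect_error(to_bio(unann, v), "no mention annotation")
})

test_that("from_bio inverts to_bio and repairs ill-formed sequences", {
  v <- build_tag_vocabulary()
  expect_identical(from_bio(c("a", "b"), c("O", "O"), v), list())

  m <- from_bio(c("a", "b", "c"), c("B-HyC", "I-HyC", "O"), v)
  expect_length(m, 1L)
  expect_equal(m[[1L]]$start, 0L)
  expect_equal(m[[1L]]$end, 2L)
  expect_identical(m[[1L]]$category, "Hypertension")
  expect_identical(m[[1L]]$time_attr, "Continue")

  # dangling I promoted to B (IOB2 repair)
  m2 <- from_bio(c("a", "b", "c"), c("O", "I-HyC", "I-HyC"), v)
  expect_length(m2, 1L)
  expect_equal(c(m2[[1L]]$start, m2[[1L]]$end), c(1L, 3L))

  # I of a different pair after B starts a new mention
  m3 <- from_bio(c("a", "b"), c("B-HyC", "I-HyD"), v)
  expect_length(m3, 2L)
  expect_identical(m3[[2L]]$time_attr, "During")
})

test_that("to_bio/from_bio round-trip on random generated documents", {
  v <- build_tag_vocabulary()
  corpus <- generate_corpus(small_world(seed = 42L))
  for (d in corpus$train) {
    back <- from_bio(d$chars, to_bio(d, v), v)
    expect_equal(length(back), length(d$mentions))
    for (i in seq_along(back)) {
      expect_equal(back[[i]][c("start", "end", "category", "time_attr",
                               "surface")],
                   d$mentions[[i]][c("start", "end", "category", "time_attr",
                                     "surface")])
    }
  }
})

test_that("document invariants are enforced", {
  expect_error(entity_mention(3, 3, "Age", "None", ""), "invalid span")
  expect_error(entity_mention(0, 2, "Age", "None", "abc"), "3 characters")
  expect_error(
    emr_document("d", "abcd",
                 list(entity_mention(0, 2, "Age", "None", "ab"),
                      entity_mention(1, 3, "Gender", "None", "bc"))),
    "overlap")
  expect_error(
    emr_document("d", "abcd", list(entity_mention(0, 2, "Age", "None",
                                                  "xy"))),
    "does not match")
  expect_error(emr_document("d", "ab", cvd_label = "maybe"), "cvd_label")
})

test_that("JSONL document round trip is lossless", {
  corpus <- generate_corpus(small_world(seed = 5L))
  docs <- corpus$train
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(docs, path)
  back <- read_documents(path)
  expect_equal(back, docs)
  # byte-stable serialisation
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(back, path2)
  expect_identical(readLines(path, warn = FALSE),
                   readLines(path2, warn = FALSE))

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_identical(read_documents(empty), list())

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","chars":"ab"}', "not json"), bad)
  expect_error(read_documents(bad), "line 2")
})

test_that("CoNLL round trip and dialect", {
  v <- build_tag_vocabulary()
  corpus <- generate_corpus(small_world(seed = 6L, sizes = c(5L, 2L, 2L)))
  tagged <- lapply(corpus$train, function(d)
    list(chars = d$chars, tags = to_bio(d, v)))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(tagged, path)
  expect_equal(read_conll(path, v), tagged)

  # one char + tag per line, tab separated, blank line after each doc
  p3 <- withr::local_tempfile()
  write_conll(list(list(chars = c("a", "b", "c"),
                        tags = c("O", "B-HyC", "I-HyC"))), p3)
  lines <- readLines(p3, warn = FALSE)
  expect_length(lines, 4L)
  expect_identical(lines[2L], "b\tB-HyC")
  expect_identical(lines[4L], "")

  bad <- withr::local_tempfile()
  writeLines(c("a\tO", "b"), bad)
  expect_error(read_conll(bad), "line 2")
  bad2 <- withr::local_tempfile()
  writeLines(c("a\tNOT-A-TAG"), bad2)
  expect_error(read_conll(bad2, v), "unknown tag")
})
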