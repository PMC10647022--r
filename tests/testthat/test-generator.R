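test_that("identical configs generate byte-identical corpora", {
  cfg <- generator_config(seed = 7, n_procedures = 5)
  d1 <- generate_corpus(cfg)
  d2 <- generate_corpus(cfg)
  for (i in seq_along(d1)) {
    expect_identical(serialize_standoff(d1[[i]]), serialize_standoff(d2[[i]]))
  }
  # a different seed changes the text
  d3 <- generate_corpus(generator_config(seed = 8, n_procedures = 5))
  expect_false(identical(d1[[1]]$text, d3[[1]]$text))
})

test_that("every generated document validates with zero errors", {
  reg <- load_registry()
  docs <- generate_corpus(generator_config(seed = 7, n_procedures = 20))
  for (doc in docs) {
    rep_ <- validate_document(doc, registry = reg)
    expect_equal(sum(rep_$severity == "error"), 0)
  }
})

test_that("generated relations always fit the head's roleset frame", {
  reg <- load_registry()
  docs <- generate_corpus(generator_config(seed = 47, n_procedures = 20))
  for (doc in docs) {
    rep_ <- validate_document(doc, registry = reg)
    expect_false("arg-not-in-roleset" %in% rep_$code)
  }
  # ... unless the adversarial flag is set for validator testing
  adv <- generate_corpus(generator_config(seed = 47, n_procedures = 30,
                                          adversarial = TRUE))
  codes <- unlist(lapply(adv, function(d) {
    validate_document(d, registry = reg)$code
  }))
  expect_true("arg-not-in-roleset" %in% codes)
})

test_that("the verb distribution is skewed with add dominant", {
  docs <- generate_corpus(generator_config(seed = 53, n_procedures = 60))
  lemmas <- unlist(lapply(docs, function(d) {
    vapply(d$mentions$surface[d$mentions$label == "REACTION_STEP"],
           function(s) resolve_roleset(s)$lemma, character(1))
  }))
  counts <- sort(table(lemmas), decreasing = TRUE)
  # charge is boosted by the opening-sentence convention; add dominates
  # the remaining draws as in the published distribution
  expect_true(names(counts)[1] %in% c("add", "charge"))
  expect_true("add" %in% names(counts)[1:2])
  reflux_n <- if ("reflux" %in% names(counts)) counts[["reflux"]] else 0L
  expect_gt(counts[["add"]], reflux_n)
})

test_that("noise flags control cross-references, workup and repetition", {
  noisy <- generate_corpus(generator_config(seed = 61, n_procedures = 15))
  texts <- vapply(noisy, function(d) d$text, character(1))
  expect_true(any(grepl("\\(Note \\d+\\)", texts)))
  expect_true(any(grepl("washed|purified|dried|recrystallized", texts)))
  expect_true(any(grepl("After \\d", texts)))

  clean <- generate_corpus(noise_free_config(seed = 61, n = 15))
  texts2 <- vapply(clean, function(d) d$text, character(1))
  expect_false(any(grepl("\\(Note \\d+\\)", texts2)))
  expect_false(any(grepl("purified|recrystallized", texts2)))

  # note references never carry annotations: stripping them leaves every
  # mention intact
  for (d in noisy) expect_no_error(preprocess_document(d))
})

test_that("unknown lemmas in verb weights are rejected", {
  expect_error(
    generate_corpus(generator_config(seed = 1, n_procedures = 1,
                                     verb_weights = c(sparge = 1))),
    "unknown lemmas"
  )
  expect_error(generator_config(verb_weights = c(add = -1)), "positive")
})

test_that("split sizes follow the floor rule with remainder to train", {
  mk <- function(n) {
    lapply(seq_len(n), function(i) {
      rxn_document("X was added.", doc_id = sprintf("d%03d", i))
    })
  }
  s112 <- split_corpus(mk(112), seed = 5)
  expect_equal(lengths(s112), c(train = 90L, dev = 11L, test = 11L))
  s10 <- split_corpus(mk(10), seed = 5)
  expect_equal(lengths(s10), c(train = 8L, dev = 1L, test = 1L))
  s23 <- split_corpus(mk(23), seed = 5)
  expect_equal(lengths(s23), c(train = 19L, dev = 2L, test = 2L))

  # disjoint and exhaustive, procedure-level
  all_ids <- unname(unlist(lapply(unlist(s23, recursive = FALSE),
                                  function(d) d$doc_id)))
  expect_equal(sort(all_ids), sort(vapply(mk(23), function(d) d$doc_id,
                                          character(1))))
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("corpus statistics total rows equal column sums", {
  docs <- generate_corpus(generator_config(seed = 67, n_procedures = 12))
  splits <- split_corpus(docs, seed = 2)
  st <- corpus_stats(splits)
  for (tbl in list(st$ner, st$re)) {
    body <- tbl[tbl$label != "total", ]
    tot <- tbl[tbl$label == "total", ]
    for (cn in setdiff(names(tbl), "label")) {
      expect_equal(sum(body[[cn]]), tot[[cn]])
    }
    expect_equal(body$total, rowSums(as.matrix(
      body[setdiff(names(body), c("label", "total"))])))
  }
  expect_equal(sum(st$documents$procedures), 12)

  # empty corpus gives all-zero tables
  st0 <- corpus_stats(list())
  expect_true(all(st0$ner$all == 0))
  expect_true(all(st0$re$all == 0))
})

test_that("rule baseline fully recovers gold on a noise-free corpus", {
  docs <- generate_corpus(noise_free_config(seed = 7, n = 20))
  preds <- lapply(docs, function(d) run_pipeline(d$text, doc_id = d$doc_id))
  ner <- evaluate_ner(docs, preds, "exact")
  expect_true(all(ner$fscore == 1))
  re <- evaluate_re(docs, preds, "gold")
  expect_true(all(re$fscore == 1))
})
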