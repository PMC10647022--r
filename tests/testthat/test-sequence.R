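test_that("a two-step sentence builds the expected grouped sequence", {
  seq <- build_sequence(two_step_doc())
  s <- seq$steps
  expect_equal(nrow(s), 2)
  expect_equal(s$ordinal, 1:2)
  expect_equal(s$lemma, c("add", "stir"))
  expect_equal(s$roleset_id, c("add.01", "stir.01"))
  expect_equal(s$arg1[[1]], "A (1 g)")
  expect_equal(s$arg2[[1]], "B (5 mL)")
  expect_equal(s$arg1[[2]], "the mixture")
  expect_equal(s$arg2[[2]], character(0))
  expect_equal(s$params[[2]]$label, c("TEMPERATURE", "TIME"))
  expect_equal(s$params[[2]]$surface, c("0 °C", "2 h"))
  expect_true(all(lengths(s$warnings) == 0))
})

test_that("a document with zero actions gives an empty sequence", {
  seq <- build_sequence(rxn_document("No actions here."))
  expect_equal(nrow(seq$steps), 0)
  expect_equal(render_text(seq), "")
})

test_that("off-frame arguments are kept and flagged, not dropped", {
  txt <- "A and dichloromethane (50 mL) were mixed."
  m <- mention_table(
    label = c("ENTITY", "ENTITY", "REACTION_STEP"),
    start = c(loc0(txt, "A")[1], loc0(txt, "dichloromethane (50 mL)")[1],
              loc0(txt, "mixed")[1]),
    end = c(loc0(txt, "A")[2], loc0(txt, "dichloromethane (50 mL)")[2],
            loc0(txt, "mixed")[2]),
    text = txt
  )
  doc <- rxn_document(txt, m, relation_table(c("ARG1", "ARG2"),
                                             c("T3", "T3"), c("T1", "T2")))
  seq <- build_sequence(doc)
  expect_equal(seq$steps$arg2[[1]], "dichloromethane (50 mL)")
  expect_true("arg-not-in-roleset" %in% seq$steps$warnings[[1]])
  expect_match(render_text(seq), "\\[!\\]")
})

test_that("unresolved verbs produce a warning step, never a drop", {
  txt <- "The gel was sonicated."
  m <- mention_table("REACTION_STEP", loc0(txt, "sonicated")[1],
                     loc0(txt, "sonicated")[2], text = txt)
  seq <- build_sequence(rxn_document(txt, m))
  expect_equal(nrow(seq$steps), 1)
  expect_true(is.na(seq$steps$roleset_id[1]))
  expect_true("unresolved-lemma" %in% seq$steps$warnings[[1]])
})

test_that("rendered text follows the numbered format", {
  lines <- strsplit(render_text(build_sequence(two_step_doc())), "\n")[[1]]
  expect_length(lines, 2)
  expect_match(lines[1], "^1\\. Add A \\(1 g\\) → B \\(5 mL\\)$")
  expect_match(lines[2], "^2\\. Stir the mixture \\(0 °C, 2 h\\)$")

  # container steps render with an "in <container>" prefix
  txt <- "The flask contained DMF."
  m <- mention_table(
    label = c("ENTITY", "REACTION_STEP", "ENTITY"),
    start = c(loc0(txt, "The flask")[1], loc0(txt, "contained")[1],
              loc0(txt, "DMF")[1]),
    end = c(loc0(txt, "The flask")[2], loc0(txt, "contained")[2],
            loc0(txt, "DMF")[2]),
    text = txt
  )
  doc <- rxn_document(txt, m, relation_table(c("ARG0", "ARG1"),
                                             c("T2", "T2"), c("T1", "T3")))
  expect_equal(render_text(build_sequence(doc)),
               "1. Contain in The flask DMF")
})

test_that("JSON serialization round-trips losslessly", {
  docs <- generate_corpus(generator_config(seed = 41, n_procedures = 6))
  for (doc in docs) {
    seq <- build_sequence(doc)
    back <- parse_sequence_json(render_json(seq))
    expect_equal(back$doc_id, seq$doc_id)
    expect_equal(back$steps, seq$steps)
  }
  # empty sequence and unicode surfaces survive
  empty <- build_sequence(rxn_document("Nothing."))
  expect_equal(parse_sequence_json(render_json(empty))$steps, empty$steps)
  two <- build_sequence(two_step_doc())
  back2 <- parse_sequence_json(render_json(two))
  expect_identical(back2$steps$params[[2]]$surface[1], "0 °C")
})

test_that("step count equals the number of action mentions, always", {
  docs <- generate_corpus(generator_config(seed = 43, n_procedures = 15))
  for (doc in docs) {
    seq <- build_sequence(doc)
    expect_equal(nrow(seq$steps),
                 sum(doc$mentions$label == "REACTION_STEP"))
    expect_equal(seq$steps$ordinal, seq_len(nrow(seq$steps)))
    # steps sorted by source span
    expect_true(all(diff(seq$steps$start) >= 0))
    # every argument surface is an exact slice of the document text
    for (i in seq_len(nrow(seq$steps))) {
      surfs <- c(seq$steps$arg0[[i]], seq$steps$arg1[[i]],
                 seq$steps$arg2[[i]], seq$steps$params[[i]]$surface)
      for (sf in surfs) expect_true(grepl(sf, doc$text, fixed = TRUE))
    }
  }
})

test_that("build_sequence is invariant under relation permutation", {
  doc <- two_step_doc()
  set.seed(1)
  for (k in 1:5) {
    doc2 <- doc
    perm <- sample.int(nrow(doc$relations))
    doc2$relations <- doc$relations[perm, ]
    expect_equal(build_sequence(doc2)$steps, build_sequence(doc)$steps)
  }
})
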