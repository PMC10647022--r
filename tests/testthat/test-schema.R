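test_that("a well-formed document yields an empty validation report", {
  rep_ <- validate_document(tiny_doc(), registry = load_registry())
  expect_s3_class(rep_, "rxn_validation")
  expect_equal(nrow(rep_), 0)
  expect_true(doc_is_valid(rep_))
})

test_that("label incompatibilities and duplicates are hard errors", {
  doc <- tiny_doc()
  # ARGM pointing at an ENTITY is incompatible
  doc$relations$label[doc$relations$tail_id == "T1"] <- "ARGM"
  rep_ <- validate_document(doc)
  expect_true("label-incompatible" %in% rep_$code)
  expect_false(doc_is_valid(rep_))

  # ARG1 pointing at a parameter is equally incompatible
  doc2 <- tiny_doc()
  doc2$relations$label[doc2$relations$tail_id == "T4"] <- "ARG1"
  expect_true("label-incompatible" %in% validate_document(doc2)$code)

  # duplicated (head, tail, label) triple
  doc3 <- tiny_doc()
  doc3$relations <- dplyr::bind_rows(
    doc3$relations,
    tibble::tibble(id = "R9", label = "ARG1", head_id = "T2", tail_id = "T1")
  )
  expect_true("duplicate-relation" %in% validate_document(doc3)$code)

  # a relation head that is not an action
  doc4 <- tiny_doc()
  doc4$relations$head_id[1] <- "T3"
  expect_true("head-not-action" %in% validate_document(doc4)$code)
})

test_that("span bounds and surface consistency are checked", {
  doc <- tiny_doc()
  doc$mentions$spans[[1]] <- tibble::tibble(start = 0L, end = 2000L)
  doc$mentions$end[1] <- 2000L
  expect_true("span-bounds" %in% validate_document(doc)$code)

  doc2 <- tiny_doc()
  doc2$mentions$surface[1] <- "not the text"
  expect_true("surface-mismatch" %in% validate_document(doc2)$code)

  doc3 <- tiny_doc()
  doc3$mentions$label[1] <- "CHEMICAL"
  expect_true("unknown-label" %in% validate_document(doc3)$code)
})

test_that("unresolvable mention references are reported, never raised", {
  doc <- tiny_doc()
  doc$relations$tail_id[1] <- "T99"
  rep_ <- expect_no_error(validate_document(doc))
  expect_true("unresolved-ref" %in% rep_$code)
})

test_that("roleset-aware checks separate errors from warnings", {
  reg <- load_registry()
  txt <- "A and B were mixed."
  m <- mention_table(
    label = c("ENTITY", "ENTITY", "REACTION_STEP"),
    start = c(loc0(txt, "A")[1], loc0(txt, "B")[1], loc0(txt, "mixed")[1]),
    end = c(loc0(txt, "A")[2], loc0(txt, "B")[2], loc0(txt, "mixed")[2]),
    text = txt
  )
  # ARG2 on mix.01 (whose frame has only ARG1) is a warning, not an error
  doc <- rxn_document(txt, m, relation_table(c("ARG1", "ARG2"),
                                             c("T3", "T3"), c("T1", "T2")))
  rep_ <- validate_document(doc, registry = reg)
  warn <- rep_[rep_$severity == "warning", ]
  expect_true("arg-not-in-roleset" %in% warn$code)
  expect_true(doc_is_valid(rep_))

  # ARG0 anywhere but contain.01 is an error
  doc2 <- rxn_document(txt, m, relation_table("ARG0", "T3", "T1"))
  rep2 <- validate_document(doc2, registry = reg)
  expect_true("arg0-restricted" %in% rep2$code)
  expect_false(doc_is_valid(rep2))

  # ARG0 on contain.01 passes
  txt3 <- "The flask contained DMF."
  m3 <- mention_table(
    label = c("ENTITY", "REACTION_STEP", "ENTITY"),
    start = c(loc0(txt3, "The flask")[1], loc0(txt3, "contained")[1],
              loc0(txt3, "DMF")[1]),
    end = c(loc0(txt3, "The flask")[2], loc0(txt3, "contained")[2],
            loc0(txt3, "DMF")[2]),
    text = txt3
  )
  doc3 <- rxn_document(txt3, m3, relation_table(c("ARG0", "ARG1"),
                                                c("T2", "T2"), c("T1", "T3")))
  expect_equal(nrow(validate_document(doc3, registry = reg)), 0)

  # an action verb outside the registry is flagged as a warning
  txt4 <- "The gel was sonicated."
  m4 <- mention_table("REACTION_STEP", loc0(txt4, "sonicated")[1],
                      loc0(txt4, "sonicated")[2], text = txt4)
  rep4 <- validate_document(rxn_document(txt4, m4), registry = reg)
  expect_true("unresolved-lemma" %in% rep4$code)
  expect_true(doc_is_valid(rep4))
})

test_that("validation is invariant under brat serialization round-trip", {
  for (doc in list(tiny_doc(), two_step_doc())) {
    ser <- serialize_standoff(doc)
    doc2 <- parse_standoff(ser$txt, ser$ann, doc_id = doc$doc_id,
                           from_strings = TRUE)
    r1 <- validate_document(doc, registry = load_registry())
    r2 <- validate_document(doc2, registry = load_registry())
    expect_equal(r1$code, r2$code)
    expect_equal(r1$severity, r2$severity)
  }
})
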