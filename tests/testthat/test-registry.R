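test_that("the packaged registry loads with the expected frames", {
  reg <- load_registry()
  expect_s3_class(reg, "rxn_registry")
  core <- c("add", "stir", "charge", "cool", "heat", "mix", "hold",
            "contain", "reflux", "transfer", "wash", "backfill")
  expect_true(all(core %in% reg$lemma))
  expect_true(all(grepl("\\.01$", reg$roleset_id)))
  expect_true(all(reg$origin_type %in% c("A", "B", "C", "D")))
  # every frame defines ARG1
  expect_false(anyNA(reg$arg1))
  # ARG0 exists only on the container frame
  expect_equal(reg$lemma[!is.na(reg$arg0)], "contain")
})

test_that("malformed registry files are rejected at load", {
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("lemma\tsense\torigin_type\targ0\targ1\targ2",
               "add\t01\tA\t\tx\ty",
               "add\t01\tA\t\tx\t"), dup)
  expect_error(load_registry(dup), "duplicate lemma")

  wrong_sense <- tempfile(fileext = ".tsv")
  writeLines(c("lemma\tsense\torigin_type\targ0\targ1\targ2",
               "add\t02\tA\t\tx\t"), wrong_sense)
  expect_error(load_registry(wrong_sense), "01")

  extra_slot <- tempfile(fileext = ".tsv")
  writeLines(c("lemma\tsense\torigin_type\targ0\targ1\targ2\targ3",
               "add\t01\tA\t\tx\ty\tz"), extra_slot)
  expect_error(load_registry(extra_slot), "ARG2")

  header_only <- tempfile(fileext = ".tsv")
  writeLines("lemma\tsense\torigin_type\targ0\targ1\targ2", header_only)
  expect_equal(nrow(load_registry(header_only)), 0)
})

test_that("lemmatization handles inflections, noun forms and case", {
  cases <- c(
    added = "add", adding = "add", adds = "add", addition = "add",
    Charged = "charge", charges = "charge", stirred = "stir",
    stirring = "stir", held = "hold", kept = "keep", mixed = "mix",
    heated = "heat", cooled = "cool", transferred = "transfer",
    wrapped = "wrap", filled = "fill", refluxed = "reflux",
    dissolved = "dissolve", backfilled = "backfill", placed = "place",
    removed = "remove", contains = "contain", contained = "contain",
    washed = "wash", activated = "activate", opened = "open",
    maintained = "maintain"
  )
  expect_equal(lemmatize(names(cases)), unname(cases))
})

test_that("lemmatize is idempotent and total", {
  forms <- c("added", "Charged", "stirring", "held", "zzz", "dried",
             "overnight", "mixture")
  once <- lemmatize(forms)
  expect_equal(lemmatize(once), once)
  expect_true(all(nzchar(once)))
})

test_that("resolve_roleset finds the verb inside multi-token surfaces", {
  expect_equal(resolve_roleset("was added")$roleset_id, "add.01")
  expect_equal(resolve_roleset("held")$roleset_id, "hold.01")
  expect_null(resolve_roleset("zzz"))
  expect_null(resolve_roleset(""))
})

test_that("has_arg reflects frame slots and rejects ARGM", {
  reg <- load_registry()
  expect_true(has_arg(resolve_roleset("added", reg), "ARG2"))
  expect_false(has_arg(resolve_roleset("mixed", reg), "ARG2"))
  expect_true(has_arg(resolve_roleset("contained", reg), "ARG0"))
  expect_false(has_arg(resolve_roleset("added", reg), "ARG0"))
  expect_error(has_arg(resolve_roleset("added", reg), "ARGM"), "ARGM")
})

test_that("origin-type shares follow the published type distribution", {
  # the full inventory's printed type counts: 25 kept from PropBank,
  # 4 with redefined slots, 11+8 newly defined, of 48 total
  counts <- c(A = 25L, B = 4L, C = 11L, D = 8L)
  reg48 <- tibble::tibble(
    lemma = sprintf("verb%02d", 1:48),
    roleset_id = sprintf("verb%02d.01", 1:48),
    origin_type = rep(names(counts), counts),
    arg0 = NA_character_, arg1 = "thing", arg2 = NA_character_
  )
  dist <- type_distribution(reg48)
  expect_equal(dist$n, unname(counts))
  expect_equal(dist$pct[dist$origin_type == "A"], 52L)
  expect_equal(pct_share(sum(counts[c("C", "D")]), 48), 40L)
  # integer shares sum to 100 within rounding slack
  expect_lte(abs(sum(dist$pct) - 100L), 1L)
})

test_that("type_distribution of an empty registry is all zeros", {
  header_only <- tempfile(fileext = ".tsv")
  writeLines("lemma\tsense\torigin_type\targ0\targ1\targ2", header_only)
  dist <- type_distribution(load_registry(header_only))
  expect_equal(dist$n, rep(0L, 4))
  expect_equal(dist$pct, rep(0L, 4))
})
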