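# Published benchmark rows used as arithmetic fixtures: printed
# (precision, recall, support) triples from the NER and RE result tables,
# from which the integer counts are exactly recoverable.
ner_exact_rows <- tibble::tribble(
  ~label,          ~p,     ~r,     ~f,     ~n,
  "REACTION_STEP", 0.9474, 0.9153, 0.9310, 59,
  "ENTITY",        0.8447, 0.8700, 0.8571, 100,
  "TEMPERATURE",   0.6786, 0.9048, 0.7755, 21,
  "TEMP_TARGET",   0.5000, 0.7500, 0.6000, 4,
  "TIME",          0.9231, 1.0000, 0.9600, 24,
  "MODIFIER",      0.8571, 0.8000, 0.8276, 15,
  "all",           0.8504, 0.8924, 0.8709, 223
)
ner_relaxed_rows <- tibble::tribble(
  ~label,          ~p,     ~r,     ~f,     ~n,
  "REACTION_STEP", 0.9474, 0.9153, 0.9310, 59,
  "ENTITY",        0.8932, 0.9200, 0.9064, 100,
  "TEMPERATURE",   0.7500, 1.0000, 0.8571, 21,
  "TEMP_TARGET",   0.6667, 1.0000, 0.8000, 4,
  "TIME",          0.9231, 1.0000, 0.9600, 24,
  "MODIFIER",      0.9286, 0.8667, 0.8966, 15,
  "all",           0.8889, 0.9327, 0.9103, 223
)
re_rows <- tibble::tribble(
  ~setting,    ~p,     ~r,     ~f,     ~n,
  "predicted", 0.8393, 0.8393, 0.8393, 168,
  "gold",      0.9408, 0.9464, 0.9436, 168
)

test_that("prf implements the P/R/F formulas with the 0/0 convention", {
  expect_equal(prf(54, 3, 5),
               tibble::tibble(precision = 54 / 57, recall = 54 / 59,
                              fscore = 2 * (54 / 57) * (54 / 59) /
                                (54 / 57 + 54 / 59)))
  expect_equal(round(unlist(prf(54, 3, 5)), 4),
               c(precision = 0.9474, recall = 0.9153, fscore = 0.9310))
  expect_equal(unlist(prf(0, 0, 0)),
               c(precision = 0, recall = 0, fscore = 0))
  expect_equal(unlist(prf(5, 0, 0)),
               c(precision = 1, recall = 1, fscore = 1))
})

test_that("integer counts recovered from printed P/R/n reproduce every row", {
  rows <- dplyr::bind_rows(
    dplyr::mutate(ner_exact_rows, src = "exact"),
    dplyr::mutate(ner_relaxed_rows, src = "relaxed"),
    dplyr::rename(dplyr::mutate(re_rows, src = "re"), label = setting)
  )
  for (i in seq_len(nrow(rows))) {
    cts <- counts_from_prn(rows$p[i], rows$r[i], rows$n[i])
    back <- prf(cts$tp, cts$fp, cts$fn)
    expect_equal(round(back$precision, 4), rows$p[i])
    expect_equal(round(back$recall, 4), rows$r[i])
    expect_equal(round(back$fscore, 4), rows$f[i])
    expect_equal(cts$tp + cts$fn, as.integer(rows$n[i]))
  }
  expect_equal(counts_from_prn(0.9231, 1.0000, 24),
               tibble::tibble(tp = 24L, fp = 2L, fn = 0L))
  expect_equal(counts_from_prn(1, 1, 7),
               tibble::tibble(tp = 7L, fp = 0L, fn = 0L))
  expect_equal(counts_from_prn(0.8932, 0.9200, 100),
               tibble::tibble(tp = 92L, fp = 11L, fn = 8L))
  expect_error(counts_from_prn(0.5, 0.99, 3), "reproduce")
})

test_that("per-label counts recovered from the exact-match table are
           mutually consistent with the micro row", {
  per_label <- ner_exact_rows[ner_exact_rows$label != "all", ]
  cts <- dplyr::bind_rows(lapply(seq_len(nrow(per_label)), function(i) {
    counts_from_prn(per_label$p[i], per_label$r[i], per_label$n[i])
  }))
  micro <- counts_from_prn(0.8504, 0.8924, 223)
  expect_equal(sum(cts$tp), micro$tp)
  expect_equal(sum(cts$fp), micro$fp)
  expect_equal(sum(cts$fn), micro$fn)
})

test_that("exact vs relaxed matching behaves as defined", {
  gold <- mention_table("ENTITY", 10, 25, surface = NA_character_)
  pred <- mention_table("ENTITY", 12, 25, surface = NA_character_)
  ex <- match_mentions(gold, pred, "exact")
  expect_equal(ex[ex$label == "ENTITY", c("tp", "fp", "fn")],
               tibble::tibble(tp = 0L, fp = 1L, fn = 1L))
  rel <- match_mentions(gold, pred, "relaxed")
  expect_equal(rel[rel$label == "ENTITY", c("tp", "fp", "fn")],
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L))

  # overlap with the wrong label is no TP under either criterion
  pred2 <- mention_table("TIME", 12, 25, surface = NA_character_)
  for (crit in c("exact", "relaxed")) {
    mm <- match_mentions(gold, pred2, crit)
    expect_equal(sum(mm$tp), 0L)
  }

  # two predictions over one gold: one-to-one gives tp=1, fp=1
  pred3 <- mention_table(c("ENTITY", "ENTITY"), c(10, 14), c(13, 25),
                         surface = c(NA, NA))
  rel3 <- match_mentions(gold, pred3, "relaxed")
  expect_equal(rel3[, c("tp", "fp", "fn")],
               tibble::tibble(tp = 1L, fp = 1L, fn = 0L))
})

test_that("greedy one-to-one relaxed matching attains the maximum matching
           on small instances", {
  set.seed(42)
  for (rep in 1:60) {
    ng <- sample(0:6, 1)
    np <- sample(0:6, 1)
    gold <- random_mentions(ng)
    pred <- random_mentions(np)
    mm <- match_mentions(gold, pred, "relaxed")
    tp_greedy <- if (nrow(mm)) sum(mm$tp) else 0L
    compat <- matrix(FALSE, nrow = np, ncol = ng)
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        compat[i, j] <- pred$start[i] < gold$end[j] &&
          gold$start[j] < pred$end[i]
      }
    }
    tp_oracle <- if (np == 0 || ng == 0) 0L else max_bipartite_matching(compat)
    expect_equal(tp_greedy, tp_oracle)
  }
})

test_that("relaxed F dominates exact F per label on perturbed predictions", {
  set.seed(7)
  base <- generate_corpus(noise_free_config(seed = 17, n = 10))
  for (rep in 1:50) {
    doc <- base[[sample.int(length(base), 1)]]
    pred <- perturb_mentions(doc)
    ex <- evaluate_ner(list(doc), list(pred), "exact")
    rel <- evaluate_ner(list(doc), list(pred), "relaxed")
    joined <- merge(as.data.frame(ex), as.data.frame(rel), by = "label",
                    suffixes = c("_ex", "_rel"))
    expect_true(all(joined$tp_rel >= joined$tp_ex))
    expect_true(all(joined$fscore_rel >= joined$fscore_ex - 1e-12))
  }
})

test_that("micro counts equal summed per-label counts", {
  docs <- generate_corpus(noise_free_config(seed = 19, n = 5))
  preds <- lapply(docs, perturb_mentions)
  rep_ <- evaluate_ner(docs, preds, "exact")
  per <- rep_[rep_$label != "all", ]
  all_row <- rep_[rep_$label == "all", ]
  expect_equal(sum(per$tp), all_row$tp)
  expect_equal(sum(per$fp), all_row$fp)
  expect_equal(sum(per$fn), all_row$fn)
  expect_equal(all_row$support, sum(per$support))
})

test_that("gold evaluated against itself is perfect everywhere", {
  docs <- generate_corpus(generator_config(seed = 29, n_procedures = 6))
  for (crit in c("exact", "relaxed")) {
    rep_ <- evaluate_ner(docs, docs, crit)
    expect_true(all(rep_$precision == 1))
    expect_true(all(rep_$recall == 1))
    expect_true(all(rep_$fscore == 1))
  }
  rep_re <- evaluate_re(docs, docs, "gold")
  expect_true(all(rep_re$fscore == 1))
})

test_that("relation scoring requires both endpoints and the label", {
  gold <- two_step_doc()
  pred <- two_step_doc()
  # flip one relation label
  pred$relations$label[pred$relations$label == "ARG2"] <- "ARG1"
  rep_ <- evaluate_re(list(gold), list(pred), "gold")
  arg2 <- rep_[rep_$label == "ARG2", ]
  expect_equal(arg2$tp, 0L)
  expect_equal(arg2$fn, 1L)
  arg1 <- rep_[rep_$label == "ARG1", ]
  expect_equal(arg1$fp, 1L)

  # shifting an endpoint span breaks the exact endpoint match
  pred2 <- two_step_doc()
  pred2$mentions$start[1] <- pred2$mentions$start[1] + 2L
  pred2$mentions$spans[[1]]$start <- pred2$mentions$spans[[1]]$start + 2L
  pred2$mentions$surface[1] <- NA_character_
  rep2 <- evaluate_re(list(gold), list(pred2), "gold")
  expect_lt(rep2$fscore[rep2$label == "all"], 1)
  # ... but relaxed endpoint matching accepts the overlap
  rep3 <- evaluate_re(list(gold), list(pred2), "gold",
                      endpoint_match = "relaxed")
  expect_equal(rep3$fscore[rep3$label == "all"], 1)

  # dangling endpoints are an error
  bad <- two_step_doc()
  bad$relations$tail_id[1] <- "T99"
  expect_error(evaluate_re(list(gold), list(bad), "gold"), "dangling")
})

test_that("per-verb recall groups gold actions by resolved lemma", {
  docs <- generate_corpus(noise_free_config(seed = 37, n = 15))
  preds <- lapply(docs, function(d) run_pipeline(d$text, doc_id = d$doc_id))
  vr <- verb_recall(docs, preds)
  expect_true(all(vr$recall == 1))
  # bookkeeping matches a direct count of gold actions
  n_gold <- sum(vapply(docs, function(d) {
    sum(d$mentions$label == "REACTION_STEP")
  }, integer(1)))
  expect_equal(sum(vr$n), n_gold)

  # a missed verb shows recall 0 for its lemma
  gold <- tiny_doc()
  none <- rxn_document(gold$text, doc_id = "tiny")
  vr2 <- verb_recall(list(gold), list(none))
  expect_equal(vr2$recall[vr2$lemma == "add"], 0)

  # split metadata propagates into per-split counts
  splits <- split_corpus(docs, seed = 3)
  flat <- c(splits$train, splits$dev, splits$test)
  vr3 <- verb_recall(flat, flat)
  expect_true(all(c("n_train") %in% names(vr3)))
  expect_equal(sum(vr3$n), n_gold)
  expect_true(all(vr3$recall == 1))
})
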