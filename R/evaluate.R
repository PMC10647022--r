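# Exact and relaxed span-matching evaluation for NER, plus relation
# scoring. P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R), with the 0/0 -> 0
# convention throughout.

#' Precision, recall and F-score from counts
#'
#' @param tp,fp,fn Non-negative integer counts (vectorized).
#' @return A tibble with `precision`, `recall`, `fscore`; any 0/0 is 0.
#' @export
#' @examples
#' prf(54, 3, 5)
prf <- function(tp, fp, fn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  tibble(
    precision = p, recall = r,
    fscore = safe_div(2 * p * r, p + r)
  )
}

#' Recover integer counts from printed precision/recall/support
#'
#' Published tables print P, R and the gold support n to four decimal
#' places; since TP, FP and FN are integers they are recoverable exactly:
#' `tp = round(r * n)`, `fp = round(tp / p) - tp`, `fn = n - tp`. The
#' recovered counts must reproduce the printed P and R at 4 decimal places,
#' otherwise the inputs are inconsistent and an error is raised.
#'
#' @param p,r Printed precision and recall (0 < value <= 1).
#' @param n Gold support (tp + fn).
#' @return A tibble with `tp`, `fp`, `fn`.
#' @export
#' @examples
#' counts_from_prn(0.9474, 0.9153, 59)
counts_from_prn <- function(p, r, n) {
  stopifnot(p > 0, p <= 1, r > 0, r <= 1, n > 0)
  tp <- as.integer(round(r * n))
  fp <- as.integer(round(tp / p)) - tp
  fn <- as.integer(n) - tp
  back <- prf(tp, fp, fn)
  if (round(back$precision, 4) != round(p, 4) ||
      round(back$recall, 4) != round(r, 4)) {
    abort(sprintf(
      "counts (tp=%d, fp=%d, fn=%d) do not reproduce p=%.4f, r=%.4f",
      tp, fp, fn, p, r
    ))
  }
  tibble(tp = tp, fp = fp, fn = fn)
}

# Fragment-level overlap between two (possibly discontinuous) mentions.
mentions_overlap <- function(sp_a, sp_b) {
  for (i in seq_len(nrow(sp_a))) {
    if (any(spans_overlap(sp_a$start[i], sp_a$end[i], sp_b$start, sp_b$end))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Match predicted mentions against gold
#'
#' Exact match: a prediction is a true positive iff its full span set and
#' label both equal a gold mention's. Relaxed match: at least one character
#' of overlap with the same label suffices. Matching is one-to-one by
#' default — each gold mention absorbs at most one prediction, assigned
#' greedily in order of predicted start offset (each prediction takes the
#' earliest-starting unmatched overlapping gold) — so duplicate
#' predictions over one gold span still cost a false positive. Set
#' `one_to_one = FALSE` for the many-to-one reading in which every
#' overlapping prediction counts.
#'
#' @param gold,pred Mention tibbles from the same document.
#' @param criterion `"exact"` or `"relaxed"`.
#' @param one_to_one Enforce one-to-one assignment (default `TRUE`).
#' @return A tibble with `label`, `tp`, `fp`, `fn` for every label present
#'   on either side.
#' @export
match_mentions <- function(gold, pred, criterion = c("exact", "relaxed"),
                           one_to_one = TRUE) {
  criterion <- match.arg(criterion)
  labels <- sort(unique(c(gold$label, pred$label)))
  rows <- map(labels, function(lab) {
    g <- arrange(gold[gold$label == lab, ], .data$start, .data$end)
    p <- arrange(pred[pred$label == lab, ], .data$start, .data$end)
    if (criterion == "exact") {
      g_sig <- map_chr(g$spans, span_signature)
      p_sig <- map_chr(p$spans, span_signature)
      g_taken <- rep(FALSE, nrow(g))
      tp <- 0L
      for (sig in p_sig) {
        j <- which(!g_taken & g_sig == sig)
        if (length(j)) {
          g_taken[j[1]] <- TRUE
          tp <- tp + 1L
        }
      }
    } else {
      g_taken <- rep(FALSE, nrow(g))
      tp <- 0L
      for (i in seq_len(nrow(p))) {
        js <- which(map_lgl(seq_len(nrow(g)), function(j) {
          mentions_overlap(p$spans[[i]], g$spans[[j]])
        }))
        if (one_to_one) {
          js <- js[!g_taken[js]]
          if (length(js)) {
            g_taken[js[1]] <- TRUE
            tp <- tp + 1L
          }
        } else if (length(js)) {
          g_taken[js] <- TRUE
          tp <- tp + 1L
        }
      }
    }
    tibble(label = lab, tp = tp, fp = nrow(p) - tp,
           fn = nrow(g) - sum(g_taken))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(label = character(), tp = integer(), fp = integer(),
                  fn = integer())
  }
  out
}

build_report <- function(counts, order_labels = NULL) {
  counts <- group_by(counts, .data$label)
  counts <- summarise(counts, tp = sum(.data$tp), fp = sum(.data$fp),
                      fn = sum(.data$fn), .groups = "drop")
  if (!is.null(order_labels)) {
    counts <- counts[order(match(counts$label, order_labels)), ]
  }
  micro <- tibble(label = "all", tp = sum(counts$tp), fp = sum(counts$fp),
                  fn = sum(counts$fn))
  all_rows <- bind_rows(counts, micro)
  out <- bind_cols(all_rows,
                   prf(all_rows$tp, all_rows$fp, all_rows$fn))
  out$support <- out$tp + out$fn
  out <- select(out, "label", "precision", "recall", "fscore", "support",
                "tp", "fp", "fn")
  class(out) <- c("rxn_eval", class(out))
  out
}

as_doc_list <- function(docs) {
  if (inherits(docs, "rxn_document")) docs <- list(docs)
  setNames(docs, map_chr(docs, function(d) d$doc_id))
}

#' Evaluate named-entity recognition
#'
#' Scores predicted documents against gold under exact or relaxed span
#' matching (see [match_mentions()]), with a per-label row for every label
#' and a micro-averaged `"all"` row whose counts are the summed per-label
#' counts.
#'
#' @param gold_docs,pred_docs Lists of [rxn_document()]s covering the same
#'   `doc_id`s.
#' @param criterion `"exact"` or `"relaxed"`.
#' @param one_to_one Passed to [match_mentions()].
#' @return An `rxn_eval` tibble: `label`, `precision`, `recall`, `fscore`,
#'   `support`, `tp`, `fp`, `fn`.
#' @export
evaluate_ner <- function(gold_docs, pred_docs,
                         criterion = c("exact", "relaxed"),
                         one_to_one = TRUE) {
  criterion <- match.arg(criterion)
  gold_docs <- as_doc_list(gold_docs)
  pred_docs <- as_doc_list(pred_docs)
  if (!setequal(names(gold_docs), names(pred_docs))) {
    abort("gold and predicted corpora must cover the same doc_ids")
  }
  counts <- bind_rows(map(names(gold_docs), function(id) {
    match_mentions(gold_docs[[id]]$mentions, pred_docs[[id]]$mentions,
                   criterion = criterion, one_to_one = one_to_one)
  }))
  if (nrow(counts) == 0) {
    counts <- tibble(label = character(), tp = integer(), fp = integer(),
                     fn = integer())
  }
  build_report(counts, order_labels = entity_labels())
}

relation_keys <- function(doc, endpoint = c("exact", "relaxed")) {
  endpoint <- match.arg(endpoint)
  m <- doc$mentions
  r <- doc$relations
  tibble(
    label = r$label,
    head_i = match(r$head_id, m$id),
    tail_i = match(r$tail_id, m$id)
  )
}

#' Evaluate relation extraction
#'
#' A predicted relation is a true positive iff its head and tail mentions
#' match a gold mention (exact span set and entity label by default) and
#' the relation label is equal; matching is one-to-one over relations.
#' With `entity_source = "gold"` the predictions are expected to reference
#' gold-standard mentions (the usual setting for scoring a relation
#' classifier in isolation); with `"predicted"` they reference
#' system-predicted mentions, so endpoint matching is what links the two
#' sides. `endpoint_match = "relaxed"` accepts overlapping endpoints with
#' the same entity label instead of identical spans.
#'
#' @inheritParams evaluate_ner
#' @param entity_source `"gold"` or `"predicted"` (documentation of the
#'   experimental setting; scoring is identical).
#' @param endpoint_match `"exact"` (default) or `"relaxed"`.
#' @return An `rxn_eval` tibble with per-relation-label rows and a micro
#'   `"all"` row.
#' @export
evaluate_re <- function(gold_docs, pred_docs,
                        entity_source = c("gold", "predicted"),
                        endpoint_match = c("exact", "relaxed")) {
  entity_source <- match.arg(entity_source)
  endpoint_match <- match.arg(endpoint_match)
  gold_docs <- as_doc_list(gold_docs)
  pred_docs <- as_doc_list(pred_docs)
  if (!setequal(names(gold_docs), names(pred_docs))) {
    abort("gold and predicted corpora must cover the same doc_ids")
  }
  counts <- bind_rows(map(names(gold_docs), function(id) {
    g <- gold_docs[[id]]
    p <- pred_docs[[id]]
    if (nrow(g$relations) > 0 &&
        anyNA(match(c(g$relations$head_id, g$relations$tail_id),
                    g$mentions$id)) ||
        nrow(p$relations) > 0 &&
        anyNA(match(c(p$relations$head_id, p$relations$tail_id),
                    p$mentions$id))) {
      abort(sprintf("dangling relation endpoints in %s", id))
    }
    end_match <- function(pm, gm) {
      if (pm$label != gm$label) return(FALSE)
      if (endpoint_match == "exact") {
        identical(span_signature(pm$spans[[1]]), span_signature(gm$spans[[1]]))
      } else {
        mentions_overlap(pm$spans[[1]], gm$spans[[1]])
      }
    }
    labels <- sort(unique(c(g$relations$label, p$relations$label)))
    bind_rows(map(labels, function(lab) {
      gr <- g$relations[g$relations$label == lab, ]
      pr <- p$relations[p$relations$label == lab, ]
      taken <- rep(FALSE, nrow(gr))
      tp <- 0L
      for (i in seq_len(nrow(pr))) {
        ph <- p$mentions[match(pr$head_id[i], p$mentions$id), ]
        pt <- p$mentions[match(pr$tail_id[i], p$mentions$id), ]
        js <- which(map_lgl(seq_len(nrow(gr)), function(j) {
          if (taken[j]) return(FALSE)
          gh <- g$mentions[match(gr$head_id[j], g$mentions$id), ]
          gt <- g$mentions[match(gr$tail_id[j], g$mentions$id), ]
          end_match(ph, gh) && end_match(pt, gt)
        }))
        if (length(js)) {
          taken[js[1]] <- TRUE
          tp <- tp + 1L
        }
      }
      tibble(label = lab, tp = tp, fp = nrow(pr) - tp, fn = nrow(gr) - tp)
    }))
  }))
  if (nrow(counts) == 0) {
    counts <- tibble(label = character(), tp = integer(), fp = integer(),
                     fn = integer())
  }
  build_report(counts, order_labels = relation_labels())
}

#' Per-verb recall of action mentions
#'
#' Groups gold `REACTION_STEP` mentions by their resolved verb lemma and
#' reports the fraction found by the predictions under exact span match,
#' together with occurrence counts. When documents carry split metadata a
#' count column per split is added.
#'
#' @inheritParams evaluate_ner
#' @param registry Roleset registry used for lemmatization.
#' @return A tibble with `lemma`, `recall`, `n` (and `n_<split>` columns
#'   when splits are present), sorted by `n` decreasing.
#' @export
verb_recall <- function(gold_docs, pred_docs, registry = default_registry()) {
  gold_docs <- as_doc_list(gold_docs)
  pred_docs <- as_doc_list(pred_docs)
  rows <- bind_rows(map(names(gold_docs), function(id) {
    g <- gold_docs[[id]]$mentions
    g <- g[g$label == "REACTION_STEP", ]
    if (nrow(g) == 0) return(NULL)
    p <- pred_docs[[id]]
    p_sig <- if (is.null(p)) character() else {
      pm <- p$mentions[p$mentions$label == "REACTION_STEP", ]
      map_chr(pm$spans, span_signature)
    }
    tibble(
      lemma = map_chr(g$surface, function(s) {
        rs <- resolve_roleset(s, registry)
        if (is.null(rs)) lemmatize(tail(tokenize(s)$token, 1),
                                   lexicon = registry$lemma) else rs$lemma
      }),
      found = map_chr(g$spans, span_signature) %in% p_sig,
      split = gold_docs[[id]]$split %||% NA_character_
    )
  }))
  if (nrow(rows) == 0) {
    return(tibble(lemma = character(), recall = double(), n = integer()))
  }
  out <- summarise(group_by(rows, .data$lemma),
                   recall = mean(.data$found), n = n(), .groups = "drop")
  if (any(!is.na(rows$split))) {
    per_split <- tidyr::pivot_wider(
      summarise(group_by(rows, .data$lemma, .data$split),
                k = n(), .groups = "drop"),
      names_from = "split", values_from = "k", names_prefix = "n_",
      values_fill = 0L
    )
    out <- left_join(out, per_split, by = "lemma")
  }
  arrange(out, dplyr::desc(.data$n), .data$lemma)
}

#' @export
tidy.rxn_eval <- function(x, ...) {
  as_tibble(x[x$label != "all", ])
}

#' @export
glance.rxn_eval <- function(x, ...) {
  as_tibble(x[x$label == "all", ])
}

#' @export
print.rxn_eval <- function(x, digits = 4, ...) {
  cat("<rxn_eval>\n")
  y <- as.data.frame(x)
  y$precision <- sprintf("%.4f", y$precision)
  y$recall <- sprintf("%.4f", y$recall)
  y$fscore <- sprintf("%.4f", y$fscore)
  print(y[, c("label", "precision", "recall", "fscore", "support")],
        row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as TSV (+ JSON alongside)
#'
#' Columns mirror the published table layout: label, precision, recall,
#' F-score (4 decimal places) and support.
#'
#' @param report An `rxn_eval` tibble.
#' @param path Output TSV path; a `.json` sibling is written next to it.
#' @export
write_eval_report <- function(report, path) {
  lines <- c(
    "label\tprecision\trecall\tfscore\tsupport",
    sprintf("%s\t%.4f\t%.4f\t%.4f\t%d", report$label, report$precision,
            report$recall, report$fscore, report$support)
  )
  writeLines(lines, path, useBytes = TRUE)
  jsonlite::write_json(
    as.data.frame(report[, c("label", "precision", "recall", "fscore",
                             "support", "tp", "fp", "fn")]),
    sub("\\.tsv$", ".json", paste0(sub("\\.json$", "", path))),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
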