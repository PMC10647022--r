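# Model-training views: per-track IOB2 token tagging and pairwise
# entity-marker relation instances. Tracks mirror the three overlapping
# taggers (actions, entities, parameters): labels may overlap across
# tracks, never within one.

track_labels <- function(track) {
  switch(track,
    action = "REACTION_STEP",
    entity = "ENTITY",
    parameter = parameter_labels(),
    abort("track must be one of 'action', 'entity', 'parameter'")
  )
}

# Tag a token table against a set of mentions (same track, non-overlapping).
mentions_to_iob2 <- function(tokens, mentions) {
  tags <- rep("O", nrow(tokens))
  if (nrow(mentions) == 0 || nrow(tokens) == 0) return(tags)
  mentions <- arrange(mentions, .data$start)
  for (i in seq_len(nrow(mentions))) {
    sp <- mentions$spans[[i]]
    covered <- which(map_lgl(seq_len(nrow(tokens)), function(j) {
      any(spans_overlap(tokens$start[j], tokens$end[j], sp$start, sp$end))
    }))
    if (length(covered) == 0) next
    tags[covered] <- paste0("I-", mentions$label[i])
    tags[covered[1]] <- paste0("B-", mentions$label[i])
  }
  tags
}

# IOB2 validity: I-x only after B-x or I-x.
check_iob2 <- function(tags) {
  prev <- "O"
  for (t in tags) {
    if (str_starts(t, "I-")) {
      lab <- sub("^I-", "", t)
      if (!(prev %in% paste0(c("B-", "I-"), lab))) return(FALSE)
    }
    prev <- t
  }
  TRUE
}

#' Export a document as per-sentence IOB2 token rows
#'
#' One of three views: `track = "action"` emits only `REACTION_STEP` tags,
#' `"entity"` only `ENTITY`, `"parameter"` the four parameter labels. The
#' document is sentence-split and tokenized with the packaged tokenizer; a
#' mention crossing a sentence boundary is an error.
#'
#' @param doc An [rxn_document()] that validates structurally.
#' @param track `"action"`, `"entity"` or `"parameter"`.
#' @return A tibble with `sentence` (1-based), `token`, `start`, `end`,
#'   `tag` columns; tags satisfy the IOB2 constraint.
#' @export
#' @examples
#' doc <- rxn_document("DMF was added.",
#'   mentions = mention_table(c("ENTITY", "REACTION_STEP"), c(0, 8), c(3, 13),
#'     text = "DMF was added."))
#' export_iob2(doc, "action")
export_iob2 <- function(doc, track = c("action", "entity", "parameter")) {
  track <- match.arg(track)
  labels <- track_labels(track)
  rep_ <- validate_document(doc)
  if (!doc_is_valid(rep_)) abort("document has structural errors")
  sents <- split_sentences(doc$text)
  m <- doc$mentions[doc$mentions$label %in% labels, ]
  out <- map(seq_len(nrow(sents)), function(si) {
    toks <- tokenize(sents$text[si], offset = sents$start[si])
    in_sent <- m[m$start >= sents$start[si] & m$start < sents$end[si], ]
    if (any(in_sent$end > sents$end[si])) {
      abort(sprintf("mention crosses sentence boundary in %s", doc$doc_id))
    }
    toks$tag <- mentions_to_iob2(toks, in_sent)
    toks$sentence <- si
    toks
  })
  out <- if (length(out)) bind_rows(out) else
    tibble(token = character(), start = integer(), end = integer(),
           tag = character(), sentence = integer())
  select(out, "sentence", "token", "start", "end", "tag")
}

#' Write IOB2 rows as CoNLL-style TSV
#'
#' Two columns (`token<TAB>tag`), one blank line between sentences.
#'
#' @param rows Output of [export_iob2()].
#' @param path Output file.
#' @export
write_iob2 <- function(rows, path) {
  lines <- character()
  for (si in unique(rows$sentence)) {
    chunk <- rows[rows$sentence == si, ]
    lines <- c(lines, sprintf("%s\t%s", chunk$token, chunk$tag), "")
  }
  writeLines(head(lines, -1), path, useBytes = TRUE)
  invisible(path)
}

mark_instance <- function(sent_text, sent_start, head_sp, tail_sp) {
  # insert [E1]..[/E1] around the action, [E2]..[/E2] around the argument;
  # offsets relative to the sentence
  h <- c(head_sp[1] - sent_start, head_sp[2] - sent_start)
  t <- c(tail_sp[1] - sent_start, tail_sp[2] - sent_start)
  pieces <- list(
    list(pos = h[1], tag = "[E1]"), list(pos = h[2], tag = "[/E1]"),
    list(pos = t[1], tag = "[E2]"), list(pos = t[2], tag = "[/E2]")
  )
  ord <- order(map_int(pieces, function(p) p$pos),
               map_int(pieces, function(p) match(p$tag, c("[/E1]", "[/E2]", "[E1]", "[E2]"))))
  pieces <- pieces[ord]
  out <- ""
  cursor <- 0L
  for (p in pieces) {
    out <- paste0(out, substr0(sent_text, cursor, p$pos), p$tag)
    cursor <- p$pos
  }
  paste0(out, substr0(sent_text, cursor, nchar(sent_text)))
}

#' Export pairwise relation-classification instances
#'
#' For every sentence, each (`REACTION_STEP`, other-mention) pair becomes
#' one instance: the sentence with `[E1]...[/E1]` markers around the action
#' and `[E2]...[/E2]` around the candidate argument, labelled with the gold
#' relation label or `"NONE"`. Pairs whose mentions overlap are skipped
#' (markers must not nest).
#'
#' @param doc An [rxn_document()] that validates structurally.
#' @return A tibble with `doc_id`, `sentence`, `head_id`, `tail_id`,
#'   `head_surface`, `tail_label`, `instance`, `label`.
#' @export
export_relation_instances <- function(doc) {
  rep_ <- validate_document(doc)
  if (!doc_is_valid(rep_)) abort("document has structural errors")
  sents <- split_sentences(doc$text)
  m <- doc$mentions
  r <- doc$relations
  out <- map(seq_len(nrow(sents)), function(si) {
    in_sent <- m[m$start >= sents$start[si] & m$start < sents$end[si], ]
    acts <- in_sent[in_sent$label == "REACTION_STEP", ]
    others <- in_sent[in_sent$label != "REACTION_STEP", ]
    if (nrow(acts) == 0 || nrow(others) == 0) return(NULL)
    pairs <- tidyr::expand_grid(hi = seq_len(nrow(acts)),
                                ti = seq_len(nrow(others)))
    rows <- pmap(pairs, function(hi, ti) {
      h <- acts[hi, ]
      t <- others[ti, ]
      if (spans_overlap(h$start, h$end, t$start, t$end)) return(NULL)
      gold <- r$label[r$head_id == h$id & r$tail_id == t$id]
      tibble(
        doc_id = doc$doc_id, sentence = si,
        head_id = h$id, tail_id = t$id,
        head_surface = h$surface, tail_label = t$label,
        instance = mark_instance(sents$text[si], sents$start[si],
                                 c(h$start, h$end), c(t$start, t$end)),
        label = if (length(gold)) gold[[1]] else "NONE"
      )
    })
    bind_rows(compact(rows))
  })
  out <- bind_rows(compact(out))
  if (nrow(out) == 0) {
    out <- tibble(doc_id = character(), sentence = integer(),
                  head_id = character(), tail_id = character(),
                  head_surface = character(), tail_label = character(),
                  instance = character(), label = character())
  }
  out
}

#' @rdname export_relation_instances
#' @param instances Output of `export_relation_instances()`.
#' @param path Output TSV file (`instance<TAB>label`).
#' @export
write_instances <- function(instances, path) {
  writeLines(sprintf("%s\t%s", instances$instance, instances$label), path,
             useBytes = TRUE)
  invisible(path)
}
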