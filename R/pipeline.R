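# Rule/lexicon reference pipeline: three overlapping NER tracks feeding a
# pairwise relation classifier. The taggers and classifier are pluggable
# contracts — the deterministic rule baseline here stands in for fine-tuned
# sequence models, and any model satisfying the same contracts can replace
# it.

#' Pipeline configuration
#'
#' Bundles the lexicon paths, pattern toggles and the first-mention filter
#' flag. Lexicon files hold one term per line (UTF-8); matching is
#' case-sensitive and longest-match-first within a track.
#'
#' @param entity_lexicon,modifier_lexicon,temperature_lexicon,temp_target_lexicon
#'   Paths to term lists; default to the packaged lexicons.
#' @param registry Roleset registry used by the action tagger and the rule
#'   relation classifier.
#' @param first_mention_filter Drop repeated identical parameters, keeping
#'   only the first mention per document (default `TRUE`, matching the
#'   annotation policy).
#' @param re_endpoint_match Endpoint matching mode recorded for evaluation
#'   runs (`"exact"` or `"relaxed"`).
#' @return A list of class `rxn_pipeline_config` with materialized lexicons.
#' @export
pipeline_config <- function(entity_lexicon = rxn_example("lexicon_entities.txt"),
                            modifier_lexicon = rxn_example("lexicon_modifiers.txt"),
                            temperature_lexicon = rxn_example("lexicon_temperature_words.txt"),
                            temp_target_lexicon = rxn_example("lexicon_temp_targets.txt"),
                            registry = default_registry(),
                            first_mention_filter = TRUE,
                            re_endpoint_match = "exact") {
  read_lex <- function(path) {
    if (is.null(path)) return(character())
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    unique(x[nzchar(str_trim(x))])
  }
  ents <- read_lex(entity_lexicon)
  structure(
    list(
      # sentence-initial uses of lexicon terms are capitalized in text
      entities = unique(c(ents, capitalize(ents))),
      modifiers = read_lex(modifier_lexicon),
      temperature_words = read_lex(temperature_lexicon),
      temp_targets = read_lex(temp_target_lexicon),
      registry = registry,
      first_mention_filter = isTRUE(first_mention_filter),
      re_endpoint_match = re_endpoint_match
    ),
    class = "rxn_pipeline_config"
  )
}

# ---- span pattern helpers -------------------------------------------------

# Locate all matches of `pattern` in `text`, returned as a start/end tibble
# (0-based half-open, sentence-local).
locate_pattern <- function(text, pattern, fixed_ = FALSE) {
  loc <- str_locate_all(text, if (fixed_) fixed(pattern) else pattern)[[1]]
  tibble(start = as.integer(loc[, "start"] - 1L), end = as.integer(loc[, "end"]))
}

# Drop candidate spans that overlap an earlier-accepted span;
# longest-match-first, ties by leftmost start.
resolve_overlaps <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  cands <- cands[order(-(cands$end - cands$start), cands$start), ]
  kept <- cands[0, ]
  for (i in seq_len(nrow(cands))) {
    if (nrow(kept) == 0 ||
        !any(spans_overlap(cands$start[i], cands$end[i], kept$start, kept$end))) {
      kept <- bind_rows(kept, cands[i, ])
    }
  }
  arrange(kept, .data$start)
}

word_bounded <- function(text, spans) {
  # keep only matches not glued to an adjacent letter/digit
  n <- nchar(text)
  ok <- map_lgl(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]
    e <- spans$end[i]
    before <- if (s > 0) substr0(text, s - 1L, s) else ""
    after <- if (e < n) substr0(text, e, e + 1L) else ""
    !grepl("[A-Za-z0-9]", before) && !grepl("[A-Za-z0-9]", after)
  })
  spans[ok, ]
}

num <- "[−-]?\\d+(?:\\.\\d+)?"

time_patterns <- function() {
  unit <- "(?:h|hr|hrs|hour|hours|min|minutes|s|sec|seconds|d|day|days)"
  c(
    paste0("\\d+(?:\\.\\d+)?\\s?[–—-]\\s?\\d+(?:\\.\\d+)?\\s?", unit, "\\b"),
    paste0("\\d+(?:\\.\\d+)?\\s?", unit, "\\b"),
    "\\bovernight\\b"
  )
}

temperature_patterns <- function(words) {
  deg <- paste0(num, "\\s?°C")
  c(
    "room temperature \\(\\d+(?:\\.\\d+)?\\s?°C\\)",
    paste0("between ", deg, " and ", deg),
    paste0(deg, "\\s?[–—-]\\s?", deg),
    paste0(deg),
    map_chr(words, function(w) paste0("\\Q", w, "\\E"))
  )
}

# ---- action detection -----------------------------------------------------

action_context_tokens <- function() c("to", "was", "were", "is", "are", "then", "and")
action_block_tokens <- function() {
  c("the", "a", "an", "of", "with", "under", "for", "in", "on", "at", "by",
    "from", "while", "during", "after", "before")
}

# Detect action-verb tokens in one tokenized sentence: the lemma must
# resolve in the registry and the token must sit in a verb context —
# sentence-initial (imperative), after an auxiliary/infinitive marker, or
# visibly inflected and not preceded by a determiner/preposition (which
# would signal a noun or modifier reading, e.g. "with stirring").
detect_actions <- function(tokens, registry) {
  if (nrow(tokens) == 0) return(integer())
  lems <- lemmatize(tokens$token, lexicon = registry$lemma)
  hits <- integer()
  for (i in seq_len(nrow(tokens))) {
    if (!lems[i] %in% registry$lemma) next
    low <- str_to_lower(tokens$token[i])
    prev <- if (i > 1) str_to_lower(tokens$token[i - 1]) else ""
    in_context <- i == 1 || prev %in% action_context_tokens()
    inflected <- low != lems[i] &&
      (str_detect(low, "(ed|ing|s)$") || low %in% names(default_lemma_dict()))
    if (in_context || (inflected && !prev %in% action_block_tokens() &&
                       !prev %in% c(",", ";", "("))) {
      hits <- c(hits, i)
    }
  }
  hits
}

# ---- rule NER -------------------------------------------------------------

#' Rule-based sequence tagger for one sentence
#'
#' The reference tagger for the three NER tracks. The `action` track tags
#' registry verbs in verb contexts as `REACTION_STEP`; the `parameter`
#' track tags times (number + unit, ranges, "overnight"), temperatures
#' (signed degrees, ranges, "between X °C and Y °C", worded temperatures
#' such as "room temperature" or "ice/water"), temperature targets
#' ("internal temperature", ...) and modifier phrases ("dropwise", "under
#' nitrogen", ...); the `entity` track matches the entity lexicon
#' longest-first and absorbs a following parenthesized amount or
#' coreference label into the span, so "A (1) (9.00 g, ...)" is one
#' mention.
#'
#' @param sentence Sentence text.
#' @param track `"action"`, `"entity"` or `"parameter"`.
#' @param config A [pipeline_config()].
#' @param offset 0-based offset of the sentence within its document.
#' @return A tibble of tokens with `token`, `start`, `end`, `tag` (IOB2).
#' @export
#' @examples
#' rule_ner("DMF was added to the flask over 10 min.", "parameter")
rule_ner <- function(sentence, track = c("action", "entity", "parameter"),
                     config = pipeline_config(), offset = 0L) {
  track <- match.arg(track)
  toks <- tokenize(sentence) # sentence-local offsets for span work
  spans <- rule_spans(sentence, toks, track, config)
  spans$label <- spans$label %||% character()
  mention_like <- tibble(
    id = paste0("x", seq_len(nrow(spans))),
    label = spans$label,
    start = spans$start, end = spans$end,
    surface = substr0(sentence, spans$start, spans$end),
    spans = map2(spans$start, spans$end, single_span)
  )
  toks$tag <- mentions_to_iob2(toks, mention_like)
  toks$start <- toks$start + as.integer(offset)
  toks$end <- toks$end + as.integer(offset)
  toks
}

# Compute labeled candidate spans (sentence-local) for one track.
rule_spans <- function(sentence, toks, track, config) {
  registry <- config$registry
  empty <- tibble(start = integer(), end = integer(), label = character())
  if (track == "action") {
    idx <- detect_actions(toks, registry)
    if (length(idx) == 0) return(empty)
    return(tibble(start = toks$start[idx], end = toks$end[idx],
                  label = "REACTION_STEP"))
  }
  if (track == "parameter") {
    cands <- list()
    collect <- function(patterns, label, fixed_ = FALSE) {
      for (p in patterns) {
        sp <- locate_pattern(sentence, p, fixed_ = fixed_)
        if (fixed_) sp <- word_bounded(sentence, sp)
        if (nrow(sp) > 0) {
          sp$label <- label
          cands[[length(cands) + 1]] <<- sp
        }
      }
    }
    collect(map_chr(config$temp_targets,
                    function(w) paste0("\\Q", w, "\\E")), "TEMP_TARGET")
    collect(temperature_patterns(config$temperature_words), "TEMPERATURE")
    collect(time_patterns(), "TIME")
    mod_sp <- map(config$modifiers, function(w) {
      sp <- word_bounded(sentence, locate_pattern(sentence, w, fixed_ = TRUE))
      if (nrow(sp) > 0) sp$label <- "MODIFIER"
      sp
    })
    cands <- c(cands, mod_sp)
    cands <- bind_rows(cands)
    if (nrow(cands) == 0) return(empty)
    # a bare number matched as TIME inside a temperature span etc. is
    # resolved longest-first
    return(resolve_overlaps(cands))
  }
  # entity track
  cands <- bind_rows(map(config$entities, function(term) {
    sp <- word_bounded(sentence, locate_pattern(sentence, term, fixed_ = TRUE))
    sp
  }))
  if (nrow(cands) == 0) return(empty)
  cands$label <- "ENTITY"
  cands <- resolve_overlaps(cands)
  # absorb following parenthesized amount/coreference groups
  n <- nchar(sentence)
  amount_re <- "^ \\(([^()]*)\\)"
  for (i in seq_len(nrow(cands))) {
    repeat {
      rest <- substr0(sentence, cands$end[i], n)
      mt <- regmatches(rest, regexec(amount_re, rest))[[1]]
      if (length(mt) == 0) break
      inner <- mt[2]
      looks_amount <- grepl("\\d", inner) &&
        !grepl("^(Notes?|Figures?|Figs?\\.?)\\s", inner)
      if (!looks_amount) break
      cands$end[i] <- cands$end[i] + nchar(mt[1])
    }
  }
  resolve_overlaps(cands)
}

#' Build a tagger contract from the rule baseline
#'
#' @param track NER track for the tagger.
#' @param config A [pipeline_config()].
#' @return A function `(sentence, offset) -> token/tag tibble` satisfying
#'   the sequence-tagger contract of [run_pipeline()].
#' @export
rule_tagger <- function(track, config = pipeline_config()) {
  force(track); force(config)
  function(sentence, offset = 0L) rule_ner(sentence, track, config, offset)
}

# ---- rule RE --------------------------------------------------------------

parse_marked_instance <- function(instance) {
  # recover the unmarked sentence and the E1/E2 spans
  tags <- c("[E1]", "[/E1]", "[E2]", "[/E2]")
  raw_pos <- map_int(tags, function(tag) {
    p <- str_locate_all(instance, fixed(tag))[[1]]
    if (nrow(p) != 1) abort("instance must contain each marker exactly once")
    as.integer(p[1, "start"] - 1L)
  })
  names(raw_pos) <- tags
  # unmarked position = raw position minus the widths of markers before it
  unmark <- function(tag) {
    before <- tags[raw_pos < raw_pos[[tag]]]
    raw_pos[[tag]] - sum(nchar(before))
  }
  pos <- setNames(map_int(tags, unmark), tags)
  ord <- order(raw_pos)
  text <- ""
  cursor <- 0L
  for (tag in tags[ord]) {
    text <- paste0(text, substr0(instance, cursor, raw_pos[[tag]]))
    cursor <- raw_pos[[tag]] + nchar(tag)
  }
  text <- paste0(text, substr0(instance, cursor, nchar(instance)))
  list(
    text = text,
    e1 = c(pos[["[E1]"]], pos[["[/E1]"]]),
    e2 = c(pos[["[E2]"]], pos[["[/E2]"]])
  )
}

prepositions_arg2 <- function() c("to", "into", "in", "onto", "with")

#' Rule-based relation classifier
#'
#' Classifies one entity-marker instance. Parameters attach as `ARGM` iff
#' the marked action is the nearest action to them in the sentence.
#' Entities: a subject preceding the action maps to `ARG1` (or `ARG0` for
#' the container subject of *contain*); an object introduced by
#' to/into/in/onto/with after the action maps to `ARG2` when the roleset
#' defines that slot and otherwise falls back to `ARG1`; a bare direct
#' object after the verb is `ARG1`. Pairs failing the nearest-action gate
#' are `NONE`.
#'
#' @param instance A marked instance string (one `[E1]..[/E1]` and one
#'   `[E2]..[/E2]` pair), or one row of [export_relation_instances()]
#'   output as a list.
#' @param registry Roleset registry.
#' @param config A [pipeline_config()] (used to recognize parameter
#'   arguments when the tail label is not supplied).
#' @param tail_label Optional entity label of the E2 mention; inferred from
#'   the surface when missing.
#' @return A relation label or `"NONE"`.
#' @export
#' @examples
#' rule_re("[E2]A[/E2] is [E1]added[/E1] to B")
#' rule_re("A is [E1]added[/E1] to [E2]B[/E2]")
rule_re <- function(instance, registry = default_registry(),
                    config = NULL, tail_label = NULL) {
  parsed <- parse_marked_instance(instance)
  text <- parsed$text
  e1 <- parsed$e1
  e2 <- parsed$e2
  toks <- tokenize(text)
  acts <- detect_actions(toks, registry)
  act_spans <- tibble(start = toks$start[acts], end = toks$end[acts])
  # the marked action itself may not be context-detectable (e.g. marked
  # surface spans several tokens); always include it
  if (!any(act_spans$start <= e1[1] & act_spans$end >= e1[2])) {
    act_spans <- bind_rows(act_spans, tibble(start = e1[1], end = e1[2]))
  }
  e1_surface <- substr0(text, e1[1], e1[2])
  e2_surface <- substr0(text, e2[1], e2[2])

  if (is.null(tail_label)) {
    tail_label <- infer_tail_label(e2_surface, config)
  }

  gaps <- span_gap(act_spans$start, act_spans$end, e2[1], e2[2])
  nearest <- act_spans[which.min(gaps), ]
  e1_is_nearest <- nearest$start < e1[2] && nearest$end > e1[1]
  if (!e1_is_nearest) return("NONE")

  if (tail_label %in% parameter_labels()) return("ARGM")

  rs <- resolve_roleset(e1_surface, registry)
  lemma <- if (is.null(rs)) NA_character_ else rs$lemma

  if (e2[2] <= e1[1]) {
    # argument precedes the action: surface subject
    if (!is.na(lemma) && lemma == "contain") return("ARG0")
    return("ARG1")
  }
  # argument follows the action: look for a governing preposition
  between <- toks[toks$start >= e1[2] & toks$end <= e2[1], ]
  preps <- str_to_lower(between$token)
  preps <- preps[preps %in% prepositions_arg2()]
  if (length(preps) > 0) {
    arg2_ok <- if (is.null(rs)) TRUE else has_arg(rs, "ARG2")
    return(if (arg2_ok) "ARG2" else "ARG1")
  }
  "ARG1"
}

infer_tail_label <- function(surface, config = NULL) {
  cfg <- config %||% pipeline_config()
  if (surface %in% cfg$temp_targets) return("TEMP_TARGET")
  for (p in temperature_patterns(cfg$temperature_words)) {
    if (grepl(paste0("^(?:", p, ")$"), surface, perl = TRUE)) return("TEMPERATURE")
  }
  for (p in time_patterns()) {
    if (grepl(paste0("^(?:", gsub("\\\\b", "", p), ")$"), surface, perl = TRUE)) {
      return("TIME")
    }
  }
  if (surface %in% cfg$modifiers) return("MODIFIER")
  "ENTITY"
}

#' Build a relation-classifier contract from the rule baseline
#'
#' @param registry Roleset registry.
#' @param config A [pipeline_config()].
#' @return A function `(instance, tail_label) -> label` satisfying the
#'   relation-classifier contract of [run_pipeline()].
#' @export
rule_re_model <- function(registry = default_registry(),
                          config = pipeline_config()) {
  force(registry); force(config)
  function(instance, tail_label = NULL) {
    rule_re(instance, registry = registry, config = config,
            tail_label = tail_label)
  }
}

# ---- first-mention filter -------------------------------------------------

normalize_param <- function(surface) {
  str_to_lower(gsub("\\s+", "", surface))
}

#' Keep only the first mention of each repeated parameter
#'
#' The annotation policy records a parameter only at its first mention:
#' the second "12 h" in "... was stirred 12 h. After 12 h, ..." is not
#' annotated. This filter drops later parameter mentions whose normalized
#' surface (lowercased, whitespace removed) and label repeat an earlier
#' one in the same document, together with their relations.
#'
#' @param doc An [rxn_document()].
#' @return A filtered `rxn_document`.
#' @export
apply_first_mention_filter <- function(doc) {
  m <- doc$mentions
  is_param <- m$label %in% parameter_labels()
  if (!any(is_param)) return(doc)
  ord <- order(m$start, m$end)
  seen <- character()
  drop <- character()
  for (i in ord) {
    if (!is_param[i]) next
    key <- paste(m$label[i], normalize_param(m$surface[i]), sep = "|")
    if (key %in% seen) drop <- c(drop, m$id[i]) else seen <- c(seen, key)
  }
  if (length(drop) == 0) return(doc)
  keep_m <- !(m$id %in% drop)
  r <- doc$relations
  keep_r <- !(r$tail_id %in% drop)
  rxn_document(doc$text, m[keep_m, ], r[keep_r, ], doc_id = doc$doc_id,
               split = doc$split, meta = doc$meta)
}

# ---- the pipeline ---------------------------------------------------------

#' Run the extraction pipeline over raw procedure text
#'
#' Preprocesses the text ([strip_note_refs()]), splits sentences, runs the
#' three sequence taggers (action, entity, parameter tracks), decodes and
#' merges their mentions (tracks may overlap each other but never
#' themselves), optionally applies the first-mention filter, builds all
#' intra-sentence candidate pairs and classifies each with the relation
#' model. The output document (over the cleaned text) always validates
#' structurally.
#'
#' @param text Raw procedure text.
#' @param taggers Named list with `action`, `entity`, `parameter` tagger
#'   functions `(sentence, offset) -> token/tag tibble`; defaults to the
#'   rule baseline.
#' @param re_model Relation classifier `(instance, tail_label) -> label`;
#'   defaults to the rule baseline.
#' @param config A [pipeline_config()].
#' @param doc_id Id for the output document.
#' @return An [rxn_document()] with predicted mentions and relations.
#' @export
#' @examples
#' doc <- run_pipeline("DMF (5 mL) was added to the flask over 10 min.")
#' doc$mentions[, 1:5]
run_pipeline <- function(text, taggers = NULL, re_model = NULL,
                         config = pipeline_config(), doc_id = "doc") {
  taggers <- taggers %||% list(
    action = rule_tagger("action", config),
    entity = rule_tagger("entity", config),
    parameter = rule_tagger("parameter", config)
  )
  re_model <- re_model %||% rule_re_model(config$registry, config)

  cleaned <- strip_note_refs(text)$text
  sents <- split_sentences(cleaned)
  mention_rows <- list()
  for (si in seq_len(nrow(sents))) {
    for (track in c("action", "entity", "parameter")) {
      tagged <- taggers[[track]](sents$text[si], sents$start[si])
      if (!check_iob2(tagged$tag)) {
        abort(sprintf("tagger for track '%s' emitted invalid IOB2 at sentence %d",
                      track, si))
      }
      mention_rows <- c(mention_rows, list(decode_iob2(tagged, cleaned)))
    }
  }
  mentions <- bind_rows(mention_rows)
  mentions <- if (nrow(mentions) == 0) empty_mentions() else {
    mentions <- arrange(mentions, .data$start, .data$end, .data$label)
    mentions$id <- paste0("T", seq_len(nrow(mentions)))
    mentions
  }
  doc <- rxn_document(cleaned, mentions, empty_relations(), doc_id = doc_id)
  if (config$first_mention_filter) doc <- apply_first_mention_filter(doc)

  inst <- export_relation_instances(doc)
  if (nrow(inst) > 0) {
    labels <- map_chr(seq_len(nrow(inst)), function(i) {
      re_model(inst$instance[i], inst$tail_label[i])
    })
    keep <- labels != "NONE"
    doc$relations <- relation_table(labels[keep], inst$head_id[keep],
                                    inst$tail_id[keep])
  }
  doc
}

# Decode one sentence's tagged tokens into mention rows.
decode_iob2 <- function(tagged, text) {
  rows <- list()
  cur <- NULL
  flush_cur <- function(cur) {
    if (is.null(cur)) return(NULL)
    tibble(
      id = NA_character_, label = cur$label,
      start = cur$start, end = cur$end,
      surface = substr0(text, cur$start, cur$end),
      spans = list(single_span(cur$start, cur$end))
    )
  }
  for (i in seq_len(nrow(tagged))) {
    tag <- tagged$tag[i]
    if (tag == "O") {
      rows <- c(rows, list(flush_cur(cur)))
      cur <- NULL
    } else if (str_starts(tag, "B-")) {
      rows <- c(rows, list(flush_cur(cur)))
      cur <- list(label = sub("^B-", "", tag),
                  start = tagged$start[i], end = tagged$end[i])
    } else {
      cur$end <- tagged$end[i]
    }
  }
  rows <- c(rows, list(flush_cur(cur)))
  bind_rows(compact(rows))
}

#' @rdname run_pipeline
#' @export
extract_procedure <- function(text, config = pipeline_config(),
                              doc_id = "doc") {
  run_pipeline(text, config = config, doc_id = doc_id)
}
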