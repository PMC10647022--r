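# Seeded generator of schema-conformant synthetic procedures. Templates
# instantiate the annotation-schema definitions (passive synthesis
# sentences, parameters annotated at first mention, amounts and
# coreference labels absorbed into one entity span) with a skewed verb
# distribution, standing in for the non-distributed corpus.

#' Generator configuration
#'
#' @param seed Integer seed; the generator draws from a single PRNG stream
#'   so identical configs give byte-identical corpora.
#' @param n_procedures Number of documents.
#' @param sentences_per_procedure Inclusive range (length-2 integer) of
#'   synthesis sentences per document.
#' @param verb_weights Named positive weights over registry lemmas; the
#'   default follows the published per-verb occurrence counts, so the
#'   add/stir-dominant skew of the real corpus is reproduced.
#' @param noise List of flags: `note_refs` inserts "(Note n)"/"(Figure n)"
#'   cross-references (never annotated), `workup_tail` appends unannotated
#'   workup sentences, `repeated_params` re-mentions an already-annotated
#'   parameter in later text (left unannotated, per the first-mention
#'   policy). All default to `TRUE`, matching raw journal text; pass all
#'   `FALSE` for a noise-free corpus.
#' @param adversarial Emit occasional relations whose label is missing
#'   from the head's roleset (`FALSE` by default; used to exercise the
#'   validator, never the evaluation).
#' @return A list of class `rxn_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_procedures = 10L,
                             sentences_per_procedure = c(4L, 10L),
                             verb_weights = default_verb_weights(),
                             noise = list(note_refs = TRUE,
                                          workup_tail = TRUE,
                                          repeated_params = TRUE),
                             adversarial = FALSE) {
  stopifnot(length(sentences_per_procedure) == 2,
            sentences_per_procedure[1] >= 1,
            sentences_per_procedure[1] <= sentences_per_procedure[2])
  if (any(verb_weights <= 0)) abort("verb weights must be positive")
  noise <- modifyList(list(note_refs = TRUE, workup_tail = TRUE,
                           repeated_params = TRUE), noise)
  structure(
    list(seed = as.integer(seed), n_procedures = as.integer(n_procedures),
         sentences_per_procedure = as.integer(sentences_per_procedure),
         verb_weights = verb_weights, noise = noise,
         adversarial = isTRUE(adversarial)),
    class = "rxn_generator_config"
  )
}

#' @rdname generator_config
#' @export
default_verb_weights <- function() {
  # corpus-wide occurrence counts of each action verb in the published
  # per-verb table, plus the handful of verbs attested only in examples
  c(add = 204, stir = 143, charge = 106, cool = 65, heat = 36,
    remove = 17, place = 12, backfill = 11, reflux = 8, transfer = 4,
    dissolve = 4, wash = 2, fill = 1, wrap = 1, hold = 1, mix = 1,
    open = 1, activate = 1, contain = 1, keep = 2, maintain = 2)
}

# ---- vocabularies ---------------------------------------------------------

gen_vocab <- function() {
  list(
    chems = c("DMF", "anhydrous CH2Cl2", "dichloromethane", "THF",
              "anhydrous THF", "toluene", "methanol", "diethyl ether",
              "ethyl acetate", "benzaldehyde", "triethylamine",
              "12-aminododecanolactam", "sodium chloride", "sodium hydride",
              "potassium carbonate", "acetic anhydride", "n-butyllithium",
              "cyclohexanone", "pyridine", "acetonitrile"),
    amounts = c("(150 mL)", "(5 mL)", "(20 mL)", "(0.50 g)",
                "(9.00 g, 45.6 mmol, 1.00 equiv)", "(2.50 g, 10.2 mmol)",
                "(1.1 equiv)", "(12.0 mL, 86.1 mmol)", "(3.2 g, 25 mmol)"),
    vessels = c("a 500-mL three-necked round-bottomed flask",
                "a 250-mL round-bottomed flask", "a 1-L round-bottomed flask",
                "a 100-mL Schlenk flask", "the flask", "the reaction vessel",
                "a dropping funnel"),
    mixtures = c("The mixture", "The reaction mixture",
                 "The resulting solution", "The suspension", "The solution"),
    times = c("10 min", "30 min", "45 min", "1 h", "2 h", "3 h", "12 h",
              "overnight", "14–15 h"),
    temps = c("0 °C", "−78 °C", "−10 °C", "65 °C", "100 °C",
              "room temperature", "room temperature (23 °C)",
              "between 0 °C and 5 °C", "ice/water"),
    temp_targets = c("internal temperature", "bath temperature"),
    modifiers = c("dropwise", "in one portion", "portionwise",
                  "under nitrogen", "under argon", "slowly", "via cannula"),
    workup = c(
      "The reaction mixture was washed with brine and concentrated under reduced pressure.",
      "The residue was purified by flash column chromatography.",
      "The combined organic layers were dried over MgSO4.",
      "The crude product was recrystallized from hot ethanol."
    )
  )
}

# ---- sentence builder -----------------------------------------------------

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$text <- ""
  b$mentions <- list()  # list(label, start, end)
  b$relations <- list() # list(label, head, tail) indices into mentions
  b
}

emit <- function(b, piece) {
  b$text <- paste0(b$text, piece)
  invisible(NULL)
}

emit_mention <- function(b, piece, label) {
  start <- nchar(b$text)
  emit(b, piece)
  b$mentions[[length(b$mentions) + 1]] <-
    list(label = label, start = start, end = nchar(b$text))
  length(b$mentions)
}

emit_relation <- function(b, label, head, tail) {
  b$relations[[length(b$relations) + 1]] <-
    list(label = label, head = head, tail = tail)
  invisible(NULL)
}

# ---- generator state ------------------------------------------------------

pick <- function(x, n = 1) x[sample.int(length(x), n)]

new_doc_state <- function(vocab) {
  st <- new.env(parent = emptyenv())
  st$vocab <- vocab
  st$seen_params <- character() # "LABEL|normalized"
  st$used_times <- character()
  st$coref <- 0L
  st$note <- 0L
  st
}

sample_entity <- function(st, kind = c("chem", "vessel", "mixture", "target")) {
  kind <- match.arg(kind)
  v <- st$vocab
  if (kind == "chem") {
    base <- pick(v$chems)
    p <- stats::runif(1)
    if (p < 0.25) {
      st$coref <- st$coref + 1L
      paste0(base, " (", st$coref, ") ", pick(v$amounts))
    } else if (p < 0.75) {
      paste(base, pick(v$amounts))
    } else {
      base
    }
  } else if (kind == "vessel") {
    pick(v$vessels)
  } else if (kind == "mixture") {
    pick(v$mixtures)
  } else {
    pick(v$vessels[1:4]) # an indefinite vessel for destinations
  }
}

# Emit an optional parameter: always writes the text, annotates (and
# relates) only at the parameter's first mention in the document.
emit_param <- function(b, st, label, surface, head) {
  key <- paste(label, normalize_param(surface), sep = "|")
  if (key %in% st$seen_params) {
    emit(b, surface)
  } else {
    st$seen_params <- c(st$seen_params, key)
    idx <- emit_mention(b, surface, label)
    emit_relation(b, "ARGM", head, idx)
  }
  if (label == "TIME") st$used_times <- unique(c(st$used_times, surface))
  invisible(NULL)
}

emit_entity_arg <- function(b, st, surface, label, head) {
  idx <- emit_mention(b, surface, "ENTITY")
  emit_relation(b, label, head, idx)
  idx
}

# ---- sentence templates ---------------------------------------------------

# Each template writes one full sentence (with trailing period) into the
# builder and records gold mentions and relations.
sentence_templates <- function() {
  list(
    charge = function(b, st) {
      vessel <- sample_entity(st, "vessel")
      v_idx <- emit_mention(b, capitalize(vessel), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "charged", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " with ")
      emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG2", a)
      if (stats::runif(1) < 0.3) {
        emit(b, " and ")
        emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG2", a)
      }
      if (stats::runif(1) < 0.3) {
        emit(b, " ")
        emit_param(b, st, "MODIFIER", pick(c("under nitrogen", "under argon")), a)
      }
      emit(b, ".")
    },
    add = function(b, st) {
      c_idx <- emit_mention(b, capitalize(sample_entity(st, "chem")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "added", "REACTION_STEP")
      emit_relation(b, "ARG1", a, c_idx)
      if (stats::runif(1) < 0.35) {
        emit(b, " ")
        emit_param(b, st, "MODIFIER",
                   pick(c("dropwise", "in one portion", "portionwise", "slowly")), a)
      }
      emit(b, " to ")
      tgt <- if (stats::runif(1) < 0.5) str_to_lower(sample_entity(st, "mixture"))
             else sample_entity(st, "vessel")
      emit_entity_arg(b, st, tgt, "ARG2", a)
      if (stats::runif(1) < 0.45) {
        emit(b, " over ")
        emit_param(b, st, "TIME", pick(st$vocab$times[st$vocab$times != "overnight"]), a)
      }
      if (stats::runif(1) < 0.3) {
        emit(b, " at ")
        emit_param(b, st, "TEMPERATURE", pick(st$vocab$temps), a)
      }
      emit(b, ".")
    },
    stir = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "stirred", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      if (stats::runif(1) < 0.6) {
        emit(b, " at ")
        emit_param(b, st, "TEMPERATURE", pick(st$vocab$temps), a)
      }
      if (stats::runif(1) < 0.7) {
        emit(b, " for ")
        emit_param(b, st, "TIME", pick(st$vocab$times[st$vocab$times != "overnight"]), a)
      }
      if (stats::runif(1) < 0.25) {
        emit(b, " ")
        emit_param(b, st, "MODIFIER", pick(c("under nitrogen", "under argon")), a)
      }
      emit(b, ".")
    },
    cool = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "cooled", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      emit(b, " to ")
      emit_param(b, st, "TEMPERATURE",
                 pick(c("0 °C", "−78 °C", "−10 °C", "ice/water",
                        "between 0 °C and 5 °C", "room temperature")), a)
      if (stats::runif(1) < 0.3) {
        emit(b, " over ")
        emit_param(b, st, "TIME", pick(c("10 min", "30 min", "45 min")), a)
      }
      emit(b, ".")
    },
    heat = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "heated", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      if (stats::runif(1) < 0.4) {
        emit(b, " in ")
        emit_entity_arg(b, st, "an oil bath", "ARG2", a)
      }
      emit(b, " to ")
      emit_param(b, st, "TEMPERATURE", pick(c("65 °C", "100 °C")), a)
      if (stats::runif(1) < 0.5) {
        emit(b, " for ")
        emit_param(b, st, "TIME", pick(st$vocab$times), a)
      }
      emit(b, ".")
    },
    remove = function(b, st) {
      e_idx <- emit_mention(b, "The cooling bath", "ENTITY")
      emit(b, " was then ")
      a <- emit_mention(b, "removed", "REACTION_STEP")
      emit_relation(b, "ARG1", a, e_idx)
      emit(b, ".")
    },
    place = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "placed", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " in ")
      emit_entity_arg(b, st, "an oil bath", "ARG2", a)
      emit(b, ".")
    },
    backfill = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "backfilled", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " with ")
      emit_entity_arg(b, st, pick(c("dry nitrogen gas", "dry argon gas")),
                      "ARG2", a)
      emit(b, ".")
    },
    reflux = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "refluxed", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      emit(b, " for ")
      emit_param(b, st, "TIME", pick(st$vocab$times[st$vocab$times != "overnight"]), a)
      emit(b, ".")
    },
    transfer = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "transferred", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      if (stats::runif(1) < 0.4) {
        emit(b, " ")
        emit_param(b, st, "MODIFIER", "via cannula", a)
      }
      emit(b, " to ")
      emit_entity_arg(b, st, sample_entity(st, "vessel"), "ARG2", a)
      emit(b, ".")
    },
    dissolve = function(b, st) {
      c_idx <- emit_mention(b, capitalize(sample_entity(st, "chem")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "dissolved", "REACTION_STEP")
      emit_relation(b, "ARG1", a, c_idx)
      emit(b, " in ")
      emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG2", a)
      emit(b, ".")
    },
    wash = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "washed", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " with ")
      emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG2", a)
      emit(b, ".")
    },
    fill = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "filled", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " with ")
      emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG2", a)
      emit(b, ".")
    },
    wrap = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "wrapped", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, " in ")
      emit_entity_arg(b, st, "aluminum foil", "ARG2", a)
      emit(b, ".")
    },
    hold = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "held", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      emit(b, " at ")
      emit_param(b, st, "TEMPERATURE", pick(c("0 °C", "−10 °C")), a)
      emit(b, " (")
      emit_param(b, st, "TEMP_TARGET", pick(st$vocab$temp_targets), a)
      emit(b, ") for ")
      emit_param(b, st, "TIME", pick(c("1 h", "30 min")), a)
      emit(b, ".")
    },
    mix = function(b, st) {
      c1 <- emit_mention(b, capitalize(sample_entity(st, "chem")), "ENTITY")
      emit(b, " and ")
      a_pre <- sample_entity(st, "chem")
      c2 <- emit_mention(b, a_pre, "ENTITY")
      emit(b, " were ")
      a <- emit_mention(b, "mixed", "REACTION_STEP")
      emit_relation(b, "ARG1", a, c1)
      emit_relation(b, "ARG1", a, c2)
      if (stats::runif(1) < 0.5) {
        emit(b, " for ")
        emit_param(b, st, "TIME", pick(c("10 min", "30 min")), a)
      }
      emit(b, ".")
    },
    open_ = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "opened", "REACTION_STEP")
      emit_relation(b, "ARG1", a, v_idx)
      emit(b, ".")
    },
    activate = function(b, st) {
      c_idx <- emit_mention(b, capitalize(sample_entity(st, "chem")), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "activated", "REACTION_STEP")
      emit_relation(b, "ARG1", a, c_idx)
      emit(b, ".")
    },
    contain = function(b, st) {
      v_idx <- emit_mention(b, capitalize(sample_entity(st, "vessel")), "ENTITY")
      emit(b, " ")
      a <- emit_mention(b, "contained", "REACTION_STEP")
      emit_relation(b, "ARG0", a, v_idx)
      emit(b, " ")
      emit_entity_arg(b, st, sample_entity(st, "chem"), "ARG1", a)
      emit(b, ".")
    },
    keep = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "kept", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      emit(b, " at ")
      emit_param(b, st, "TEMPERATURE", pick(c("room temperature",
                                              "room temperature (23 °C)")), a)
      if (stats::runif(1) < 0.5) {
        emit(b, " ")
        emit_param(b, st, "TIME", "overnight", a)
      }
      emit(b, ".")
    },
    maintain = function(b, st) {
      m_idx <- emit_mention(b, sample_entity(st, "mixture"), "ENTITY")
      emit(b, " was ")
      a <- emit_mention(b, "maintained", "REACTION_STEP")
      emit_relation(b, "ARG1", a, m_idx)
      emit(b, " at ")
      emit_param(b, st, "TEMPERATURE", pick(st$vocab$temps), a)
      emit(b, " for ")
      emit_param(b, st, "TIME", pick(st$vocab$times[st$vocab$times != "overnight"]), a)
      emit(b, ".")
    }
  )
}

template_for_lemma <- function(lemma) {
  if (lemma == "open") "open_" else lemma
}

# ---- document generation --------------------------------------------------

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the config seed. Every generated document satisfies
#' all schema invariants (zero validation errors against the registry) and
#' survives the brat round-trip; relation labels are always consistent
#' with the head's roleset slots unless `adversarial` is set.
#'
#' @param config A [generator_config()].
#' @param registry Roleset registry the verb weights must resolve in.
#' @return A list of [rxn_document()]s (ids `synth-001`, ...).
#' @export
#' @examples
#' docs <- generate_corpus(generator_config(seed = 7, n_procedures = 2))
#' docs[[1]]
generate_corpus <- function(config = generator_config(),
                            registry = default_registry()) {
  stopifnot(inherits(config, "rxn_generator_config"))
  unknown <- setdiff(names(config$verb_weights), registry$lemma)
  if (length(unknown)) {
    abort(paste0("verb weights reference unknown lemmas: ",
                 paste(unknown, collapse = ", ")))
  }
  templates <- sentence_templates()
  vocab <- gen_vocab()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  lemmas <- names(config$verb_weights)
  probs <- config$verb_weights / sum(config$verb_weights)

  map(seq_len(config$n_procedures), function(d) {
    st <- new_doc_state(vocab)
    rng <- config$sentences_per_procedure
    n_sent <- sample(seq(rng[1], rng[2]), 1)
    sent_parts <- list()
    for (si in seq_len(n_sent)) {
      b <- new_builder()
      lemma <- if (si == 1 && stats::runif(1) < 0.6) "charge" else
        sample(lemmas, 1, prob = probs)
      templates[[template_for_lemma(lemma)]](b, st)
      if (config$adversarial && stats::runif(1) < 0.3) {
        inject_adversarial_relation(b, registry)
      }
      if (config$noise$note_refs && stats::runif(1) < 0.35) {
        st$note <- st$note + 1L
        ref <- if (stats::runif(1) < 0.8) sprintf("(Note %d)", st$note) else
          sprintf("(Figure %d)", st$note)
        n <- nchar(b$text)
        b$text <- paste0(substr0(b$text, 0L, n - 1L), " ", ref, ".")
      }
      sent_parts[[si]] <- b
    }
    if (config$noise$repeated_params && length(st$used_times) > 0 &&
        stats::runif(1) < 0.5) {
      b <- new_builder()
      emit(b, sprintf("After %s, the reaction was judged complete.",
                      pick(st$used_times)))
      sent_parts[[length(sent_parts) + 1]] <- b
    }
    if (config$noise$workup_tail && stats::runif(1) < 0.7) {
      for (w in pick(vocab$workup, sample(1:2, 1))) {
        b <- new_builder()
        emit(b, w)
        sent_parts[[length(sent_parts) + 1]] <- b
      }
    }
    assemble_document(sent_parts, sprintf("synth-%03d", d),
                      meta = list(seed = config$seed,
                                  n_synthesis_sentences = n_sent))
  })
}

# An ARG2 relation on a roleset lacking the slot (the validator's
# warning case); only reachable through the adversarial flag.
inject_adversarial_relation <- function(b, registry) {
  labs <- map_chr(b$mentions, "label")
  acts <- which(labs == "REACTION_STEP")
  ents <- which(labs == "ENTITY")
  if (length(acts) == 0 || length(ents) == 0) return(invisible(NULL))
  a <- acts[[1]]
  surf <- substr0(b$text, b$mentions[[a]]$start, b$mentions[[a]]$end)
  rs <- resolve_roleset(surf, registry)
  if (is.null(rs) || has_arg(rs, "ARG2")) return(invisible(NULL))
  existing <- map_lgl(b$relations, function(r) {
    r$head == a && r$tail == ents[[1]] && r$label == "ARG2"
  })
  if (!any(existing)) emit_relation(b, "ARG2", a, ents[[1]])
  invisible(NULL)
}

assemble_document <- function(builders, doc_id, meta = list()) {
  text <- ""
  mentions <- list()
  relations <- list()
  offset_base <- 0L
  idx_base <- 0L
  for (b in builders) {
    if (nzchar(text)) {
      text <- paste0(text, " ")
      offset_base <- nchar(text)
    }
    text <- paste0(text, b$text)
    for (mn in b$mentions) {
      mentions[[length(mentions) + 1]] <-
        list(label = mn$label, start = mn$start + offset_base,
             end = mn$end + offset_base)
    }
    for (r in b$relations) {
      relations[[length(relations) + 1]] <-
        list(label = r$label, head = r$head + idx_base,
             tail = r$tail + idx_base)
    }
    idx_base <- idx_base + length(b$mentions)
    offset_base <- nchar(text)
  }
  if (length(mentions) == 0) {
    return(rxn_document(text, doc_id = doc_id, meta = meta))
  }
  m <- tibble(
    label = map_chr(mentions, "label"),
    start = map_int(mentions, function(x) as.integer(x$start)),
    end = map_int(mentions, function(x) as.integer(x$end))
  )
  ord <- order(m$start, m$end)
  m <- m[ord, ]
  m$id <- paste0("T", seq_len(nrow(m)))
  m$surface <- substr0(text, m$start, m$end)
  m$spans <- map2(m$start, m$end, single_span)
  old_pos <- match(seq_along(mentions), ord) # original index -> new row
  rel <- if (length(relations)) {
    tibble(
      label = map_chr(relations, "label"),
      head_id = m$id[old_pos[map_int(relations, function(x) as.integer(x$head))]],
      tail_id = m$id[old_pos[map_int(relations, function(x) as.integer(x$tail))]]
    )
  } else {
    empty_relations()
  }
  if (nrow(rel) > 0) {
    rel <- arrange(rel, match(.data$head_id, m$id), match(.data$tail_id, m$id))
    rel$id <- paste0("R", seq_len(nrow(rel)))
  }
  rxn_document(
    text,
    select(m, "id", "label", "start", "end", "surface", "spans"),
    if (nrow(rel) > 0) select(rel, "id", "label", "head_id", "tail_id")
    else empty_relations(),
    doc_id = doc_id, meta = meta
  )
}

# ---- splitting and statistics ---------------------------------------------

#' Split a corpus into train/dev/test
#'
#' Procedure-level split (a document is never divided): documents are
#' shuffled with the seed, then sliced contiguously. Dev and test each get
#' `floor(n * part / total)` documents and the remainder goes to train, so
#' 112 documents at 8:1:1 give 90/11/11.
#'
#' @param docs A list of [rxn_document()]s (at least 3).
#' @param ratio Positive integer ratio `c(train, dev, test)` with
#'   `train >= dev` and `train >= test`; default `c(8, 1, 1)`.
#' @param seed Shuffle seed.
#' @return A named list `train`/`dev`/`test` of documents with their
#'   `split` field set.
#' @export
split_corpus <- function(docs, ratio = c(8, 1, 1), seed = 1L) {
  stopifnot(length(docs) >= 3, length(ratio) == 3, all(ratio > 0),
            ratio[1] >= ratio[2], ratio[1] >= ratio[3])
  n <- length(docs)
  n_dev <- floor(n * ratio[2] / sum(ratio))
  n_test <- floor(n * ratio[3] / sum(ratio))
  n_train <- n - n_dev - n_test
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ord <- sample.int(n)
  assign_split <- function(idx, split) {
    map(docs[idx], function(d) {
      d$split <- split
      d
    })
  }
  list(
    train = assign_split(ord[seq_len(n_train)], "train"),
    dev = assign_split(ord[n_train + seq_len(n_dev)], "dev"),
    test = assign_split(ord[n_train + n_dev + seq_len(n_test)], "test")
  )
}

#' Corpus statistics tables
#'
#' Per-split document and sentence counts, and per-label mention/relation
#' counts with a total row — the bookkeeping views usually reported for an
#' annotated corpus.
#'
#' @param docs Either a flat list of [rxn_document()]s (their `split`
#'   fields are used when present) or a named list of splits as returned
#'   by [split_corpus()].
#' @return A list of class `rxn_corpus_stats` with tibbles `documents`
#'   (`split`, `procedures`, `sentences`), `ner` and `re` (one column per
#'   split plus `total`; last row is the per-column total).
#' @export
corpus_stats <- function(docs) {
  if (is.list(docs) && !is.null(names(docs)) &&
      all(names(docs) %in% c("train", "dev", "test")) &&
      !inherits(docs, "rxn_document")) {
    docs <- unlist(unname(imap(docs, function(ds, nm) {
      map(ds, function(d) {
        d$split <- nm
        d
      })
    })), recursive = FALSE)
  }
  if (inherits(docs, "rxn_document")) docs <- list(docs)
  splits <- map_chr(docs, function(d) {
    if (is.null(d$split) || is.na(d$split)) "all" else d$split
  })
  split_levels <- intersect(c("train", "dev", "test", "all"), unique(splits))
  if (length(split_levels) == 0) split_levels <- "all"

  documents <- bind_rows(map(split_levels, function(s) {
    ds <- docs[splits == s]
    tibble(
      split = s, procedures = length(ds),
      sentences = sum(map_int(ds, function(d) nrow(split_sentences(d$text))))
    )
  }))

  count_table <- function(get_labels, levels) {
    cols <- map(split_levels, function(s) {
      ds <- docs[splits == s]
      labs <- unlist(map(ds, get_labels))
      as.integer(table(factor(labs, levels = levels)))
    })
    out <- tibble(label = levels)
    for (i in seq_along(split_levels)) out[[split_levels[i]]] <- cols[[i]]
    out$total <- rowSums(as.matrix(out[split_levels]))
    total_row <- out[1, ]
    total_row$label <- "total"
    for (cn in c(split_levels, "total")) total_row[[cn]] <- sum(out[[cn]])
    bind_rows(out, total_row)
  }

  structure(
    list(
      documents = documents,
      ner = count_table(function(d) d$mentions$label, entity_labels()),
      re = count_table(function(d) d$relations$label, relation_labels())
    ),
    class = "rxn_corpus_stats"
  )
}

#' @export
print.rxn_corpus_stats <- function(x, ...) {
  cat("<rxn_corpus_stats>\n\nDocuments:\n")
  print(as.data.frame(x$documents), row.names = FALSE)
  cat("\nMention labels:\n")
  print(as.data.frame(x$ner), row.names = FALSE)
  cat("\nRelation labels:\n")
  print(as.data.frame(x$re), row.names = FALSE)
  invisible(x)
}
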