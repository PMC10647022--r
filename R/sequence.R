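# Ordered, roleset-resolved action sequences aligned to the source text.
# One step per REACTION_STEP mention, in text-offset order; arguments are
# grouped by relation label and carried verbatim (no unit parsing or
# chemistry inference), so every surface traces back to a text slice.

#' Build an action sequence from an annotated document
#'
#' Emits one step per `REACTION_STEP` mention in offset order. Arguments
#' are grouped by relation label (`arg0`/`arg1`/`arg2` surfaces, `params`
#' as label/surface pairs), each group ordered by mention start offset.
#' Nothing is dropped: a relation label missing from the head's roleset
#' (e.g. `ARG2` on `mix.01`) keeps its argument and adds an
#' `arg-not-in-roleset` warning to the step, and a verb with no resolvable
#' roleset yields an `unresolved-lemma` warning.
#'
#' @param doc An [rxn_document()] that validates structurally.
#' @param registry Roleset registry.
#' @return An object of class `rxn_sequence`: a list with `doc_id` and
#'   `steps`, a tibble with columns `ordinal`, `verb_surface`, `lemma`,
#'   `roleset_id`, `arg0`, `arg1`, `arg2` (list columns of surfaces),
#'   `params` (list column of label/surface tibbles), `start`, `end`,
#'   `warnings` (list column).
#' @export
#' @examples
#' txt <- "DMF was added to the flask."
#' doc <- rxn_document(txt,
#'   mentions = mention_table(c("ENTITY", "REACTION_STEP", "ENTITY"),
#'     c(0, 8, 17), c(3, 13, 26), text = txt),
#'   relations = relation_table(c("ARG1", "ARG2"), c("T2", "T2"),
#'     c("T1", "T3")))
#' build_sequence(doc)
build_sequence <- function(doc, registry = default_registry()) {
  rep_ <- validate_document(doc)
  if (!doc_is_valid(rep_)) abort("document has structural errors")
  m <- doc$mentions
  acts <- arrange(m[m$label == "REACTION_STEP", ], .data$start, .data$end)
  steps <- map(seq_len(nrow(acts)), function(i) {
    a <- acts[i, ]
    warnings <- character()
    rs <- resolve_roleset(a$surface, registry)
    if (is.null(rs)) {
      lemma <- lemmatize(tail(tokenize(a$surface)$token, 1),
                         lexicon = registry$lemma)
      roleset_id <- NA_character_
      warnings <- c(warnings, "unresolved-lemma")
    } else {
      lemma <- rs$lemma
      roleset_id <- rs$roleset_id
    }
    rel <- doc$relations[doc$relations$head_id == a$id, ]
    rel <- left_join(rel, m[, c("id", "label", "start", "surface")],
                     by = c(tail_id = "id"), suffix = c("", "_tail"))
    rel <- arrange(rel, .data$start)
    grab <- function(lab) rel$surface[rel$label == lab]
    for (lab in c("ARG0", "ARG1", "ARG2")) {
      if (any(rel$label == lab) && !is.null(rs) && !has_arg(rs, lab)) {
        warnings <- c(warnings, "arg-not-in-roleset")
      }
    }
    params <- rel[rel$label == "ARGM", ]
    tibble(
      ordinal = i, verb_surface = a$surface, lemma = lemma,
      roleset_id = roleset_id,
      arg0 = list(grab("ARG0")), arg1 = list(grab("ARG1")),
      arg2 = list(grab("ARG2")),
      params = list(tibble(label = params$label_tail,
                           surface = params$surface)),
      start = a$start, end = a$end,
      warnings = list(unique(warnings))
    )
  })
  steps <- if (length(steps)) bind_rows(steps) else
    tibble(ordinal = integer(), verb_surface = character(),
           lemma = character(), roleset_id = character(),
           arg0 = list(), arg1 = list(), arg2 = list(), params = list(),
           start = integer(), end = integer(), warnings = list())
  structure(list(doc_id = doc$doc_id, steps = steps),
            class = "rxn_sequence")
}

#' @export
print.rxn_sequence <- function(x, ...) {
  cat(sprintf("<rxn_sequence '%s'> %d steps\n", x$doc_id, nrow(x$steps)))
  if (nrow(x$steps) > 0) cat(render_text(x), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rxn_sequence <- function(x, ...) {
  as_tibble(x$steps)
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Render an action sequence as a numbered listing
#'
#' One line per step: `"N. <Lemma> <arg1, ...> [-> <arg2, ...>]
#' [(<param>, ...)]"`; container (`ARG0`) arguments render as an
#' `"in <container>"` prefix, and a step carrying warnings is suffixed
#' `"[!]"`. Deterministic given the sequence.
#'
#' @param seq An `rxn_sequence`.
#' @return A single string (empty for an empty sequence).
#' @export
render_text <- function(seq) {
  stopifnot(inherits(seq, "rxn_sequence"))
  s <- seq$steps
  if (nrow(s) == 0) return("")
  lines <- map_chr(seq_len(nrow(s)), function(i) {
    parts <- capitalize(s$lemma[i])
    if (length(s$arg0[[i]]) > 0) {
      parts <- paste(parts, paste0("in ", paste(s$arg0[[i]], collapse = ", ")))
    }
    if (length(s$arg1[[i]]) > 0) {
      parts <- paste(parts, paste(s$arg1[[i]], collapse = ", "))
    }
    if (length(s$arg2[[i]]) > 0) {
      parts <- paste(parts, "→", paste(s$arg2[[i]], collapse = ", "))
    }
    p <- s$params[[i]]
    if (nrow(p) > 0) {
      parts <- paste0(parts, " (", paste(p$surface, collapse = ", "), ")")
    }
    if (length(s$warnings[[i]]) > 0) parts <- paste(parts, "[!]")
    sprintf("%d. %s", s$ordinal[i], parts)
  })
  paste(lines, collapse = "\n")
}

sequence_schema_version <- "1.0"

#' Serialize an action sequence to JSON (and back)
#'
#' Loss-free, schema-versioned serialization:
#' `parse_sequence_json(render_json(seq))` reproduces the sequence,
#' including unicode surfaces, exactly.
#'
#' @param seq An `rxn_sequence`.
#' @return `render_json()`: a JSON string.
#' @export
render_json <- function(seq) {
  stopifnot(inherits(seq, "rxn_sequence"))
  s <- seq$steps
  steps <- map(seq_len(nrow(s)), function(i) {
    list(
      ordinal = s$ordinal[i],
      verb_surface = s$verb_surface[i],
      lemma = s$lemma[i],
      roleset_id = s$roleset_id[i],
      arg0 = as.list(s$arg0[[i]]), arg1 = as.list(s$arg1[[i]]),
      arg2 = as.list(s$arg2[[i]]),
      params = pmap(s$params[[i]], function(label, surface) {
        list(label = label, surface = surface)
      }),
      span = list(start = s$start[i], end = s$end[i]),
      warnings = as.list(s$warnings[[i]])
    )
  })
  jsonlite::toJSON(
    list(schema_version = sequence_schema_version,
         doc_id = seq$doc_id, steps = steps),
    auto_unbox = TRUE, null = "null", digits = NA
  )
}

#' @rdname render_json
#' @param json A JSON string produced by `render_json()`.
#' @return `parse_sequence_json()`: an `rxn_sequence`.
#' @export
parse_sequence_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(x$schema_version, sequence_schema_version)) {
    abort(paste0("unsupported sequence schema version: ", x$schema_version))
  }
  steps <- map(x$steps, function(st) {
    params <- if (length(st$params)) {
      tibble(label = map_chr(st$params, "label"),
             surface = map_chr(st$params, "surface"))
    } else {
      tibble(label = character(), surface = character())
    }
    tibble(
      ordinal = as.integer(st$ordinal),
      verb_surface = st$verb_surface,
      lemma = st$lemma,
      roleset_id = st$roleset_id %||% NA_character_,
      arg0 = list(as.character(unlist(st$arg0) %||% character())),
      arg1 = list(as.character(unlist(st$arg1) %||% character())),
      arg2 = list(as.character(unlist(st$arg2) %||% character())),
      params = list(params),
      start = as.integer(st$span$start), end = as.integer(st$span$end),
      warnings = list(as.character(unlist(st$warnings) %||% character()))
    )
  })
  steps <- if (length(steps)) bind_rows(steps) else
    tibble(ordinal = integer(), verb_surface = character(),
           lemma = character(), roleset_id = character(),
           arg0 = list(), arg1 = list(), arg2 = list(), params = list(),
           start = integer(), end = integer(), warnings = list())
  structure(list(doc_id = x$doc_id, steps = steps), class = "rxn_sequence")
}
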