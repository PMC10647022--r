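#' Annotation label sets
#'
#' The schema uses six labels for entity mentions and four for relations.
#' `REACTION_STEP` marks actions that transform reactants towards the
#' product; `ENTITY` marks chemicals, gases, flasks and other instruments;
#' `TIME`, `TEMPERATURE`, `TEMP_TARGET` and `MODIFIER` are collectively the
#' *parameter* labels. Relations always point from a `REACTION_STEP` head to
#' an argument: `ARG1`/`ARG2` (and, for containers only, `ARG0`) link to an
#' `ENTITY`, while `ARGM` links to a parameter.
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' entity_labels()
#' relation_labels()
entity_labels <- function() {
  c("REACTION_STEP", "ENTITY", "TIME", "TEMPERATURE", "TEMP_TARGET", "MODIFIER")
}

#' @rdname entity_labels
#' @export
relation_labels <- function() {
  c("ARG0", "ARG1", "ARG2", "ARGM")
}

#' @rdname entity_labels
#' @export
parameter_labels <- function() {
  c("TIME", "TEMPERATURE", "TEMP_TARGET", "MODIFIER")
}

#' Empty mention / relation tables
#'
#' Mentions are kept as a tibble with one row per mention: an `id`, a label,
#' the covering `start`/`end` offsets (0-based half-open), the covered
#' `surface` text, and a `spans` list-column holding one `start`/`end`
#' tibble per mention so that discontinuous (fragmented) brat mentions are
#' representable. Relations are a tibble of (`id`, `label`, `head_id`,
#' `tail_id`) rows.
#'
#' @return An empty tibble with the mention (or relation) columns.
#' @export
empty_mentions <- function() {
  tibble(
    id = character(), label = character(),
    start = integer(), end = integer(),
    surface = character(), spans = list()
  )
}

#' @rdname empty_mentions
#' @export
empty_relations <- function() {
  tibble(
    id = character(), label = character(),
    head_id = character(), tail_id = character()
  )
}

#' Build a mention table from parallel vectors
#'
#' Convenience constructor for contiguous mentions. Surfaces are sliced from
#' `text` when supplied; ids default to `T1`, `T2`, ... in `start` order.
#'
#' @param label Character vector of entity labels.
#' @param start,end Integer vectors of 0-based half-open offsets.
#' @param text Optional document text used to fill `surface`.
#' @param id Optional explicit ids.
#' @param surface Optional explicit surfaces (overrides `text`).
#' @return A mention tibble (see [empty_mentions()]).
#' @export
#' @examples
#' mention_table("ENTITY", 0, 3, text = "DMF was added.")
mention_table <- function(label, start, end, text = NULL, id = NULL,
                          surface = NULL) {
  if (length(label) == 0) return(empty_mentions())
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.null(surface)) {
    surface <- if (is.null(text)) NA_character_ else substr0(text, start, end)
  }
  out <- tibble(
    id = id %||% NA_character_, label = label,
    start = start, end = end, surface = surface,
    spans = map2(start, end, single_span)
  )
  out <- arrange(out, .data$start, .data$end)
  if (is.null(id)) out$id <- paste0("T", seq_len(nrow(out)))
  out
}

#' Build a relation table from parallel vectors
#'
#' @param label Character vector of relation labels.
#' @param head_id,tail_id Mention ids of the head (`REACTION_STEP`) and the
#'   argument.
#' @param id Optional explicit ids; default `R1`, `R2`, ...
#' @return A relation tibble (see [empty_relations()]).
#' @export
relation_table <- function(label, head_id, tail_id, id = NULL) {
  if (length(label) == 0) return(empty_relations())
  tibble(
    id = id %||% paste0("R", seq_along(label)),
    label = label, head_id = head_id, tail_id = tail_id
  )
}

#' Annotated procedure document
#'
#' Bundles a procedure text with its mention and relation tables plus
#' optional split metadata (`"train"`, `"dev"` or `"test"`).
#'
#' @param text Procedure text (single string, newlines preserved).
#' @param mentions Mention tibble (see [empty_mentions()]).
#' @param relations Relation tibble (see [empty_relations()]).
#' @param doc_id Document identifier.
#' @param split Optional split assignment.
#' @param meta Optional list of free-form metadata.
#' @return An object of class `rxn_document`.
#' @export
#' @examples
#' doc <- rxn_document("DMF was added.",
#'   mentions = mention_table(c("ENTITY", "REACTION_STEP"), c(0, 8), c(3, 13),
#'     text = "DMF was added."))
#' doc
rxn_document <- function(text, mentions = empty_mentions(),
                         relations = empty_relations(),
                         doc_id = "doc", split = NA_character_, meta = list()) {
  stopifnot(is.character(text), length(text) == 1)
  structure(
    list(
      doc_id = doc_id, text = text,
      mentions = as_tibble(mentions), relations = as_tibble(relations),
      split = split, meta = meta
    ),
    class = "rxn_document"
  )
}

#' @export
print.rxn_document <- function(x, ...) {
  cat(sprintf(
    "<rxn_document '%s'>  %d chars, %d mentions, %d relations%s\n",
    x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$relations),
    if (!is.na(x$split)) paste0(" [", x$split, "]") else ""
  ))
  invisible(x)
}

#' @export
glance.rxn_document <- function(x, ...) {
  tibble(
    doc_id = x$doc_id, n_chars = nchar(x$text),
    n_mentions = nrow(x$mentions), n_relations = nrow(x$relations),
    n_actions = sum(x$mentions$label == "REACTION_STEP"),
    split = x$split
  )
}

new_issue <- function(severity, code, message, ids = NA_character_) {
  tibble(severity = severity, code = code, message = message,
         ids = paste(ids, collapse = ","))
}

#' Validate an annotated document
#'
#' Structural checks are hard errors: span bounds, span ordering, surface
#' consistency, unknown labels, duplicate ids, unresolvable relation
#' endpoints, head/tail label compatibility (`ARGn` heads must be
#' `REACTION_STEP` with an `ENTITY` tail; `ARGM` tails must carry a
#' parameter label) and duplicated (head, tail, label) triples.
#'
#' When a roleset `registry` is supplied, roleset-aware checks are added:
#' `ARG0` on any roleset other than `contain.01` is an error (the container
#' frame is the only one whose agent slot is annotated); a numbered argument
#' missing from the head's roleset (e.g. `ARG2` on `mix.01`, whose frame has
#' only `ARG1`) is a *warning*, since such links remain interpretable against
#' the roleset; an action surface whose verb cannot be resolved to any
#' roleset is also a warning, mirroring unseen-verb behaviour.
#'
#' @param doc An [rxn_document()].
#' @param registry Optional roleset registry from [load_registry()].
#' @return A tibble of issues (class `rxn_validation`) with columns
#'   `severity` (`"error"`/`"warning"`), `code`, `message`, `ids`. A document
#'   satisfying every hard constraint yields no error rows.
#' @export
#' @examples
#' doc <- rxn_document("DMF was added.")
#' validate_document(doc)
validate_document <- function(doc, registry = NULL) {
  stopifnot(inherits(doc, "rxn_document"))
  issues <- list()
  m <- doc$mentions
  r <- doc$relations
  len <- nchar(doc$text)

  if (anyDuplicated(m$id)) {
    issues <- c(issues, list(new_issue(
      "error", "duplicate-id", "duplicate mention ids",
      m$id[duplicated(m$id)]
    )))
  }
  for (i in seq_len(nrow(m))) {
    sp <- m$spans[[i]]
    bad_bounds <- any(sp$start < 0L) || any(sp$end > len) ||
      any(sp$start >= sp$end)
    if (bad_bounds) {
      issues <- c(issues, list(new_issue(
        "error", "span-bounds",
        sprintf("mention %s has spans outside [0, %d) or empty", m$id[i], len),
        m$id[i]
      )))
      next
    }
    if (nrow(sp) > 1) {
      ok_order <- all(diff(sp$start) > 0) && all(sp$end[-nrow(sp)] <= sp$start[-1])
      if (!ok_order) {
        issues <- c(issues, list(new_issue(
          "error", "span-order",
          sprintf("mention %s has unsorted or overlapping fragments", m$id[i]),
          m$id[i]
        )))
        next
      }
    }
    if (!is.na(m$surface[i])) {
      got <- paste(substr0(doc$text, sp$start, sp$end), collapse = " ")
      if (got != m$surface[i]) {
        issues <- c(issues, list(new_issue(
          "error", "surface-mismatch",
          sprintf("mention %s surface %s does not match text %s",
                  m$id[i], dQuote(m$surface[i]), dQuote(got)),
          m$id[i]
        )))
      }
    }
    if (!m$label[i] %in% entity_labels()) {
      issues <- c(issues, list(new_issue(
        "error", "unknown-label",
        sprintf("mention %s has unknown label %s", m$id[i], m$label[i]),
        m$id[i]
      )))
    }
  }

  if (nrow(r) > 0 && anyDuplicated(r[c("label", "head_id", "tail_id")])) {
    dup <- r$id[duplicated(r[c("label", "head_id", "tail_id")])]
    issues <- c(issues, list(new_issue(
      "error", "duplicate-relation",
      "duplicate (head, tail, label) relation triples", dup
    )))
  }
  for (i in seq_len(nrow(r))) {
    if (!r$label[i] %in% relation_labels()) {
      issues <- c(issues, list(new_issue(
        "error", "unknown-label",
        sprintf("relation %s has unknown label %s", r$id[i], r$label[i]),
        r$id[i]
      )))
      next
    }
    hi <- match(r$head_id[i], m$id)
    ti <- match(r$tail_id[i], m$id)
    if (is.na(hi) || is.na(ti)) {
      issues <- c(issues, list(new_issue(
        "error", "unresolved-ref",
        sprintf("relation %s references unknown mention", r$id[i]), r$id[i]
      )))
      next
    }
    if (m$label[hi] != "REACTION_STEP") {
      issues <- c(issues, list(new_issue(
        "error", "head-not-action",
        sprintf("relation %s head %s is %s, not REACTION_STEP",
                r$id[i], r$head_id[i], m$label[hi]),
        r$id[i]
      )))
    }
    tail_ok <- if (r$label[i] == "ARGM") {
      m$label[ti] %in% parameter_labels()
    } else {
      m$label[ti] == "ENTITY"
    }
    if (!tail_ok) {
      issues <- c(issues, list(new_issue(
        "error", "label-incompatible",
        sprintf("relation %s: %s tail must be %s, got %s",
                r$id[i], r$label[i],
                if (r$label[i] == "ARGM") "a parameter label" else "ENTITY",
                m$label[ti]),
        r$id[i]
      )))
    }

    if (!is.null(registry) && m$label[hi] == "REACTION_STEP") {
      rs <- resolve_roleset(m$surface[hi], registry)
      if (is.null(rs)) next # unresolved-lemma warning emitted once below
      if (r$label[i] == "ARG0" && rs$roleset_id != "contain.01") {
        issues <- c(issues, list(new_issue(
          "error", "arg0-restricted",
          sprintf("relation %s: ARG0 is only annotated for contain.01, head is %s",
                  r$id[i], rs$roleset_id),
          r$id[i]
        )))
      } else if (r$label[i] %in% c("ARG0", "ARG1", "ARG2") &&
                 !has_arg(rs, r$label[i])) {
        issues <- c(issues, list(new_issue(
          "warning", "arg-not-in-roleset",
          sprintf("relation %s: %s is not a slot of %s",
                  r$id[i], r$label[i], rs$roleset_id),
          r$id[i]
        )))
      }
    }
  }

  if (!is.null(registry)) {
    acts <- m[m$label == "REACTION_STEP", ]
    for (i in seq_len(nrow(acts))) {
      if (is.na(acts$surface[i])) next
      if (is.null(resolve_roleset(acts$surface[i], registry))) {
        issues <- c(issues, list(new_issue(
          "warning", "unresolved-lemma",
          sprintf("action %s (%s) has no resolvable roleset",
                  acts$id[i], dQuote(acts$surface[i])),
          acts$id[i]
        )))
      }
    }
  }

  out <- if (length(issues)) bind_rows(issues) else
    tibble(severity = character(), code = character(),
           message = character(), ids = character())
  class(out) <- c("rxn_validation", class(out))
  out
}

#' @rdname validate_document
#' @param report A validation report from [validate_document()].
#' @return `doc_is_valid()`: `TRUE` when the report has no error rows.
#' @export
doc_is_valid <- function(report) {
  !any(report$severity == "error")
}
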