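# brat standoff I/O (v1.3 conventions). T records are text-bound mentions,
# possibly discontinuous ("start end;start end"); R records are binary
# relations whose slot names Arg1:/Arg2: are purely positional (head/tail)
# and unrelated to the ARG1/ARG2 relation types stored as the record TYPE.

#' Parse a brat standoff annotation pair
#'
#' @param txt Path to the `.txt` file (or, with `from_strings = TRUE`, the
#'   document text itself).
#' @param ann Path to the `.ann` file (or the annotation content).
#' @param doc_id Document id; defaults to the file stem.
#' @param from_strings Interpret `txt`/`ann` as content instead of paths.
#' @return An [rxn_document()].
#' @export
#' @examples
#' doc <- parse_standoff("DMF was added.", "T1\tENTITY 0 3\tDMF",
#'                       doc_id = "ex", from_strings = TRUE)
#' doc$mentions
parse_standoff <- function(txt, ann, doc_id = NULL, from_strings = FALSE) {
  if (from_strings) {
    text <- txt
    ann_lines <- if (length(ann) == 1) strsplit(ann, "\n", fixed = TRUE)[[1]] else ann
    doc_id <- doc_id %||% "doc"
  } else {
    text <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    ann_lines <- readLines(ann, encoding = "UTF-8", warn = FALSE)
    doc_id <- doc_id %||% sub("\\.txt$", "", basename(txt))
  }
  ann_lines <- ann_lines[nzchar(str_trim(ann_lines))]

  mentions <- list()
  relations <- list()
  for (line in ann_lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rid <- parts[[1]]
    if (str_starts(rid, "T")) {
      if (length(parts) < 2) abort(paste0("malformed T record: ", line))
      header <- parts[[2]]
      surface <- if (length(parts) >= 3) parts[[3]] else NA_character_
      sp <- strsplit(header, " ", fixed = TRUE)[[1]]
      label <- sp[[1]]
      if (!label %in% entity_labels()) {
        abort(sprintf("record %s: unknown entity label %s", rid, label))
      }
      frag_str <- paste(sp[-1], collapse = " ")
      frags <- strsplit(frag_str, ";", fixed = TRUE)[[1]]
      nums <- map(frags, function(f) {
        v <- suppressWarnings(as.integer(strsplit(str_trim(f), " ")[[1]]))
        if (length(v) != 2 || anyNA(v)) {
          abort(sprintf("record %s: malformed offsets %s", rid, dQuote(f)))
        }
        v
      })
      spans <- tibble(
        start = map_int(nums, 1),
        end = map_int(nums, 2)
      )
      got <- paste(substr0(text, spans$start, spans$end), collapse = " ")
      if (!is.na(surface) && got != surface) {
        abort(sprintf(
          "record %s: surface %s does not match text at offsets (%s)",
          rid, dQuote(surface), dQuote(got)
        ))
      }
      mentions <- c(mentions, list(tibble(
        id = rid, label = label,
        start = min(spans$start), end = max(spans$end),
        surface = if (is.na(surface)) got else surface,
        spans = list(spans)
      )))
    } else if (str_starts(rid, "R")) {
      if (length(parts) < 2) abort(paste0("malformed R record: ", line))
      sp <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      label <- sp[[1]]
      if (!label %in% relation_labels()) {
        abort(sprintf("record %s: unknown relation label %s", rid, label))
      }
      args <- sp[-1]
      head_id <- sub("^Arg1:", "", args[str_starts(args, "Arg1:")])
      tail_id <- sub("^Arg2:", "", args[str_starts(args, "Arg2:")])
      if (length(head_id) != 1 || length(tail_id) != 1) {
        abort(sprintf("record %s: expected Arg1: and Arg2: slots", rid))
      }
      relations <- c(relations, list(tibble(
        id = rid, label = label, head_id = head_id, tail_id = tail_id
      )))
    } else {
      abort(paste0("unsupported annotation record: ", line))
    }
  }
  mentions <- if (length(mentions)) bind_rows(mentions) else empty_mentions()
  relations <- if (length(relations)) bind_rows(relations) else empty_relations()
  rxn_document(text, mentions, relations, doc_id = doc_id)
}

#' Serialize a document to brat standoff content
#'
#' Mentions are renumbered `T1..` by span start (then end), relations
#' `R1..` by head start, so serialization is deterministic and
#' `parse_standoff()` inverts it exactly.
#'
#' @param doc An [rxn_document()] with no structural validation errors.
#' @return A list with `txt` and `ann` strings.
#' @export
serialize_standoff <- function(doc) {
  rep_ <- validate_document(doc)
  if (!doc_is_valid(rep_)) {
    abort(paste0("document has structural errors: ",
                 paste(unique(rep_$code[rep_$severity == "error"]),
                       collapse = ", ")))
  }
  m <- arrange(doc$mentions, .data$start, .data$end, .data$label)
  old2new <- setNames(paste0("T", seq_len(nrow(m))), m$id)
  t_lines <- map_chr(seq_len(nrow(m)), function(i) {
    sp <- m$spans[[i]]
    frag <- paste(sprintf("%d %d", sp$start, sp$end), collapse = ";")
    surface <- paste(substr0(doc$text, sp$start, sp$end), collapse = " ")
    sprintf("%s\t%s %s\t%s", old2new[[m$id[i]]], m$label[i], frag, surface)
  })
  r <- doc$relations
  if (nrow(r) > 0) {
    r$head_new <- unname(old2new[r$head_id])
    r$tail_new <- unname(old2new[r$tail_id])
    ord <- order(match(r$head_new, paste0("T", seq_len(nrow(m)))),
                 match(r$tail_new, paste0("T", seq_len(nrow(m)))),
                 r$label)
    r <- r[ord, ]
    r_lines <- sprintf("R%d\t%s Arg1:%s Arg2:%s",
                       seq_len(nrow(r)), r$label, r$head_new, r$tail_new)
  } else {
    r_lines <- character()
  }
  list(
    txt = doc$text,
    ann = paste(c(t_lines, r_lines), collapse = "\n")
  )
}

#' Read or write a brat corpus tree
#'
#' `write_brat_corpus()` lays documents out as
#' `dir/<split>/<doc_id>.{txt,ann}` (documents without split metadata go
#' directly under `dir`); `read_brat_corpus()` reads such a tree back,
#' recovering split assignment from the subdirectory names.
#'
#' @param docs A list of [rxn_document()]s.
#' @param dir Corpus directory.
#' @return `read_brat_corpus()`: a list of documents.
#' @export
write_brat_corpus <- function(docs, dir) {
  for (doc in docs) {
    sub <- if (is.na(doc$split)) dir else file.path(dir, doc$split)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    ser <- serialize_standoff(doc)
    writeLines(ser$txt, file.path(sub, paste0(doc$doc_id, ".txt")),
               useBytes = TRUE)
    writeLines(ser$ann, file.path(sub, paste0(doc$doc_id, ".ann")),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' @rdname write_brat_corpus
#' @export
read_brat_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", recursive = TRUE,
                          full.names = TRUE))
  map(txts, function(txt) {
    ann <- sub("\\.txt$", ".ann", txt)
    if (!file.exists(ann)) abort(paste0("missing .ann for ", txt))
    doc <- parse_standoff(txt, ann)
    rel <- dirname(sub(paste0("^", dir, "/?"), "", txt))
    if (rel %in% c("train", "dev", "test")) doc$split <- rel
    doc
  })
}
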