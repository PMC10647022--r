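# Text utilities: Note/Figure stripping, sentence splitting, tokenization.
# All offsets are 0-based half-open.

note_ref_pattern <- function() {
  # "(Note 11)", "(Notes 3 and 4)", "(Notes 3-5)", "(Figure 1)", "(Figs. 2,3)"
  num <- "\\d+"
  joiner <- "(?:\\s*(?:[–—,-]|and|to)\\s*)"
  paste0("\\((?:Notes?|Figures?|Figs?\\.?)\\s+", num,
         "(?:", joiner, num, ")*\\)")
}

#' Strip Note/Figure cross-references from procedure text
#'
#' Journal procedure text carries parenthesized cross-references such as
#' `"(Note 11)"` or `"(Figure 1)"` that are not part of the procedure
#' itself. This removes them (together with one preceding space, so no
#' doubled space is left behind) while leaving every other parenthesized
#' group — amounts, coreference labels like `"(1)"` — untouched.
#'
#' @param text A single string.
#' @return A list with `text` (the cleaned string) and `offset_map`, an
#'   integer vector with one element per cleaned character giving the
#'   0-based offset of that character in the original text. The map is
#'   strictly increasing, so cleaned spans translate back to original
#'   spans with [map_offsets()].
#' @export
#' @examples
#' strip_note_refs("anhydrous CH2Cl2 (150 mL) (Note 11) (Figure 1)")$text
strip_note_refs <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  pat <- paste0(" ?", note_ref_pattern())
  hits <- str_locate_all(text, pat)[[1]]
  keep <- rep(TRUE, nchar(text))
  for (i in seq_len(nrow(hits))) {
    keep[hits[i, "start"]:hits[i, "end"]] <- FALSE
  }
  kept <- which(keep)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  list(
    text = paste(chars[kept], collapse = ""),
    offset_map = as.integer(kept - 1L)
  )
}

#' Translate cleaned-text offsets back to original-text offsets
#'
#' @param offset_map Map from [strip_note_refs()].
#' @param start,end 0-based half-open span in the cleaned text.
#' @return Integer vector `c(start, end)` in the original text.
#' @export
map_offsets <- function(offset_map, start, end) {
  stopifnot(start >= 0, end > start, end <= length(offset_map))
  c(offset_map[start + 1L], offset_map[end] + 1L)
}

sentence_abbrevs <- function() {
  c("equiv", "aq", "approx", "ca", "cf", "vs", "al", "e.g", "i.e",
    "fig", "figs", "no", "wt", "vol", "mp", "bp", "anhyd", "conc", "sat",
    "dr", "prof", "etc", "ref")
}

#' Split procedure text into sentences
#'
#' Rule-based splitter with a fixed abbreviation list, tuned so that it
#' never breaks inside chemistry tokens: decimal numbers (`0.5 M`),
#' `equiv.`, `aq.`, temperatures (`0 °C.` ends a sentence only when a
#' new sentence follows) and `Fig.`-style abbreviations. A boundary is a
#' `.`, `?` or `!` followed by whitespace and an upper-case letter, digit
#' or opening bracket, where the preceding word is not a known
#' abbreviation or a single initial.
#'
#' @param text A single string.
#' @return A tibble with one row per sentence: `start`, `end` (0-based
#'   half-open, trimmed of surrounding whitespace) and `text`.
#' @export
#' @examples
#' split_sentences("A was added. B was stirred.")
split_sentences <- function(text) {
  empty <- tibble(start = integer(), end = integer(), text = character())
  if (is.na(text) || !nzchar(str_trim(text))) return(empty)
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  boundaries <- integer() # index (1-based) of the terminator character
  for (i in seq_len(n - 1L)) {
    ch <- chars[i]
    if (!ch %in% c(".", "?", "!")) next
    nxt <- chars[i + 1L]
    if (!grepl("\\s", nxt)) next
    after <- sub("^\\s+", "", substr(text, i + 1L, min(n, i + 8L)))
    if (!grepl("^[A-Z0-9(\"“]", after)) next
    if (ch == ".") {
      before <- substr(text, max(1L, i - 15L), i - 1L)
      word <- str_extract(before, "[°A-Za-z.\\-]+$")
      if (!is.na(word)) {
        wl <- str_to_lower(word)
        if (wl %in% sentence_abbrevs() || grepl("^[A-Z]$", word)) next
      }
      # never split a decimal number like "0.5"
      if (i > 1 && grepl("[0-9]", chars[i - 1L]) &&
          grepl("[0-9]", substr(text, i + 1L, i + 1L))) next
    }
    boundaries <- c(boundaries, i)
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  out <- purrr::map2(starts, ends, function(s, e) {
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 < s2) return(NULL)
    tibble(start = s2 - 1L, end = e2, text = substr(text, s2, e2))
  })
  out <- bind_rows(compact(out))
  if (nrow(out) == 0) empty else out
}

token_pattern <- function() {
  # keeps "°C", decimal numbers, ranges ("14–15"), hyphenated/slashed
  # chemical names and abbreviations with internal periods as one token;
  # any other non-space character is its own token
  paste0(
    "°C",
    "|[A-Za-z0-9](?:[A-Za-z0-9'’/.–—-]*[A-Za-z0-9])?",
    "|\\S"
  )
}

#' Tokenize text with the packaged regex tokenizer
#'
#' The tokenizer splits on whitespace and punctuation while keeping decimal
#' numbers (`9.00`), ranges (`14–15`), hyphenated chemical names
#' (`12-aminododecanolactam`), slashed words (`ice/water`) and the degree
#' unit `°C` as single tokens. The exact pattern is part of the
#' package contract so IOB2 exports are reproducible byte for byte.
#'
#' @param text A single string (usually one sentence).
#' @param offset 0-based offset of `text` within its document; added to
#'   token offsets.
#' @return A tibble with `token`, `start`, `end` (0-based half-open).
#' @export
#' @examples
#' tokenize("DMF (5 mL) was added at 0 °C.")
tokenize <- function(text, offset = 0L) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  loc <- str_locate_all(text, token_pattern())[[1]]
  tibble(
    token = str_sub(text, loc[, "start"], loc[, "end"]),
    start = as.integer(loc[, "start"] - 1L + offset),
    end = as.integer(loc[, "end"] + offset)
  )
}

#' Preprocess an annotated document
#'
#' Applies [strip_note_refs()] to the document text and remaps every
#' mention span through the offset map. A mention that overlaps removed
#' text raises an error (gold annotations never cover cross-references).
#'
#' @param doc An [rxn_document()].
#' @return A new `rxn_document` over the cleaned text.
#' @export
preprocess_document <- function(doc) {
  stopifnot(inherits(doc, "rxn_document"))
  cleaned <- strip_note_refs(doc$text)
  if (identical(cleaned$text, doc$text)) return(doc)
  # inverse map: original 0-based offset -> cleaned 0-based offset (or NA)
  inv <- rep(NA_integer_, nchar(doc$text))
  inv[cleaned$offset_map + 1L] <- seq_along(cleaned$offset_map) - 1L
  m <- doc$mentions
  for (i in seq_len(nrow(m))) {
    sp <- m$spans[[i]]
    ns <- inv[sp$start + 1L]
    ne <- inv[sp$end] + 1L # end-1 is the last covered char
    if (any(is.na(ns)) || any(is.na(ne)) ||
        any((ne - ns) != (sp$end - sp$start))) {
      abort(sprintf("mention %s overlaps removed cross-reference text", m$id[i]))
    }
    m$spans[[i]] <- tibble(start = as.integer(ns), end = as.integer(ne))
    m$start[i] <- min(ns)
    m$end[i] <- max(ne)
  }
  rxn_document(cleaned$text, m, doc$relations, doc_id = doc$doc_id,
               split = doc$split, meta = doc$meta)
}
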