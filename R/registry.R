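#' Load a roleset registry
#'
#' A roleset is a verb sense paired with described argument slots. The
#' registry file is tab-separated with a header row and columns
#' `lemma`, `sense`, `origin_type`, `arg0`, `arg1`, `arg2`; an empty slot
#' description means the slot is absent from the frame. Every roleset here
#' carries sense `01` (no verb in this domain needs more than one frame) and
#' an origin type classifying its provenance relative to PropBank:
#'
#' * `A` — taken from PropBank as-is or with surface/slot-ordering edits,
#' * `B` — slot definitions changed (e.g. `mix.01` collapsing two
#'   ingredient slots into one `ARG1`),
#' * `C` — new frame for a verb PropBank already lists,
#' * `D` — new frame for a verb absent from PropBank.
#'
#' Numbered slots stop at `ARG2`; parameters attach through `ARGM`, which is
#' never slot-governed. `ARG0` (the container) appears only on
#' `contain.01`.
#'
#' @param path Path to a registry TSV; defaults to the packaged registry.
#' @return A tibble (class `rxn_registry`) with one row per roleset:
#'   `lemma`, `roleset_id`, `origin_type`, `arg0`, `arg1`, `arg2`
#'   (slot descriptions, `NA` when absent).
#' @export
#' @examples
#' reg <- load_registry()
#' reg[reg$lemma == "add", ]
load_registry <- function(path = rxn_example("rolesets.tsv")) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE,
                           na.strings = "", quote = "",
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    out <- tibble(lemma = character(), roleset_id = character(),
                  origin_type = character(), arg0 = character(),
                  arg1 = character(), arg2 = character())
    class(out) <- c("rxn_registry", class(out))
    return(out)
  }
  needed <- c("lemma", "sense", "origin_type")
  if (!all(needed %in% names(raw))) {
    abort("registry file must have columns lemma, sense, origin_type, arg0, arg1, arg2")
  }
  for (slot in c("arg0", "arg1", "arg2")) {
    if (!slot %in% names(raw)) raw[[slot]] <- NA_character_
  }
  if (anyDuplicated(raw$lemma)) {
    abort(paste0("duplicate lemma in registry: ",
                 paste(unique(raw$lemma[duplicated(raw$lemma)]), collapse = ", ")))
  }
  if (any(raw$sense != "01")) {
    abort("registry sense suffix must be '01' for every roleset")
  }
  if (!all(raw$origin_type %in% c("A", "B", "C", "D"))) {
    abort("origin_type must be one of A, B, C, D")
  }
  extra <- setdiff(names(raw), c(needed, "arg0", "arg1", "arg2"))
  if (length(extra)) {
    abort("registry rows define slots beyond ARG2; frames stop at ARG2")
  }
  no_arg1 <- is.na(raw$arg1)
  if (any(no_arg1)) {
    warn(paste0("roleset(s) without an ARG1 slot: ",
                paste(raw$lemma[no_arg1], collapse = ", ")))
  }
  out <- tibble(
    lemma = str_to_lower(raw$lemma),
    roleset_id = paste0(str_to_lower(raw$lemma), ".", raw$sense),
    origin_type = raw$origin_type,
    arg0 = raw$arg0, arg1 = raw$arg1, arg2 = raw$arg2
  )
  class(out) <- c("rxn_registry", class(out))
  out
}

#' @rdname load_registry
#' @export
default_registry <- function() {
  cache <- getOption("rxnroles.registry_cache")
  if (is.null(cache)) {
    cache <- load_registry()
    options(rxnroles.registry_cache = cache)
  }
  cache
}

#' Load a surface-to-lemma dictionary
#'
#' Actions are sometimes written as nouns ("addition") or irregular forms
#' ("held") that suffix rules cannot reduce; the dictionary maps such
#' surfaces straight to their verb lemma and is consulted before any rule.
#'
#' @param path Path to a two-column TSV (`surface`, `lemma`); defaults to
#'   the packaged dictionary.
#' @return A named character vector (surface -> lemma, surfaces lowercased).
#' @export
load_lemma_dict <- function(path = rxn_example("lemma_dict.tsv")) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  setNames(str_to_lower(raw$lemma), str_to_lower(raw$surface))
}

#' @rdname load_lemma_dict
#' @export
default_lemma_dict <- function() {
  cache <- getOption("rxnroles.lemma_dict_cache")
  if (is.null(cache)) {
    cache <- load_lemma_dict()
    options(rxnroles.lemma_dict_cache = cache)
  }
  cache
}

#' Lemmatize a verb surface form
#'
#' Case-insensitive. The custom dictionary is consulted first; otherwise
#' English inflection suffixes (`-ed`, `-ing`, `-(e)s`) are stripped with
#' the usual candidate stems (bare stem, stem + `e`, undoubled final
#' consonant, `-i` back to `y`) and the first candidate found in `lexicon`
#' (by default, the packaged registry's lemmas) wins. Unknown tokens come
#' back lowercased so that [resolve_roleset()] can flag them.
#'
#' @param token Surface form(s), e.g. `"Charged"`.
#' @param dict Lemma dictionary from [load_lemma_dict()].
#' @param lexicon Character vector of known lemmas used to pick between
#'   candidate stems.
#' @return Lowercase lemma, vectorized over `token`.
#' @export
#' @examples
#' lemmatize(c("added", "addition", "Charged", "stirred"))
lemmatize <- function(token, dict = default_lemma_dict(),
                      lexicon = default_registry()$lemma) {
  vapply(token, function(tok) {
    low <- str_to_lower(str_trim(tok))
    if (!nzchar(low)) return(low)
    if (low %in% names(dict)) return(unname(dict[[low]]))
    if (low %in% lexicon) return(low)

    cands <- character()
    add_cands <- function(stem) {
      out <- stem
      n <- nchar(stem)
      if (n >= 2 && substr(stem, n, n) == substr(stem, n - 1, n - 1) &&
          !substr(stem, n, n) %in% c("l", "s")) {
        out <- c(out, substr(stem, 1, n - 1)) # stirr -> stir
      }
      out <- c(out, paste0(stem, "e"))        # charg -> charge
      if (n >= 1 && substr(stem, n, n) == "i") {
        out <- c(out, paste0(substr(stem, 1, n - 1), "y")) # dri -> dry
      }
      out
    }
    if (str_detect(low, "ed$") && nchar(low) > 3) {
      cands <- c(cands, add_cands(str_sub(low, 1, -3)),
                 str_sub(low, 1, -2)) # placed -> place
    }
    if (str_detect(low, "ing$") && nchar(low) > 4) {
      cands <- c(cands, add_cands(str_sub(low, 1, -4)))
    }
    if (str_detect(low, "es$") && nchar(low) > 3) {
      cands <- c(cands, str_sub(low, 1, -3))
    }
    if (str_detect(low, "s$") && nchar(low) > 2) {
      cands <- c(cands, str_sub(low, 1, -2))
    }
    hit <- cands[cands %in% lexicon]
    if (length(hit)) hit[[1]] else low
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve a mention surface to its roleset
#'
#' Tokenizes the surface, lemmatizes each token (so auxiliaries in
#' `"was added"` are skipped) and returns the first roleset hit in the
#' registry, or `NULL` when no token resolves — unknown verbs never create
#' rolesets, they surface later as warnings.
#'
#' @param surface Mention surface text, e.g. `"was added"`.
#' @param registry Registry from [load_registry()].
#' @param dict Lemma dictionary.
#' @return A one-row registry tibble, or `NULL`.
#' @export
#' @examples
#' resolve_roleset("was added")$roleset_id
resolve_roleset <- function(surface, registry = default_registry(),
                            dict = default_lemma_dict()) {
  if (is.na(surface) || !nzchar(surface)) return(NULL)
  toks <- tokenize(surface)$token
  if (length(toks) == 0) return(NULL)
  lems <- lemmatize(toks, dict = dict, lexicon = registry$lemma)
  hit <- match(lems, registry$lemma)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) return(NULL)
  registry[hit[[1]], ]
}

#' Does a roleset define a numbered argument slot?
#'
#' `ARGM` is not slot-governed (any roleset may take parameters), so
#' passing it is a contract violation.
#'
#' @param rs A one-row registry tibble (e.g. from [resolve_roleset()]).
#' @param label One of `"ARG0"`, `"ARG1"`, `"ARG2"`.
#' @return `TRUE` if the slot exists in the frame.
#' @export
#' @examples
#' has_arg(resolve_roleset("added"), "ARG2")
#' has_arg(resolve_roleset("mixed"), "ARG2")
has_arg <- function(rs, label) {
  stopifnot(is.data.frame(rs), nrow(rs) == 1)
  if (!label %in% c("ARG0", "ARG1", "ARG2")) {
    abort("has_arg() is defined for numbered slots only; ARGM is always allowed")
  }
  slot <- str_to_lower(label)
  !is.na(rs[[slot]])
}

#' Origin-type distribution of a registry
#'
#' Tabulates rolesets by origin type (see [load_registry()]) with integer
#' percentage shares; `pct_share()` is the matching helper for the share of
#' any subset count.
#'
#' @param registry Registry tibble.
#' @return A tibble with one row per type `A`--`D`: `origin_type`, `n`,
#'   `pct` (share rounded to the nearest integer percent).
#' @export
#' @examples
#' type_distribution(load_registry())
type_distribution <- function(registry) {
  counts <- table(factor(registry$origin_type, levels = c("A", "B", "C", "D")))
  n <- as.integer(counts)
  total <- sum(n)
  tibble(
    origin_type = names(counts), n = n,
    pct = if (total > 0) pct_share(n, total) else rep(0L, 4)
  )
}

#' @rdname type_distribution
#' @param n Count(s) in the subset.
#' @param total Registry size.
#' @return `pct_share()`: integer percent `round(100 * n / total)`.
#' @export
pct_share <- function(n, total) {
  as.integer(round(100 * n / total))
}
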