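# Shared internal helpers. Offsets are 0-based half-open throughout.

# Slice `text` at a 0-based half-open [start, end); vectorized over
# start/end.
substr0 <- function(text, start, end) {
  if (length(start) == 0) return(character(0))
  substring(text, start + 1L, end)
}

# Path to a packaged data file under inst/extdata.
rxn_example <- function(file) {
  path <- system.file("extdata", file, package = "rxnroles")
  if (!nzchar(path)) abort(paste0("packaged file not found: ", file))
  path
}

# Character gap between two 0-based spans; 0 when they touch or overlap.
span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# TRUE when [s1,e1) and [s2,e2) share at least one character.
spans_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# Canonical signature of a (possibly discontinuous) span set: "s-e;s-e".
span_signature <- function(spans) {
  paste(sprintf("%d-%d", spans$start, spans$end), collapse = ";")
}

# One-row-per-fragment tibble for a contiguous span.
single_span <- function(start, end) {
  tibble(start = as.integer(start), end = as.integer(end))
}

compact_chr <- function(x) x[!is.na(x) & nzchar(x)]
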