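# Shared fixtures and independent oracles, built in code.

# 0-based half-open span of the first occurrence of `piece` in `text`.
loc0 <- function(text, piece) {
  m <- regexpr(piece, text, fixed = TRUE)
  if (m < 0) stop("piece not found: ", piece)
  c(as.integer(m - 1L), as.integer(m - 1L + attr(m, "match.length")))
}

# A small gold-annotated single-sentence document.
tiny_doc <- function() {
  txt <- "DMF (5 mL) was added to the flask over 10 min."
  spans <- rbind(
    c(loc0(txt, "DMF (5 mL)"), 1),
    c(loc0(txt, "added"), 2),
    c(loc0(txt, "the flask"), 3),
    c(loc0(txt, "10 min"), 4)
  )
  m <- mention_table(
    label = c("ENTITY", "REACTION_STEP", "ENTITY", "TIME"),
    start = spans[, 1], end = spans[, 2], text = txt
  )
  r <- relation_table(c("ARG1", "ARG2", "ARGM"),
                      c("T2", "T2", "T2"), c("T1", "T3", "T4"))
  rxn_document(txt, m, r, doc_id = "tiny")
}

# Gold two-step sentence exercising argument grouping and parameters.
two_step_doc <- function() {
  txt <- "A (1 g) was added to B (5 mL) and the mixture was stirred at 0 °C for 2 h."
  sp <- list(
    a = loc0(txt, "A (1 g)"), add = loc0(txt, "added"),
    b = loc0(txt, "B (5 mL)"), mix = loc0(txt, "the mixture"),
    stir = loc0(txt, "stirred"), temp = loc0(txt, "0 °C"),
    time = loc0(txt, "2 h")
  )
  m <- mention_table(
    label = c("ENTITY", "REACTION_STEP", "ENTITY", "ENTITY",
              "REACTION_STEP", "TEMPERATURE", "TIME"),
    start = vapply(sp, `[`, integer(1), 1),
    end = vapply(sp, `[`, integer(1), 2),
    text = txt
  )
  # ids in start order: T1=A, T2=added, T3=B, T4=mixture, T5=stirred,
  # T6=temp, T7=time
  r <- relation_table(
    c("ARG1", "ARG2", "ARG1", "ARGM", "ARGM"),
    c("T2", "T2", "T5", "T5", "T5"),
    c("T1", "T3", "T4", "T6", "T7")
  )
  rxn_document(txt, m, r, doc_id = "two-step")
}

noise_free_config <- function(seed, n) {
  generator_config(
    seed = seed, n_procedures = n,
    noise = list(note_refs = FALSE, workup_tail = FALSE,
                 repeated_params = FALSE)
  )
}

# Independent oracle: maximum bipartite matching size via augmenting
# paths over an overlap (or exact) compatibility matrix.
max_bipartite_matching <- function(compat) {
  np <- nrow(compat)
  ng <- ncol(compat)
  match_g <- rep(0L, ng)
  try_kuhn <- function(i, visited) {
    for (j in seq_len(ng)) {
      if (compat[i, j] && !visited[j]) {
        visited[j] <- TRUE
        if (match_g[j] == 0L) {
          match_g[j] <<- i
          return(list(ok = TRUE, visited = visited))
        }
        res <- try_kuhn(match_g[j], visited)
        visited <- res$visited
        if (res$ok) {
          match_g[j] <<- i
          return(list(ok = TRUE, visited = visited))
        }
      }
    }
    list(ok = FALSE, visited = visited)
  }
  size <- 0L
  for (i in seq_len(np)) {
    if (try_kuhn(i, rep(FALSE, ng))$ok) size <- size + 1L
  }
  size
}

# Random mention sets for matching property tests. Mentions within one
# set are pairwise disjoint, as gold (and single-track predicted)
# mentions always are.
random_mentions <- function(n, label = "ENTITY") {
  if (n == 0) return(empty_mentions())
  widths <- sample.int(5L, n, replace = TRUE)
  gaps <- sample(0:4, n, replace = TRUE)
  starts <- cumsum(gaps) + c(0L, cumsum(utils::head(widths, -1)))
  ends <- starts + widths
  mention_table(label = rep(label, n), start = starts, end = ends,
                surface = rep(NA_character_, n))
}

# Randomly perturb a document's mentions: drop some, shift some spans,
# add spurious ones. Used for relaxed >= exact properties.
perturb_mentions <- function(doc) {
  m <- doc$mentions
  keep <- runif(nrow(m)) > 0.15
  m <- m[keep, ]
  n <- nchar(doc$text)
  for (i in seq_len(nrow(m))) {
    if (runif(1) < 0.3) {
      shift <- sample(c(-2L, -1L, 1L, 2L), 1)
      s <- max(0L, m$start[i] + shift)
      e <- min(n, max(s + 1L, m$end[i] + sample(c(-1L, 0L, 1L), 1)))
      m$start[i] <- s
      m$end[i] <- e
      m$spans[[i]] <- tibble::tibble(start = s, end = e)
      m$surface[i] <- NA_character_
    }
  }
  if (runif(1) < 0.5 && nchar(doc$text) > 12) {
    s <- sample.int(nchar(doc$text) - 6L, 1) - 1L
    extra <- mention_table(sample(entity_labels(), 1), s, s + 5L,
                           surface = NA_character_, id = "TX")
    m <- dplyr::bind_rows(m, extra)
  }
  m$id <- paste0("T", seq_len(nrow(m)))
  rxn_document(doc$text, m, empty_relations(), doc_id = doc$doc_id)
}
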