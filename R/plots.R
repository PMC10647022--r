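# ggplot2 views of the package's result objects.

#' @export
autoplot.rxn_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("label", "precision", "recall", "fscore")],
    cols = c("precision", "recall", "fscore"),
    names_to = "metric", values_to = "value"
  )
  df$metric <- factor(df$metric, levels = c("precision", "recall", "fscore"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Span-matching evaluation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rxn_corpus_stats <- function(object, ...) {
  df <- object$ner[object$ner$label != "total", ]
  df <- tidyr::pivot_longer(df, cols = setdiff(names(df), c("label", "total")),
                            names_to = "split", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                   y = .data$n, fill = .data$split)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "mentions", fill = NULL,
                  title = "Mention labels per split") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the verb (roleset) frequency distribution of a corpus
#'
#' Bars of action-mention counts per resolved lemma, most frequent first —
#' the skewed distribution characteristic of synthesis procedures.
#'
#' @param docs A list of [rxn_document()]s.
#' @param registry Roleset registry for lemmatization.
#' @param top Show only the `top` most frequent lemmas.
#' @return A ggplot object.
#' @export
plot_verb_distribution <- function(docs, registry = default_registry(),
                                   top = 15) {
  if (inherits(docs, "rxn_document")) docs <- list(docs)
  lemmas <- unlist(map(docs, function(d) {
    surfs <- d$mentions$surface[d$mentions$label == "REACTION_STEP"]
    map_chr(surfs, function(s) {
      rs <- resolve_roleset(s, registry)
      if (is.null(rs)) "(unresolved)" else rs$lemma
    })
  }))
  df <- as_tibble(table(lemma = lemmas))
  df <- head(arrange(df, dplyr::desc(.data$n)), top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$lemma, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = NULL, y = "occurrences",
                  title = "Action verb distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
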