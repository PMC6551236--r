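#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a unified consensus ranking
#'
#' Rank scores of the consensus elements, most central first, coloured by
#' element type (single agreed node vs supernode toss-up).
#'
#' @param object A `matria_ranking` from [matria()].
#' @param top Show at most this many elements (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot matria_ranking
#' @export
autoplot.matria_ranking <- function(object, top = 30, ...) {
  df <- tidy(object)
  df <- utils::head(df[order(df$position), ], top)
  df$label <- factor(df$members, levels = rev(df$members))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_score, y = .data$label,
                                   fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "consensus rank score (lower = more central)",
                  y = NULL, fill = "element") +
    ggplot2::theme_minimal()
}

#' Plot a discovery trace
#'
#' Centrality value of each extracted node against its discovery rank --
#' the de-biasing loop's decay profile.
#'
#' @param object A `discovery_trace` from [iterate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discovery_trace
#' @export
autoplot.discovery_trace <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "discovery rank", y = "centrality at discovery",
                  title = sprintf("iterative %s", object$backbone)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
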