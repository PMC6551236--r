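#' Stable-triad dependency edges of a node
#'
#' Structural balance theory says a triangle is stable when it has zero or
#' exactly two negative edges (two friends, or two nodes sharing a common
#' enemy).  When the most central node `m` is extracted, the opposite edge
#' `B-C` of every stable triangle through `m` is treated as coincidental --
#' a tie that exists because of `m` -- and is removed with it.
#'
#' @param g A [signed_network].
#' @param m A node id in `g`.
#' @return A tibble with columns `from`, `to`: the opposite edges of all
#'   stable triangles through `m` (possibly zero rows).
#' @export
stable_triad_edges <- function(g, m) {
  stopifnot(inherits(g, "signed_network"))
  if (!m %in% g$nodes) rlang::abort(sprintf("node '%s' is not in the network", m))
  nb <- neighbours_of(g, m)
  out_from <- character(); out_to <- character()
  if (nrow(nb) >= 2) {
    w_m <- stats::setNames(nb$weight, nb$node)
    e <- g$edges
    cand <- e$from %in% nb$node & e$to %in% nb$node
    if (any(cand)) {
      ce <- e[cand, ]
      n_neg <- (w_m[ce$from] < 0) + (w_m[ce$to] < 0) + (ce$weight < 0)
      stable <- n_neg == 0 | n_neg == 2
      out_from <- ce$from[stable]
      out_to <- ce$to[stable]
    }
  }
  tibble::tibble(from = out_from, to = out_to)
}

#' Iterative centrality discovery
#'
#' The de-biasing loop around any centrality backbone: compute centralities
#' on the current network; if every value is (numerically) zero, stop;
#' otherwise extract the arg-max node, record it, remove it together with
#' its incident edges and its stable-triad dependency edges, and recompute.
#' Discovery order is the node's rank (1 = most central).  Arg-max ties are
#' broken by lexicographically smallest node id; the loop is fully
#' deterministic.
#'
#' @param g A [signed_network]; not modified.
#' @param backbone A registered backbone label (see [list_backbones()]).
#' @param zero_tol Centrality values at or below this are treated as zero
#'   ("unimportant").  Default `1e-9`: closeness values are sums of products
#'   of reals and never hit exact zero.
#' @return A `discovery_trace`: list with `backbone`, `trace` (tibble of
#'   `rank`, `node`, `value` at discovery), and `removed_edges` (one tibble
#'   of deleted stable-triad edges per iteration).  [tidy()] gives the
#'   (backbone, rank, node) table.
#' @examples
#' g <- generate_network(n_nodes = 12, topology = "modular", n_modules = 2,
#'                       seed = 1)
#' iterate(g, "DEG")
#' @export
iterate <- function(g, backbone, zero_tol = 1e-9) {
  stopifnot(inherits(g, "signed_network"), zero_tol >= 0)
  fn <- get_backbone(backbone)
  cur <- g
  discovered <- character()
  values <- double()
  removed <- list()
  repeat {
    cv <- fn(cur)
    if (!nrow(cv) || max(cv$value) <= zero_tol) break
    top <- cv$node[cv$value == max(cv$value)]
    m <- min(top)
    dep <- stable_triad_edges(cur, m)
    discovered <- c(discovered, m)
    values <- c(values, max(cv$value))
    removed <- c(removed, list(dep))
    cur <- remove_node_and_edges(cur, m, dep)
  }
  structure(list(backbone = backbone,
                 trace = tibble::tibble(rank = seq_along(discovered),
                                        node = discovered, value = values),
                 removed_edges = removed),
            class = "discovery_trace")
}

#' @export
print.discovery_trace <- function(x, ...) {
  cat(sprintf("<discovery_trace: backbone %s, %d nodes discovered>\n",
              x$backbone, nrow(x$trace)))
  if (nrow(x$trace)) print(utils::head(x$trace, 10))
  invisible(x)
}

#' Tidy a discovery trace
#' @param x A `discovery_trace` from [iterate()].
#' @param ... Unused.
#' @return A tibble with columns `backbone`, `rank`, `node`.
#' @method tidy discovery_trace
#' @export
tidy.discovery_trace <- function(x, ...) {
  tibble::tibble(backbone = x$backbone, rank = x$trace$rank, node = x$trace$node)
}

#' Write / read a discovery trace as TSV
#'
#' Columns `backbone`, `rank`, `node`, tab-separated with a header.
#' @param x A `discovery_trace`.
#' @param path File path.
#' @return `x` (write) or a `discovery_trace` (read).
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "discovery_trace"))
  utils::write.table(tidy(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character"))
  if (nrow(df)) df <- df[order(df$rank), ]
  structure(list(backbone = if (nrow(df)) df$backbone[1] else basename(path),
                 trace = tibble::tibble(rank = df$rank, node = df$node,
                                        value = NA_real_),
                 removed_edges = NULL),
            class = "discovery_trace")
}
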