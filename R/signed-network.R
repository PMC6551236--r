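#' Construct a signed weighted network
#'
#' A signed network is an undirected graph whose edge weights lie in
#' \[-1, 1\] excluding 0, the usual container for thresholded correlation
#' networks (microbial co-occurrence, gene co-expression): positive weights
#' are cooperative/co-occurring associations, negative weights antagonistic
#' ones.  Zero weights are rejected because a zero-weight edge is
#' indistinguishable from "no edge" in every path product and degree sum.
#'
#' @param edges A data frame with columns `from`, `to`, `weight` (extra
#'   columns are ignored).  The graph is undirected: `a b w` and `b a w`
#'   describe the same edge; listing both with equal weight is tolerated,
#'   with conflicting weights it is an error.  Self-loops are errors.
#' @param nodes Optional character vector of node ids; must contain every
#'   endpoint in `edges`.  Use it to declare isolated nodes.
#'
#' @return An object of class `signed_network` with elements `nodes` (a
#'   lexicographically sorted character vector) and `edges` (a tibble with
#'   columns `from`, `to`, `weight`, `from < to`, sorted).
#' @examples
#' g <- signed_network(tibble::tibble(
#'   from = c("a", "b"), to = c("b", "c"), weight = c(0.8, -0.5)
#' ))
#' network_nodes(g)
#' edge_weight(g, "c", "b")
#' @export
signed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double())
  }
  edges <- tibble::as_tibble(edges)
  required <- c("from", "to", "weight")
  if (!all(required %in% names(edges))) {
    rlang::abort("`edges` must have columns `from`, `to` and `weight`")
  }
  edges <- edges[required]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.double(edges$weight)

  if (anyNA(edges)) rlang::abort("`edges` contains missing values")
  bad_w <- which(edges$weight < -1 | edges$weight > 1 | edges$weight == 0)
  if (length(bad_w)) {
    rlang::abort(sprintf(
      "edge weight out of range [-1, 1] \\ {0}: %s-%s (%g)",
      edges$from[bad_w[1]], edges$to[bad_w[1]], edges$weight[bad_w[1]]))
  }
  loops <- which(edges$from == edges$to)
  if (length(loops)) {
    rlang::abort(sprintf("self-loop on node '%s' is not allowed",
                         edges$from[loops[1]]))
  }

  # canonical undirected form: from < to lexicographically
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp

  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- split(edges$weight, key)
    conflict <- vapply(dup, function(ws) length(unique(ws)) > 1L, logical(1))
    if (any(conflict)) {
      pair <- strsplit(names(dup)[which(conflict)[1]], "\r", fixed = TRUE)[[1]]
      rlang::abort(sprintf(
        "duplicate edge %s-%s with conflicting weights", pair[1], pair[2]))
    }
    edges <- edges[!duplicated(key), ]
  }
  edges <- edges[order(edges$from, edges$to), ]

  node_set <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  if (!is.null(nodes)) {
    missing <- setdiff(unique(c(edges$from, edges$to)), as.character(nodes))
    if (length(missing)) {
      rlang::abort(sprintf("edge endpoint(s) not in `nodes`: %s",
                           paste(missing, collapse = ", ")))
    }
  }

  structure(list(nodes = node_set, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network: %d nodes, %d edges (%d negative)>\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight < 0)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' @method as_tibble signed_network
#' @export
as_tibble.signed_network <- function(x, ...) x$edges

#' Node identifiers of a signed network
#' @param g A `signed_network`.
#' @return Character vector of node ids, lexicographically sorted.
#' @export
network_nodes <- function(g) {
  stopifnot(inherits(g, "signed_network"))
  g$nodes
}

#' Weight of one edge (symmetric lookup)
#' @param g A `signed_network`.
#' @param i,j Node ids.
#' @return The signed weight, or `NA` if the edge is absent.
#' @export
edge_weight <- function(g, i, j) {
  a <- min(i, j); b <- max(i, j)
  hit <- g$edges$from == a & g$edges$to == b
  if (any(hit)) g$edges$weight[which(hit)[1]] else NA_real_
}

#' Remove a node, its incident edges, and extra edges
#'
#' The elementary reduction step of the iterative centrality loop: the
#' extracted node disappears with all its incident edges, and any
#' coincidental stable-triad edges are deleted with it.  The input network
#' is not modified.
#'
#' @param g A `signed_network`.
#' @param node A node id present in `g`.
#' @param extra_edges Edges to delete as well: a data frame with columns
#'   `from` and `to` (order within a pair irrelevant), or `NULL`.
#' @return A new `signed_network` with one fewer node.
#' @export
remove_node_and_edges <- function(g, node, extra_edges = NULL) {
  stopifnot(inherits(g, "signed_network"))
  if (!node %in% g$nodes) {
    rlang::abort(sprintf("node '%s' is not in the network", node))
  }
  edges <- g$edges
  keep <- edges$from != node & edges$to != node
  if (!is.null(extra_edges) && NROW(extra_edges)) {
    ex <- tibble::as_tibble(extra_edges)
    a <- pmin(as.character(ex$from), as.character(ex$to))
    b <- pmax(as.character(ex$from), as.character(ex$to))
    key <- paste(edges$from, edges$to, sep = "\r")
    exkey <- paste(a, b, sep = "\r")
    absent <- setdiff(exkey, key)
    if (length(absent)) {
      pair <- strsplit(absent[1], "\r", fixed = TRUE)[[1]]
      rlang::abort(sprintf("edge %s-%s is not in the network", pair[1], pair[2]))
    }
    keep <- keep & !(key %in% exkey)
  }
  structure(list(nodes = setdiff(g$nodes, node), edges = edges[keep, ]),
            class = "signed_network")
}

# internal: integer-indexed edge list against the sorted node vector
network_index <- function(g) {
  list(n = length(g$nodes),
       ei = match(g$edges$from, g$nodes),
       ej = match(g$edges$to, g$nodes),
       w = g$edges$weight)
}

# internal: adjacency as a named list of tibbles(to, weight)
neighbours_of <- function(g, node) {
  e <- g$edges
  hit <- e$from == node | e$to == node
  other <- ifelse(e$from[hit] == node, e$to[hit], e$from[hit])
  tibble::tibble(node = other, weight = e$weight[hit])
}
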