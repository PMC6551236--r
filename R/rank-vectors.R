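#' Expand a ranking to a per-node rank vector
#'
#' For cross-method comparison every node gets one numeric rank: members of
#' the r-th element (agreement node or supernode) inherit position `r`;
#' all remaining nodes (unresolvable and agreed-unimportant) share the tied
#' last position, number of elements + 1.  A single discovery trace expands
#' the same way: discovered nodes keep their discovery rank, undiscovered
#' nodes tie at trace length + 1.
#'
#' @param r A `matria_ranking` from [matria()] or a `discovery_trace` from
#'   [iterate()].
#' @param g The [signed_network] the ranking was computed on (supplies the
#'   node set); optional for a `matria_ranking`, which carries its own.
#' @return A tibble with columns `node` and `rank`, one row per node.
#' @export
expanded_rank_vector <- function(r, g = NULL) {
  if (inherits(r, "matria_ranking")) {
    nodes <- if (is.null(g)) r$nodes else g$nodes
    rank <- rep(nrow(r$elements) + 1, length(nodes))
    names(rank) <- nodes
    for (i in seq_len(nrow(r$elements))) {
      rank[element_members(r$elements$element[[i]])] <- r$elements$position[i]
    }
  } else if (inherits(r, "discovery_trace")) {
    if (is.null(g)) rlang::abort("`g` is required to expand a discovery trace")
    nodes <- g$nodes
    rank <- rep(nrow(r$trace) + 1, length(nodes))
    names(rank) <- nodes
    rank[r$trace$node] <- r$trace$rank
  } else {
    rlang::abort("`r` must be a matria_ranking or a discovery_trace")
  }
  tibble::tibble(node = nodes, rank = unname(rank[nodes]))
}

as_rank_map <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (!all(c("node", "rank") %in% names(x))) {
      rlang::abort(sprintf("`%s` must have columns `node` and `rank`", arg))
    }
    stats::setNames(as.double(x$rank), as.character(x$node))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    rlang::abort(sprintf("`%s` must be a (node, rank) data frame or named vector", arg))
  }
}

#' Spearman rank correlation between two node rank vectors
#'
#' Standard Spearman correlation with average-rank tie handling, after
#' aligning the two vectors on their (identical) node key sets.
#'
#' @param u,v Rank vectors: `(node, rank)` data frames (e.g. from
#'   [expanded_rank_vector()]) or named numeric vectors.  Must cover the
#'   same nodes, at least 3.
#' @return A correlation in \[-1, 1\].
#' @export
spearman <- function(u, v) {
  um <- as_rank_map(u, "u")
  vm <- as_rank_map(v, "v")
  if (!setequal(names(um), names(vm))) {
    rlang::abort("`u` and `v` cover different node sets")
  }
  if (length(um) < 3) rlang::abort("need at least 3 nodes")
  keys <- sort(names(um))
  stats::cor(um[keys], vm[keys], method = "spearman")
}

#' Pairwise Spearman matrix across rank vectors
#'
#' @param vectors A named list of rank vectors (each a `(node, rank)` data
#'   frame or named numeric vector over the same node set).
#' @return A symmetric matrix of Spearman correlations.
#' @export
spearman_matrix <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 2)
  nm <- names(vectors)
  if (is.null(nm) || any(!nzchar(nm))) {
    rlang::abort("`vectors` must be a named list")
  }
  m <- diag(1, length(vectors))
  dimnames(m) <- list(nm, nm)
  for (i in seq_along(vectors)) {
    for (j in seq_along(vectors)) {
      if (j > i) m[i, j] <- m[j, i] <- spearman(vectors[[i]], vectors[[j]])
    }
  }
  m
}
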