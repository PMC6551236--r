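#' @useDynLib unicent, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default label budget of the signed path search
#'
#' The search behind [mod_dijkstra()] keeps, per (node, sign), a set of
#' dominance-pruned (magnitude, visited-set) labels.  An unlimited set
#' (`width = 0`) makes the search exact over simple paths but exponential in
#' the worst case; a finite budget keeps the strongest `width` labels and
#' bounds the work.  The package default can be changed for one session via
#' `options(unicent.label_width = ...)`.
#'
#' @return The current default width (an integer; 0 means unlimited).
#' @export
label_width <- function() {
  w <- getOption("unicent.label_width", 8L)
  check_width(w)
}

check_width <- function(width) {
  if (is.infinite(width)) width <- 0L
  width <- as.integer(width)
  if (is.na(width) || width < 0) {
    rlang::abort("`width` must be a non-negative integer (0 = unlimited)")
  }
  width
}

new_path_labels <- function(nodes, G, L, wpos, wneg) {
  dimnames(G) <- dimnames(L) <- list(nodes, nodes)
  structure(list(nodes = nodes, G = G, L = L,
                 witness_pos = wpos, witness_neg = wneg),
            class = "path_labels")
}

pair_index <- function(n, i, j) {
  # index of unordered pair (i < j) in the row-major upper triangle
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' @export
print.path_labels <- function(x, ...) {
  cat(sprintf("<path_labels over %d nodes>\n", length(x$nodes)))
  invisible(x)
}

#' Tidy view of path labels
#'
#' @param x A `path_labels` object from [all_pairs_labels()].
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `from`, `to`,
#'   `gain` (maximum positive path product), `loss` (most negative path
#'   product), and list-columns `witness_gain` / `witness_loss` holding the
#'   realizing node sequences (`NULL` when the value is 0).
#' @method tidy path_labels
#' @export
tidy.path_labels <- function(x, ...) {
  n <- length(x$nodes)
  if (n < 2) {
    return(tibble::tibble(from = character(), to = character(),
                          gain = double(), loss = double(),
                          witness_gain = list(), witness_loss = list()))
  }
  pairs <- which(upper.tri(x$G), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  k <- pair_index(n, pairs[, 1], pairs[, 2])
  tibble::tibble(
    from = x$nodes[pairs[, 1]],
    to = x$nodes[pairs[, 2]],
    gain = x$G[pairs],
    loss = x$L[pairs],
    witness_gain = x$witness_pos[k],
    witness_loss = x$witness_neg[k])
}

#' Single-source maximum-magnitude signed path products
#'
#' A modified Dijkstra search over edge-weight products: for the given
#' source and every other node it returns the maximum product over simple
#' paths with positive product (`gain`) and the most negative product over
#' simple paths with negative product (`loss`), each 0 when no such path
#' exists, together with one witness path per nonzero value.  Because all
#' weight magnitudes are at most 1, extending a path never increases the
#' product magnitude, which is what makes a best-first search valid; the
#' implementation keeps a dominance-pruned set of (magnitude, visited-set)
#' labels per node and sign so the result is exact over simple paths even
#' when sign alternation matters.
#'
#' @param g A [signed_network].
#' @param source A node id in `g`.
#' @param width Per-(node, sign) label budget of the search.  `0` keeps every
#'   non-dominated label, which is exact over simple paths but exponential in
#'   the worst case; the default (see [label_width()]) keeps the strongest
#'   `width` labels per node and sign, the bounded label-correcting search
#'   used throughout the pipeline.
#' @return A tibble with columns `source`, `target`, `gain`, `loss` and
#'   list-columns `witness_gain`, `witness_loss` (node-id sequences).
#' @examples
#' g <- signed_network(tibble::tibble(
#'   from = c("a", "b"), to = c("b", "c"), weight = c(0.8, -0.5)
#' ))
#' mod_dijkstra(g, "a")
#' @export
mod_dijkstra <- function(g, source, width = label_width()) {
  stopifnot(inherits(g, "signed_network"))
  if (!source %in% g$nodes) {
    rlang::abort(sprintf("source node '%s' is not in the network", source))
  }
  ix <- network_index(g)
  s <- match(source, g$nodes)
  res <- .cpp_single_source(ix$n, ix$ei, ix$ej, ix$w, s, check_width(width))
  targets <- setdiff(seq_len(ix$n), s)
  to_ids <- function(p) if (is.null(p)) NULL else g$nodes[p]
  tibble::tibble(
    source = source,
    target = g$nodes[targets],
    gain = res$gain[targets],
    loss = res$loss[targets],
    witness_gain = lapply(res$witness_pos[targets], to_ids),
    witness_loss = lapply(res$witness_neg[targets], to_ids))
}

#' All-pairs maximum-magnitude signed path products
#'
#' Runs the modified Dijkstra search from every source and assembles the
#' symmetric gain/loss matrices together with one canonical witness path
#' per unordered pair and sign (oriented from the lexicographically smaller
#' endpoint; ties among co-optimal paths broken by fewer edges, then
#' lexicographically smallest node sequence).
#'
#' @param g A [signed_network].
#' @inheritParams mod_dijkstra
#' @return A `path_labels` object: `nodes`, matrices `G` (gains, values in
#'   \[0,1\]) and `L` (losses, values in \[-1,0\]), and per-pair witness
#'   lists.  Use [tidy()] for a tabular view.
#' @export
all_pairs_labels <- function(g, width = label_width()) {
  stopifnot(inherits(g, "signed_network"))
  ix <- network_index(g)
  if (ix$n == 0) {
    return(new_path_labels(character(), matrix(0, 0, 0), matrix(0, 0, 0),
                           list(), list()))
  }
  res <- .cpp_all_pairs(ix$n, ix$ei, ix$ej, ix$w, check_width(width))
  to_ids <- function(p) if (is.null(p)) NULL else g$nodes[p]
  new_path_labels(g$nodes, res$G, res$L,
                  lapply(res$witness_pos, to_ids),
                  lapply(res$witness_neg, to_ids))
}

#' Exhaustive-enumeration oracle for signed path products
#'
#' Enumerates every simple path between every node pair and takes the
#' maximum positive and most negative product directly from the definition.
#' Exponential in the node count, so it refuses networks with more than
#' `max_nodes` nodes; it exists to verify [all_pairs_labels()] on small
#' inputs, with the same witness tie-breaking (fewer edges, then
#' lexicographically smallest sequence, magnitudes compared at 1e-9
#' relative tolerance).
#'
#' @param g A [signed_network] with at most `max_nodes` nodes.
#' @param max_nodes Refusal threshold, default 10.
#' @return A `path_labels` object, same shape as [all_pairs_labels()].
#' @export
brute_force_labels <- function(g, max_nodes = 10) {
  stopifnot(inherits(g, "signed_network"))
  n <- length(g$nodes)
  if (n > max_nodes) {
    rlang::abort(sprintf(
      "brute_force_labels refuses networks with > %d nodes (got %d)",
      max_nodes, n))
  }
  G <- matrix(0, n, n)
  L <- matrix(0, n, n)
  npairs <- n * (n - 1) / 2
  wpos <- vector("list", max(npairs, 0))
  wneg <- vector("list", max(npairs, 0))

  adj <- vector("list", n)
  ix <- network_index(g)
  for (k in seq_along(ix$ei)) {
    a <- ix$ei[k]; b <- ix$ej[k]; w <- ix$w[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }

  better <- function(mag, path, best_mag, best_path) {
    # TRUE if (mag, path) should replace (best_mag, best_path)
    if (is.null(best_path)) return(TRUE)
    tol <- 1e-9 * max(1, mag, best_mag)
    if (mag > best_mag + tol) return(TRUE)
    if (mag < best_mag - tol) return(FALSE)
    if (length(path) != length(best_path)) return(length(path) < length(best_path))
    # lexicographic on the node index sequence
    cmp <- which(path != best_path)
    length(cmp) > 0 && path[cmp[1]] < best_path[cmp[1]]
  }

  for (s in seq_len(n)) {
    best_mag <- matrix(0, n, 2)       # columns: positive, negative
    best_path <- vector("list", n * 2)
    visited <- logical(n)
    dfs <- function(u, prod, path) {
      nbrs <- adj[[u]]
      if (is.null(nbrs)) return()
      for (r in seq_len(nrow(nbrs))) {
        v <- nbrs[r, 1]
        if (visited[v]) next
        p2 <- prod * nbrs[r, 2]
        path2 <- c(path, v)
        col <- if (p2 > 0) 1L else 2L
        slot <- (v - 1L) * 2L + col
        if (better(abs(p2), path2, best_mag[v, col], best_path[[slot]])) {
          best_mag[v, col] <<- abs(p2)
          best_path[[slot]] <<- path2
        }
        visited[v] <<- TRUE
        dfs(v, p2, path2)
        visited[v] <<- FALSE
      }
    }
    visited[s] <- TRUE
    dfs(s, 1, s)
    for (t in seq_len(n)) {
      if (t <= s) next
      k <- pair_index(n, s, t)
      if (best_mag[t, 1] > 0) {
        G[s, t] <- G[t, s] <- best_mag[t, 1]
        wpos[[k]] <- g$nodes[best_path[[(t - 1L) * 2L + 1L]]]
      }
      if (best_mag[t, 2] > 0) {
        L[s, t] <- L[t, s] <- -best_mag[t, 2]
        wneg[[k]] <- g$nodes[best_path[[(t - 1L) * 2L + 2L]]]
      }
    }
  }
  new_path_labels(g$nodes, G, L, wpos, wneg)
}
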