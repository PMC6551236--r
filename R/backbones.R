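# Signed path-based centrality backbones.
#
# Each backbone maps a signed network to one non-negative score per node.
# All three build on the gain/loss socio-economic reading of a signed
# network: a pair of nodes exchanges a "gain" along its best positive path
# and a "loss" along its best negative path.

backbone_registry <- new.env(parent = emptyenv())

#' Signed closeness centrality
#'
#' `value(i) = | sum over j != i of G(i,j) + L(i,j) |`, where `G` is the
#' maximum positive and `L` the most negative edge-weight product over
#' simple paths between `i` and `j`.  This is closeness over maximum-
#' magnitude product paths, with "path length" read as the pair's net gain.
#'
#' @param g A [signed_network].
#' @param labels Path labels for `g` from [all_pairs_labels()]; computed on
#'   demand when `NULL`.
#' @return A tibble with columns `node` and `value`, one row per node,
#'   carrying the backbone name in attribute `backbone`.
#' @export
closeness_centrality <- function(g, labels = NULL) {
  stopifnot(inherits(g, "signed_network"))
  if (is.null(labels)) labels <- all_pairs_labels(g)
  check_labels_match(g, labels)
  vals <- abs(rowSums(labels$G + labels$L))
  if (!length(g$nodes)) vals <- double()
  centrality_vector(g$nodes, unname(vals), "CLO")
}

#' Signed degree centrality
#'
#' `value(i) = | sum over j != i of W(i,j) |` over the edges incident to
#' `i`: cooperative and antagonistic ties cancel, so a node balanced
#' between friends and enemies scores low.
#'
#' @inheritParams closeness_centrality
#' @return A tibble with columns `node` and `value`.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "signed_network"))
  sums <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    a <- tapply(g$edges$weight, g$edges$from, sum)
    b <- tapply(g$edges$weight, g$edges$to, sum)
    sums[names(a)] <- sums[names(a)] + a
    sums[names(b)] <- sums[names(b)] + b
  }
  centrality_vector(g$nodes, unname(abs(sums)), "DEG")
}

#' Signed betweenness centrality
#'
#' For every unordered pair `{j, k}` the recorded maximum positive witness
#' path contributes 1 to every interior node on it, and likewise the
#' negative witness; `value(i)` sums both contributions over all pairs.
#' One deterministic witness per (pair, sign) is used (co-optimal paths are
#' tie-broken by fewer edges, then lexicographically), so each pair
#' contributes 0 or 1 per sign.  Endpoints do not count as interior.
#'
#' @inheritParams closeness_centrality
#' @return A tibble with columns `node` and `value` (non-negative integers).
#' @export
betweenness_centrality <- function(g, labels = NULL) {
  stopifnot(inherits(g, "signed_network"))
  if (is.null(labels)) labels <- all_pairs_labels(g)
  check_labels_match(g, labels)
  if (is.null(labels$witness_pos) || is.null(labels$witness_neg)) {
    rlang::abort("`labels` carries no witness paths")
  }
  counts <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  tally <- function(witnesses) {
    for (p in witnesses) {
      if (!is.null(p) && length(p) > 2) {
        interior <- p[-c(1, length(p))]
        counts[interior] <<- counts[interior] + 1
      }
    }
  }
  tally(labels$witness_pos)
  tally(labels$witness_neg)
  centrality_vector(g$nodes, unname(counts), "BET")
}

centrality_vector <- function(nodes, values, backbone) {
  out <- tibble::tibble(node = nodes, value = values)
  attr(out, "backbone") <- backbone
  out
}

check_labels_match <- function(g, labels) {
  if (!inherits(labels, "path_labels") ||
      !identical(labels$nodes, g$nodes)) {
    rlang::abort("`labels` were not computed on this network (node sets differ)")
  }
  invisible(TRUE)
}

#' Register a centrality backbone
#'
#' The iterative loop and the consensus stage work with any number of
#' centrality algorithms.  A backbone is a function taking a
#' [signed_network] and returning a tibble with columns `node` (every node
#' of the network) and `value` (non-negative).  `"BET"`, `"CLO"` and
#' `"DEG"` are pre-registered; further algorithms (e.g. eigenvector-style
#' signed centralities) can be plugged in under new names.
#'
#' @param name Backbone label, e.g. `"PN"`.  Must be unused.
#' @param fn The backbone function.
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (exists(name, envir = backbone_registry, inherits = FALSE)) {
    rlang::abort(sprintf("backbone '%s' is already registered", name))
  }
  assign(name, fn, envir = backbone_registry)
  invisible(name)
}

#' List registered backbone names
#' @return Character vector of registered backbone labels.
#' @export
list_backbones <- function() sort(ls(backbone_registry))

get_backbone <- function(name) {
  if (!exists(name, envir = backbone_registry, inherits = FALSE)) {
    rlang::abort(sprintf(
      "unknown backbone '%s' (registered: %s)", name,
      paste(list_backbones(), collapse = ", ")))
  }
  get(name, envir = backbone_registry, inherits = FALSE)
}

register_builtin_backbones <- function() {
  if (!exists("DEG", envir = backbone_registry, inherits = FALSE)) {
    assign("BET", function(g) betweenness_centrality(g), envir = backbone_registry)
    assign("CLO", function(g) closeness_centrality(g), envir = backbone_registry)
    assign("DEG", function(g) degree_centrality(g), envir = backbone_registry)
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backbones()
}
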