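# Consensus stage: reconcile the discovery traces of several iterative
# backbones into one ranked set of nodes and supernodes.

#' Construct a supernode
#'
#' A supernode is a centrality "toss-up": a set of neighbouring
#' disagreement nodes in which every backbone's pick appears exactly once.
#' It is stored as an ordered list of positions; each position has a
#' non-empty set of base nodes and the set of backbone labels it covers.
#' Positions jointly cover every backbone exactly once.  After merging, a
#' node discovered by two backbones may legitimately sit in two positions.
#'
#' @param positions A list; each element a list with character vectors
#'   `nodes` and `backbones`.
#' @return An object of class `supernode`.
#' @export
supernode <- function(positions) {
  stopifnot(is.list(positions), length(positions) >= 1)
  positions <- lapply(positions, function(p) {
    list(nodes = sort(unique(as.character(p$nodes))),
         backbones = sort(unique(as.character(p$backbones))))
  })
  covered <- unlist(lapply(positions, `[[`, "backbones"))
  if (anyDuplicated(covered)) {
    rlang::abort("supernode positions cover a backbone more than once")
  }
  positions <- unname(positions[order(vapply(positions, function(p) p$nodes[1],
                                             character(1)))])
  structure(list(positions = positions), class = "supernode")
}

supernode_members <- function(sn) {
  sort(unique(unlist(lapply(sn$positions, `[[`, "nodes"))))
}

supernode_backbones <- function(sn) {
  sort(unlist(lapply(sn$positions, `[[`, "backbones")))
}

format_supernode <- function(sn) {
  paste(vapply(sn$positions,
               function(p) paste(p$nodes, collapse = ","), character(1)),
        collapse = "|")
}

#' @export
print.supernode <- function(x, ...) {
  cat(sprintf("<supernode [%s]>\n", format_supernode(x)))
  invisible(x)
}

#' @export
format.supernode <- function(x, ...) format_supernode(x)

trace_list_check <- function(traces) {
  if (length(traces) < 2) rlang::abort("need at least 2 discovery traces")
  nm <- vapply(traces, `[[`, character(1), "backbone")
  if (anyDuplicated(nm)) rlang::abort("duplicate backbone names among traces")
  stats::setNames(traces, nm)
}

#' Universal agreements among discovery traces
#'
#' The nodes discovered by every iterative backbone: the intersection of
#' the traces' discovered sets.
#'
#' @param traces A list of `discovery_trace` objects (>= 2, distinct
#'   backbones).
#' @return Character vector of node ids (sorted).
#' @export
universal_agreements <- function(traces) {
  traces <- trace_list_check(traces)
  sets <- lapply(traces, function(tr) tr$trace$node)
  sort(Reduce(intersect, sets))
}

# label each disagreement node with the set of backbones that found it
disagreement_labels <- function(traces, agreements) {
  traces <- trace_list_check(traces)
  all_found <- sort(unique(unlist(lapply(traces, function(tr) tr$trace$node))))
  D <- setdiff(all_found, agreements)
  found_by <- lapply(D, function(nd) {
    names(traces)[vapply(traces, function(tr) nd %in% tr$trace$node, logical(1))]
  })
  stats::setNames(found_by, D)
}

subset_connected <- function(g, nodes) {
  k <- length(nodes)
  if (k <= 1) return(TRUE)
  e <- g$edges
  hit <- e$from %in% nodes & e$to %in% nodes
  if (!any(hit)) return(FALSE)
  reach <- nodes[1]
  ef <- e$from[hit]; et <- e$to[hit]
  repeat {
    more <- unique(c(et[ef %in% reach], ef[et %in% reach]))
    more <- setdiff(more, reach)
    if (!length(more)) break
    reach <- c(reach, more)
  }
  length(reach) == k
}

#' Detect candidate supernodes among disagreement nodes
#'
#' Over the disagreement set (nodes found by some but not all backbones),
#' returns every connected subset (connectivity judged on the original
#' network) whose members' discovering-backbone sets are pairwise disjoint
#' and together cover every backbone exactly once.  Enumeration is in two
#' passes mirroring how such toss-ups arise: first size-k subsets in which
#' every member was found by a single backbone ("triads" for k = 3), then
#' smaller subsets down to size 2 ("adjacencies"), each pass in
#' lexicographic node order.  Candidates may overlap; [merge_supernodes()]
#' reconciles them.
#'
#' @param g The original [signed_network].
#' @param traces A list of `discovery_trace` objects.
#' @param agreements Universal agreements, from [universal_agreements()].
#' @return A list of [supernode] objects (possibly empty).
#' @export
find_supernodes <- function(g, traces, agreements) {
  traces <- trace_list_check(traces)
  backbones <- sort(names(traces))
  k <- length(backbones)
  labels <- disagreement_labels(traces, agreements)
  D <- names(labels)
  out <- list()
  if (length(D) < 2) return(out)
  for (size in seq(k, 2)) {
    if (size > length(D)) next
    combos <- utils::combn(D, size, simplify = FALSE)
    for (nodes in combos) {
      labs <- labels[nodes]
      if (size == k && any(lengths(labs) != 1)) next
      covered <- unlist(labs)
      if (length(covered) != k || anyDuplicated(covered)) next
      if (!setequal(covered, backbones)) next
      if (!subset_connected(g, nodes)) next
      out <- c(out, list(supernode(
        lapply(nodes, function(nd) list(nodes = nd, backbones = labels[[nd]])))))
    }
  }
  out
}

merge_pair <- function(a, b, backbones) {
  # union the position node-sets backbone-wise, then coalesce backbones
  # whose node-sets coincide into one joint position
  nodes_for <- function(sn, bb) {
    for (p in sn$positions) if (bb %in% p$backbones) return(p$nodes)
    character()
  }
  per_bb <- lapply(backbones, function(bb)
    sort(unique(c(nodes_for(a, bb), nodes_for(b, bb)))))
  names(per_bb) <- backbones
  keysets <- vapply(per_bb, paste, character(1), collapse = "\r")
  groups <- split(backbones, keysets)
  supernode(lapply(groups, function(bbs)
    list(nodes = per_bb[[bbs[1]]], backbones = bbs)))
}

#' Merge overlapping supernodes
#'
#' Two supernodes sharing a base node are repeatedly merged until all are
#' pairwise disjoint: the shared node stays a toss-up option, and a node
#' found by several backbones joins each position matching one of its
#' backbones.  This single rule reproduces the triad+adjacency merge
#' (`[x,w,z] + [x,y] -> [x,{y,w},{y,z}]`), triads sharing two nodes
#' (`-> [x,y,{w,z}]`), triads sharing one (`-> [x,{v,y},{w,z}]`),
#' adjacencies sharing one (`-> [x,{y,z}]`), and their compositions
#' (a merged supernode may merge again).  Merge order is deterministic:
#' supernodes sorted by lexicographically smallest member, first
#' overlapping pair first.
#'
#' @param supernodes A list of [supernode] objects from [find_supernodes()].
#' @return A list of pairwise-disjoint [supernode] objects.
#' @export
merge_supernodes <- function(supernodes) {
  if (length(supernodes) < 2) return(supernodes)
  backbones <- sort(unique(unlist(lapply(supernodes, supernode_backbones))))
  sns <- supernodes
  repeat {
    ord <- order(vapply(sns, function(s) supernode_members(s)[1], character(1)),
                 vapply(sns, format_supernode, character(1)))
    sns <- sns[ord]
    members <- lapply(sns, supernode_members)
    merged <- FALSE
    for (i in seq_along(sns)) {
      for (j in seq_along(sns)) {
        if (j <= i) next
        if (length(intersect(members[[i]], members[[j]]))) {
          m <- merge_pair(sns[[i]], sns[[j]], backbones)
          sns <- c(sns[-c(i, j)], list(m))
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # drop exact duplicates that enumeration may have produced
  sig <- vapply(sns, format_supernode, character(1))
  sns[!duplicated(sig)]
}

element_members <- function(el) {
  if (inherits(el, "supernode")) supernode_members(el) else el
}

rank_in_trace <- function(tr, node) {
  r <- tr$trace$rank[match(node, tr$trace$node)]
  if (is.na(r)) {
    rlang::abort(sprintf("node '%s' was not discovered by backbone %s",
                         node, tr$backbone))
  }
  r
}

score_element <- function(el, traces) {
  if (!inherits(el, "supernode")) {
    # universal agreement: mean rank over all backbones
    return(mean(vapply(traces, rank_in_trace, double(1), node = el)))
  }
  pos_scores <- vapply(el$positions, function(p) {
    per_bb <- vapply(p$backbones, function(bb) {
      tr <- traces[[bb]]
      ranks <- tr$trace$rank[match(p$nodes, tr$trace$node)]
      ranks <- ranks[!is.na(ranks)]
      if (!length(ranks)) {
        rlang::abort(sprintf(
          "no node of position {%s} was discovered by backbone %s",
          paste(p$nodes, collapse = ","), bb))
      }
      min(ranks)  # merged position: whichever node was discovered first
    }, double(1))
    mean(per_bb)
  }, double(1))
  mean(pos_scores)
}

#' Rank consensus elements
#'
#' Scores universal-agreement nodes by their mean rank over all backbones,
#' and supernodes by the mean over positions of each position's rank under
#' the backbone(s) that cover it (a position covered by two backbones
#' contributes the mean of its two ranks; a multi-node merged position uses
#' the rank of whichever member was discovered first).  Elements are sorted
#' ascending by score (lower = more central), ties broken by the
#' lexicographically smallest member.
#'
#' @param elements A list whose entries are node ids (character scalars) or
#'   [supernode] objects.
#' @param traces A list of `discovery_trace` objects covering the elements.
#' @return A tibble with columns `position`, `rank_score`, `type`
#'   (`"node"` or `"supernode"`), `members` (formatted label) and `element`
#'   (list-column with the raw element).
#' @export
rank_elements <- function(elements, traces) {
  traces <- trace_list_check(traces)
  if (!length(elements)) {
    return(tibble::tibble(position = integer(), rank_score = double(),
                          type = character(), members = character(),
                          element = list()))
  }
  out <- tibble::tibble(
    rank_score = purrr::map_dbl(elements, score_element, traces = traces),
    first_member = purrr::map_chr(elements, ~ element_members(.x)[1]),
    type = ifelse(purrr::map_lgl(elements, inherits, "supernode"),
                  "supernode", "node"),
    members = purrr::map_chr(elements, function(el) {
      if (inherits(el, "supernode")) format_supernode(el) else el
    }),
    element = elements)
  out <- dplyr::arrange(out, .data$rank_score, .data$first_member)
  dplyr::mutate(dplyr::select(out, -"first_member"),
                position = dplyr::row_number(), .before = 1)
}

#' Unified consensus centrality
#'
#' The full pipeline: run the iterative loop for every requested backbone,
#' extract universal agreements, detect and merge supernodes among the
#' disagreements, flag the leftover disagreement nodes as unresolvable, and
#' rank the resulting elements.  The four classes -- agreed important,
#' supernode members, unresolvable, agreed unimportant (nodes in no trace)
#' -- partition the node set.
#'
#' @param g A [signed_network].
#' @param backbones Character vector of >= 2 registered backbone labels.
#' @param zero_tol Zero threshold passed to [iterate()].
#' @return A `matria_ranking`: list with `elements` (the [rank_elements()]
#'   tibble), `agreed`, `unresolvable`, `unimportant` (character vectors),
#'   `supernodes` (list), `traces` (named list of `discovery_trace`),
#'   `backbones`, and `nodes`.  See [tidy.matria_ranking()],
#'   [glance.matria_ranking()], [expanded_rank_vector()].
#' @examples
#' g <- generate_network(n_nodes = 30, topology = "modular", n_modules = 3,
#'                       seed = 42)
#' r <- matria(g)
#' tidy(r)
#' glance(r)
#' @export
matria <- function(g, backbones = c("BET", "CLO", "DEG"), zero_tol = 1e-9) {
  stopifnot(inherits(g, "signed_network"))
  if (length(backbones) < 2) rlang::abort("need at least 2 backbones")
  traces <- stats::setNames(
    lapply(backbones, function(bb) iterate(g, bb, zero_tol = zero_tol)),
    backbones)
  agreed <- universal_agreements(traces)
  sns <- merge_supernodes(find_supernodes(g, traces, agreed))
  all_found <- sort(unique(unlist(lapply(traces, function(tr) tr$trace$node))))
  D <- setdiff(all_found, agreed)
  sn_members <- sort(unique(unlist(lapply(sns, supernode_members))))
  unresolvable <- setdiff(D, sn_members)
  unimportant <- setdiff(g$nodes, all_found)
  elements <- c(as.list(agreed), sns)
  ranked <- rank_elements(elements, traces)
  structure(list(elements = ranked, agreed = agreed,
                 supernodes = sns, unresolvable = unresolvable,
                 unimportant = unimportant, traces = traces,
                 backbones = backbones, nodes = g$nodes),
            class = "matria_ranking")
}

#' @export
print.matria_ranking <- function(x, ...) {
  cat(sprintf(paste0(
    "<matria_ranking: %d nodes -> %d elements ",
    "(%d agreed, %d supernodes; %d unresolvable, %d unimportant)>\n"),
    length(x$nodes), nrow(x$elements), length(x$agreed),
    length(x$supernodes), length(x$unresolvable), length(x$unimportant)))
  if (nrow(x$elements)) print(utils::head(x$elements[1:4], 10))
  invisible(x)
}
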