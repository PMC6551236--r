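#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a unified consensus ranking
#'
#' @param x A `matria_ranking` from [matria()].
#' @param ... Unused.
#' @return A tibble with one row per ranked element: `position`,
#'   `rank_score`, `type` (`"node"` / `"supernode"`), `members` (supernode
#'   positions pipe-separated, members within a position comma-separated).
#' @method tidy matria_ranking
#' @export
tidy.matria_ranking <- function(x, ...) {
  x$elements[c("position", "rank_score", "type", "members")]
}

#' One-row summary of a consensus run
#'
#' Coverage accounting in the four-way partition: agreed important,
#' supernode members, unresolvable, agreed unimportant, plus the derived
#' percentages (universal agreement = agreed important + unimportant;
#' resolvable = everything except unresolvable).
#'
#' @param x A `matria_ranking`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance matria_ranking
#' @export
glance.matria_ranking <- function(x, ...) {
  n <- length(x$nodes)
  n_sn_members <- length(unique(unlist(lapply(x$supernodes, supernode_members))))
  tibble::tibble(
    n_nodes = n,
    n_elements = nrow(x$elements),
    agreed_important = length(x$agreed),
    supernodes = length(x$supernodes),
    supernode_members = n_sn_members,
    unresolvable = length(x$unresolvable),
    agreed_unimportant = length(x$unimportant),
    pct_universal_agreement =
      100 * (length(x$agreed) + length(x$unimportant)) / max(n, 1),
    pct_resolvable = 100 * (n - length(x$unresolvable)) / max(n, 1))
}

#' Write a unified ranking as TSV
#'
#' Columns `position`, `rank_score`, `element_type`, `members`; supernode
#' members are serialized as pipe-separated position groups with
#' comma-separated nodes.
#' @param x A `matria_ranking`.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "matria_ranking"))
  df <- tidy(x)
  names(df)[names(df) == "type"] <- "element_type"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Full partition report as JSON
#'
#' Writes the four-way node partition (agreed important, supernodes with
#' their positions, unresolvable, agreed unimportant) plus the per-backbone
#' discovery traces.
#' @param x A `matria_ranking`.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_partition_json <- function(x, path) {
  stopifnot(inherits(x, "matria_ranking"))
  report <- list(
    n_nodes = length(x$nodes),
    agreed_important = as.list(x$agreed),
    supernodes = lapply(x$supernodes, function(sn)
      lapply(sn$positions, function(p)
        list(nodes = as.list(p$nodes), backbones = as.list(p$backbones)))),
    unresolvable = as.list(x$unresolvable),
    agreed_unimportant = as.list(x$unimportant),
    traces = lapply(x$traces, function(tr)
      list(backbone = tr$backbone, nodes = as.list(tr$trace$node))))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(x)
}
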