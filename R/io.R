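#' Read a signed network from a tab-separated edge list
#'
#' The edge-list dialect is: one edge per line as
#' `source<TAB>target<TAB>weight`; lines starting with `#` are comments;
#' blank lines are ignored; a line holding a single field declares an
#' isolated node.  The graph is undirected, so `a b w` and `b a w` are the
#' same edge (both present with equal weight is tolerated, with conflicting
#' weights it is an error).
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default tab.
#' @return A [signed_network].
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  from <- character(); to <- character(); weight <- double()
  isolated <- character()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    fields <- strsplit(raw, delimiter, fixed = TRUE)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) == 1L) {
      isolated <- c(isolated, trimws(fields[1]))
      next
    }
    if (length(fields) != 3L) {
      rlang::abort(sprintf(
        "line %d: expected 3 fields (source, target, weight) or 1 (isolated node), got %d",
        ln, length(fields)))
    }
    w <- suppressWarnings(as.double(fields[3]))
    if (is.na(w)) {
      rlang::abort(sprintf("line %d: weight '%s' is not a number", ln, fields[3]))
    }
    from <- c(from, trimws(fields[1]))
    to <- c(to, trimws(fields[2]))
    weight <- c(weight, w)
  }
  signed_network(tibble::tibble(from = from, to = to, weight = weight),
                 nodes = unique(c(from, to, isolated)))
}

#' Write a signed network as a tab-separated edge list
#'
#' Inverse of [read_edge_list()]: reading the written file reproduces the
#' network exactly (node set, edge set, full-precision weights).  Isolated
#' nodes are written as single-field lines.
#'
#' @param g A [signed_network].
#' @param path Output file path.
#' @return `g`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "signed_network"))
  lines <- c("# signed network edge list: source\ttarget\tweight")
  if (nrow(g$edges)) {
    lines <- c(lines, sprintf("%s\t%s\t%s", g$edges$from, g$edges$to,
                              format(g$edges$weight, digits = 17,
                                     scientific = FALSE, trim = TRUE)))
  }
  isolated <- setdiff(g$nodes, unique(c(g$edges$from, g$edges$to)))
  lines <- c(lines, isolated)
  tryCatch(writeLines(lines, path),
           error = function(e) rlang::abort(
             sprintf("cannot write edge list to '%s': %s", path, conditionMessage(e))))
  invisible(g)
}
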