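# Seeded generators for signed weighted test networks.
#
# The modular topology emulates thresholded microbial co-occurrence
# networks: a few tightly positively-connected modules, each organised
# around a planted hub, with sparse mixed-sign ties between modules
# (co-exclusion shows up as negative inter-module edges).  The scale-free
# topology emulates co-expression-like networks via preferential
# attachment with sampled signed weights.

#' Generate a signed test network
#'
#' @param n_nodes Number of nodes.  Default 126, the size of a typical
#'   bacterial co-occurrence test network.
#' @param topology `"modular"` (planted-partition with one hub per module),
#'   `"scale_free"` (preferential attachment), `"path"` or `"star"`
#'   (deterministic skeletons for small tests).
#' @param n_modules Number of modules (modular only), default 5.
#' @param p_in Intra-module edge probability among non-hub pairs, default
#'   0.35.  The planted hub connects to every member of its module.
#' @param p_out Inter-module edge probability, default 0.03.
#' @param w_pos,w_neg Magnitude intervals (within (0, 1\]) for positive and
#'   negative weights, default \[0.3, 0.95\] -- the magnitudes that survive
#'   a typical correlation threshold.
#' @param neg_frac_in Fraction of negative intra-module edges (default 0.1);
#'   also the global negative fraction for non-modular topologies.
#' @param neg_frac_out Fraction of negative inter-module edges (default
#'   0.5: between-module associations are as often exclusions as
#'   co-occurrences).
#' @param seed Integer seed; identical arguments and seed give an
#'   identical network.
#' @return A [signed_network].  Node ids are zero-padded (`"n001"`, ...) so
#'   lexicographic and numeric order coincide.
#' @examples
#' g <- generate_network(n_nodes = 20, topology = "modular", n_modules = 2,
#'                       seed = 7)
#' g
#' @export
generate_network <- function(n_nodes = 126,
                             topology = c("modular", "scale_free", "path", "star"),
                             n_modules = 5, p_in = 0.35, p_out = 0.03,
                             w_pos = c(0.3, 0.95), w_neg = c(0.3, 0.95),
                             neg_frac_in = 0.1, neg_frac_out = 0.5,
                             seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_nodes >= 1, n_modules >= 1)
  for (p in c(p_in, p_out, neg_frac_in, neg_frac_out)) {
    if (p < 0 || p > 1) rlang::abort("probabilities and fractions must lie in [0, 1]")
  }
  for (rg in list(w_pos, w_neg)) {
    if (length(rg) != 2 || rg[1] <= 0 || rg[2] > 1 || rg[1] > rg[2]) {
      rlang::abort("weight magnitude ranges must be intervals within (0, 1]")
    }
  }
  nodes <- sprintf("n%0*d", max(3, nchar(n_nodes)), seq_len(n_nodes))
  withr::local_seed(as.integer(seed))

  draw_w <- function(k, neg_frac) {
    if (k == 0) return(double())
    neg <- stats::runif(k) < neg_frac
    mag <- ifelse(neg,
                  stats::runif(k, w_neg[1], w_neg[2]),
                  stats::runif(k, w_pos[1], w_pos[2]))
    ifelse(neg, -mag, mag)
  }

  edges <- switch(topology,
    modular = {
      module <- rep(seq_len(n_modules), length.out = n_nodes)
      module <- sort(module)
      hubs <- vapply(seq_len(n_modules), function(m) which(module == m)[1],
                     integer(1))
      pairs <- utils::combn(n_nodes, 2)
      i <- pairs[1, ]; j <- pairs[2, ]
      same <- module[i] == module[j]
      hub_pair <- same & (i %in% hubs | j %in% hubs)
      u <- stats::runif(length(i))
      keep <- ifelse(hub_pair, TRUE, ifelse(same, u < p_in, u < p_out))
      i <- i[keep]; j <- j[keep]; same <- same[keep]; hub_pair <- hub_pair[keep]
      w <- draw_w(length(i), neg_frac_in)
      # inter-module edges re-signed at their own rate; hub spokes stay positive
      inter <- !same
      w[inter] <- draw_w(sum(inter), neg_frac_out)
      w[hub_pair] <- abs(w[hub_pair])
      tibble::tibble(from = nodes[i], to = nodes[j], weight = w)
    },
    scale_free = {
      sk <- igraph::sample_pa(n_nodes, power = 1, m = 2, directed = FALSE)
      el <- igraph::as_edgelist(sk, names = FALSE)
      w <- draw_w(nrow(el), neg_frac_in)
      tibble::tibble(from = nodes[el[, 1]], to = nodes[el[, 2]], weight = w)
    },
    path = {
      if (n_nodes < 2) tibble::tibble(from = character(), to = character(),
                                      weight = double())
      else tibble::tibble(from = nodes[-n_nodes], to = nodes[-1],
                          weight = draw_w(n_nodes - 1, neg_frac_in))
    },
    star = {
      if (n_nodes < 2) tibble::tibble(from = character(), to = character(),
                                      weight = double())
      else tibble::tibble(from = nodes[1], to = nodes[-1],
                          weight = draw_w(n_nodes - 1, neg_frac_in))
    })
  # duplicate edges cannot arise by construction; zero weights cannot either
  signed_network(edges, nodes = nodes)
}

#' Hand-curated fixture networks with annotated expected outcomes
#'
#' Small signed networks whose consensus behaviour is known and frozen:
#'
#' * `"triad_tossup"`: a 10-node two-module network in which the three
#'   backbones disagree on exactly three mutually connected nodes -- the
#'   iterative loop run per backbone discovers `n007` only under
#'   betweenness, `n009` only under closeness and `n004` only under degree
#'   -- so the consensus forms exactly one three-position supernode.
#' * `"adjacency_tossup"`: a 10-node two-module network where `n010` is
#'   found only by betweenness and its neighbour `n008` by both closeness
#'   and degree: one two-position supernode.
#' * `"merge_chain"`: a symbolic re-creation of the overlapping
#'   triad-plus-adjacencies topology behind the worked merge chain; its
#'   annotation carries the candidate supernodes and the expected final
#'   merged supernode with a multi-node first position.
#'
#' Each network carries an `expected` attribute: a list describing the
#' expected discovery/supernode structure, verified in the package tests by
#' an independent simulation of the iterative loop (for the first two) and
#' by the published merge rules (for the chain).
#'
#' @param name One of `"triad_tossup"`, `"adjacency_tossup"`,
#'   `"merge_chain"`.
#' @return A [signed_network] with attribute `expected`.
#' @export
fixture_network <- function(name) {
  catalogue <- c("triad_tossup", "adjacency_tossup", "merge_chain")
  if (!name %in% catalogue) {
    rlang::abort(sprintf("unknown fixture '%s' (catalogue: %s)", name,
                         paste(catalogue, collapse = ", ")))
  }
  if (name == "triad_tossup") {
    g <- signed_network(tibble::tibble(
      from = c("n001", "n001", "n001", "n001", "n002", "n003", "n004",
               "n006", "n006", "n006", "n006", "n007", "n007"),
      to = c("n002", "n003", "n004", "n005", "n005", "n006", "n009",
             "n007", "n008", "n009", "n010", "n008", "n009"),
      weight = c(0.65330781391821802, 0.51440741134574630,
                 0.87971060925628985, 0.54380982603179284,
                 0.54185381282586598, 0.93134404147276650,
                 -0.70758855103049423, 0.87829614551737900,
                 0.40626193695934487, 0.73530152733437704,
                 0.65692500716540958, 0.59740869024535637,
                 0.86801000697305408)))
    attr(g, "expected") <- list(
      kind = "triad",
      supernode_members = c("n004", "n007", "n009"),
      found_only_by = c(n004 = "DEG", n007 = "BET", n009 = "CLO"))
    return(g)
  }
  if (name == "adjacency_tossup") {
    g <- signed_network(tibble::tibble(
      from = c("n001", "n001", "n001", "n001", "n001", "n003", "n003",
               "n005", "n006", "n006", "n006", "n006", "n007", "n008",
               "n009"),
      to = c("n002", "n003", "n004", "n005", "n007", "n006", "n010",
             "n006", "n007", "n008", "n009", "n010", "n010", "n010",
             "n010"),
      weight = c(0.57091375647578380, 0.93953758404823007,
                 0.90315752044552933, 0.60383174646412940,
                 0.94746136064641173, 0.60541403224924573,
                 0.91493204501457503, 0.71157742089126252,
                 0.76740845779422662, 0.88937063821358597,
                 0.60455083021661260, 0.80789101287955400,
                 0.40470406775129958, -0.78396545151481400,
                 0.85827406788011995)))
    attr(g, "expected") <- list(
      kind = "adjacency",
      supernode_members = c("n008", "n010"),
      found_only_by = c(n010 = "BET"),
      found_by_two = c(n008 = "CLO+DEG"))
    return(g)
  }
  # merge_chain: the overlapping triad + adjacencies topology, symbolically
  g <- signed_network(tibble::tibble(
    from = c("B3", "B3", "C5", "B3", "B3", "B4"),
    to = c("C5", "D2", "D2", "CD3", "CD4", "CD3"),
    weight = c(0.8, 0.8, 0.8, 0.7, 0.7, 0.7)))
  attr(g, "expected") <- list(
    kind = "merge_chain",
    candidates = list(
      list(BET = "B3", CLO = "C5", DEG = "D2"),
      list(BET = "B3", `CLO+DEG` = "CD3"),
      list(BET = "B3", `CLO+DEG` = "CD4"),
      list(BET = "B4", `CLO+DEG` = "CD3")),
    merged_positions = list(
      list(nodes = c("B3", "B4"), backbones = "BET"),
      list(nodes = c("C5", "CD3", "CD4"), backbones = "CLO"),
      list(nodes = c("CD3", "CD4", "D2"), backbones = "DEG")))
  g
}
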