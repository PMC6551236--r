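# Independent reference implementations used as oracles.
#
# Everything here works on a plain weight matrix and is written separately
# from the package internals (no shared code paths): exhaustive simple-path
# enumeration, direct centrality formulas, and a literal transcription of
# the iterative extraction loop.  Deliberately slow, only for tiny inputs.

# weight matrix (0 = no edge) from a signed_network
h_wmat <- function(g) {
  nodes <- network_nodes(g)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- as_tibble(g)
  for (k in seq_len(nrow(e))) {
    W[e$from[k], e$to[k]] <- e$weight[k]
    W[e$to[k], e$from[k]] <- e$weight[k]
  }
  W
}

# exhaustive max positive / most negative simple-path products, with the
# (tolerance-equal magnitude, fewer edges, lex) witness tie-break
h_labels <- function(W) {
  n <- nrow(W)
  G <- matrix(0, n, n, dimnames = dimnames(W))
  L <- matrix(0, n, n, dimnames = dimnames(W))
  wit_pos <- vector("list", n * n)
  wit_neg <- vector("list", n * n)
  dim(wit_pos) <- dim(wit_neg) <- c(n, n)
  prefer <- function(mag, path, bmag, bpath) {
    if (is.null(bpath)) return(TRUE)
    tol <- 1e-9 * max(1, mag, bmag)
    if (mag > bmag + tol) return(TRUE)
    if (mag < bmag - tol) return(FALSE)
    if (length(path) != length(bpath)) return(length(path) < length(bpath))
    d <- which(path != bpath)
    length(d) > 0 && path[d[1]] < bpath[d[1]]
  }
  for (s in seq_len(n)) {
    stack <- list(list(u = s, prod = 1, path = s))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (v in seq_len(n)) {
        if (W[fr$u, v] == 0 || v %in% fr$path) next
        p2 <- fr$prod * W[fr$u, v]
        path2 <- c(fr$path, v)
        if (p2 > 0) {
          if (prefer(p2, path2, G[s, v], wit_pos[[s, v]])) {
            G[s, v] <- p2
            wit_pos[[s, v]] <- path2
          }
        } else {
          if (prefer(-p2, path2, -L[s, v], wit_neg[[s, v]])) {
            L[s, v] <- p2
            wit_neg[[s, v]] <- path2
          }
        }
        stack[[length(stack) + 1]] <- list(u = v, prod = p2, path = path2)
      }
    }
  }
  list(G = G, L = L, wit_pos = wit_pos, wit_neg = wit_neg)
}

h_closeness <- function(W) {
  lab <- h_labels(W)
  abs(rowSums(lab$G + lab$L))
}

h_degree <- function(W) abs(rowSums(W))

h_betweenness <- function(W) {
  n <- nrow(W)
  lab <- h_labels(W)
  out <- stats::setNames(numeric(n), rownames(W))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k <= j) next
      for (wp in list(lab$wit_pos[[j, k]], lab$wit_neg[[j, k]])) {
        if (!is.null(wp) && length(wp) > 2) {
          inner <- wp[-c(1, length(wp))]
          out[inner] <- out[inner] + 1
        }
      }
    }
  }
  out
}

# opposite edges of stable triangles through m (0 or 2 negative edges)
h_stable_edges <- function(W, m) {
  nbrs <- which(W[m, ] != 0)
  out <- list()
  for (b in nbrs) for (cc in nbrs) {
    if (b < cc && W[b, cc] != 0) {
      nneg <- (W[m, b] < 0) + (W[m, cc] < 0) + (W[b, cc] < 0)
      if (nneg == 0 || nneg == 2) out[[length(out) + 1]] <- c(b, cc)
    }
  }
  out
}

# literal iterative extraction loop over the weight matrix
h_iterate <- function(W, kind, zero_tol = 1e-9) {
  nodes <- rownames(W)
  alive <- rep(TRUE, nrow(W))
  discovered <- character()
  repeat {
    Wa <- W[alive, alive, drop = FALSE]
    if (!nrow(Wa)) break
    vals <- switch(kind,
                   DEG = h_degree(Wa),
                   CLO = h_closeness(Wa),
                   BET = h_betweenness(Wa))
    if (max(vals) <= zero_tol) break
    m_name <- sort(names(vals)[vals == max(vals)])[1]
    m <- which(rownames(W) == m_name)
    for (bc in h_stable_edges(Wa, which(rownames(Wa) == m_name))) {
      bi <- which(rownames(W) == rownames(Wa)[bc[1]])
      ci <- which(rownames(W) == rownames(Wa)[bc[2]])
      W[bi, ci] <- W[ci, bi] <- 0
    }
    W[m, ] <- W[, m] <- 0
    alive[m] <- FALSE
    discovered <- c(discovered, m_name)
  }
  discovered
}

# seeded random signed network for property tests
h_rand_net <- function(n, p, seed, wmin = 0.05, wmax = 0.95,
                       sign_mix = TRUE, unit = FALSE) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  i <- pairs[1, keep]
  j <- pairs[2, keep]
  if (unit) {
    w <- rep(1, length(i))
  } else {
    mag <- stats::runif(length(i), wmin, wmax)
    sg <- if (sign_mix) sample(c(-1, 1), length(i), replace = TRUE) else 1
    w <- mag * sg
  }
  nodes <- sprintf("v%02d", seq_len(n))
  signed_network(tibble::tibble(from = nodes[i], to = nodes[j], weight = w),
                 nodes = nodes)
}

# index of the unordered pair (a, b) in a path_labels witness list
pair_idx <- function(lab, a, b) {
  n <- length(lab$nodes)
  i <- match(a, lab$nodes); j <- match(b, lab$nodes)
  if (i > j) { k <- i; i <- j; j <- k }
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

# largest incident edge magnitude of a node (0 if isolated)
neighbours_of_max <- function(g, nd) {
  e <- as_tibble(g)
  inc <- abs(e$weight[e$from == nd | e$to == nd])
  if (length(inc)) max(inc) else 0
}

# fake discovery trace (for unify unit tests)
h_trace <- function(backbone, nodes) {
  structure(list(backbone = backbone,
                 trace = tibble::tibble(rank = seq_along(nodes), node = nodes,
                                        value = rev(seq_along(nodes))),
                 removed_edges = list()),
            class = "discovery_trace")
}
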