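sn <- function(from, to, w, nodes = NULL) {
  signed_network(tibble::tibble(from = from, to = to, weight = w), nodes = nodes)
}

test_that("single-source search handles the elementary cases", {
  g <- sn("a", "b", 0.8)
  md <- mod_dijkstra(g, "a")
  expect_equal(md$gain[md$target == "b"], 0.8)
  expect_equal(md$loss[md$target == "b"], 0)

  g <- sn(c("a", "b"), c("b", "c"), c(0.8, -0.5))
  md <- mod_dijkstra(g, "a")
  expect_equal(md$gain[md$target == "c"], 0)
  expect_equal(md$loss[md$target == "c"], -0.4)
  expect_equal(md$witness_loss[md$target == "c"][[1]], c("a", "b", "c"))

  # indirect product beats the weak direct edge
  g <- sn(c("a", "b", "a"), c("b", "c", "c"), c(0.9, 0.9, 0.5))
  md <- mod_dijkstra(g, "a")
  expect_equal(md$gain[md$target == "c"], 0.81)
  expect_equal(md$witness_gain[md$target == "c"][[1]], c("a", "b", "c"))

  # disconnected pair
  g <- sn("a", "b", 0.8, nodes = c("a", "b", "z"))
  md <- mod_dijkstra(g, "a")
  expect_equal(md$gain[md$target == "z"], 0)
  expect_equal(md$loss[md$target == "z"], 0)
  expect_null(md$witness_gain[md$target == "z"][[1]])

  # negative single edge
  g <- sn("a", "b", -0.7)
  lab <- all_pairs_labels(g)
  expect_equal(lab$L["a", "b"], -0.7)
  expect_equal(lab$G["a", "b"], 0)

  expect_error(mod_dijkstra(sn("a", "b", .5), "zz"), "zz")
})

test_that("sign bookkeeping is exact where a naive walk search would not be", {
  # the only a-b path is negative; the b-c-d-b cycle has negative product, so
  # a walk around it would fabricate a positive a->b "path"
  g <- sn(c("a", "b", "c", "d"), c("b", "c", "d", "b"),
          c(-0.9, -0.8, 0.7, 0.9))
  lab <- all_pairs_labels(g)
  expect_equal(lab$G["a", "b"], 0)
  expect_equal(lab$L["a", "b"], -0.9)
})

test_that("co-optimal witnesses break ties by length then lexicographic order", {
  # square cycle: two 0.81 paths between opposite corners
  g <- sn(c("a", "b", "a", "c"), c("b", "d", "c", "d"), rep(0.9, 4))
  lab <- all_pairs_labels(g)
  expect_equal(lab$G["a", "d"], 0.81)
  expect_equal(lab$G["d", "a"], 0.81)
  k <- lab$witness_pos[[pair_idx(lab, "a", "d")]]
  expect_equal(k, c("a", "b", "d"))
})

test_that("bounded search agrees with the exhaustive oracle on random nets", {
  for (s in 1:60) {
    n <- 4 + (s %% 5)
    g <- h_rand_net(n, 0.4, seed = 1000 + s)
    a <- all_pairs_labels(g)
    b <- brute_force_labels(g)
    expect_lt(max(abs(a$G - b$G)), 1e-9)
    expect_lt(max(abs(a$L - b$L)), 1e-9)
  }
})

test_that("witness paths are simple and their products equal their labels", {
  for (s in 1:30) {
    g <- h_rand_net(7, 0.45, seed = 2000 + s)
    lab <- all_pairs_labels(g)
    td <- tidy(lab)
    for (r in seq_len(nrow(td))) {
      for (col in c("witness_gain", "witness_loss")) {
        p <- td[[col]][[r]]
        if (is.null(p)) next
        expect_false(anyDuplicated(p) > 0)
        prod <- 1
        for (k in seq_len(length(p) - 1)) {
          prod <- prod * edge_weight(g, p[k], p[k + 1])
        }
        lblv <- if (col == "witness_gain") td$gain[r] else td$loss[r]
        expect_equal(prod, lblv, tolerance = 1e-9)
      }
    }
  }
})

test_that("labels are symmetric, bounded by incident magnitude, and relabeling-equivariant", {
  for (s in 1:15) {
    g <- h_rand_net(7, 0.5, seed = 3000 + s)
    lab <- all_pairs_labels(g)
    expect_identical(lab$G, t(lab$G))
    expect_identical(lab$L, t(lab$L))
    expect_true(all(lab$G >= 0) && all(lab$L <= 0))
    # monotone magnitude: no label exceeds the max incident edge magnitude
    for (nd in network_nodes(g)) {
      inc <- neighbours_of_max(g, nd)
      expect_lte(max(abs(lab$G[nd, ]), abs(lab$L[nd, ])), inc + 1e-12)
    }
    # relabeling equivariance: reverse the node names
    nodes <- network_nodes(g)
    remap <- stats::setNames(rev(nodes), nodes)
    e <- as_tibble(g)
    g2 <- signed_network(tibble::tibble(from = remap[e$from], to = remap[e$to],
                                        weight = e$weight),
                         nodes = unname(remap))
    lab2 <- all_pairs_labels(g2)
    perm <- unname(remap[nodes])
    expect_equal(unname(lab2$G[perm, perm]), unname(lab$G))
    expect_equal(unname(lab2$L[perm, perm]), unname(lab$L))
  }
})

test_that("the exhaustive oracle refuses large networks", {
  g <- h_rand_net(12, 0.3, seed = 1)
  expect_error(brute_force_labels(g), "refuses")
})

test_that("the bounded search is a lower envelope of the exact search", {
  # a finite label budget can only lose paths, never invent them, so every
  # bounded gain/loss magnitude is at most the exact one
  for (s in c(11, 12, 13)) {
    g <- generate_network(n_nodes = 24, topology = "modular", n_modules = 3,
                          seed = s)
    a <- all_pairs_labels(g, width = label_width())
    b <- all_pairs_labels(g, width = 0)
    expect_true(all(a$G <= b$G + 1e-12))
    expect_true(all(-a$L <= -b$L + 1e-12))
    # and on these networks it is also very close to exact
    expect_lt(max(abs(a$G - b$G), abs(a$L - b$L)), 0.05)
  }
})
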