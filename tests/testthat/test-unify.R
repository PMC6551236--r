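sn <- function(from, to, w, nodes = NULL) {
  signed_network(tibble::tibble(from = from, to = to, weight = w), nodes = nodes)
}

# shorthand: supernode from backbone -> nodes assignment
mk_sn <- function(...) {
  spec <- list(...)
  supernode(lapply(names(spec), function(bbs) {
    list(nodes = spec[[bbs]], backbones = strsplit(bbs, "\\+")[[1]])
  }))
}

sn_sig <- function(x) {
  # order-free signature: set of (nodes | backbones) position pairs
  sort(vapply(x$positions, function(p)
    paste(paste(p$nodes, collapse = ","), paste(p$backbones, collapse = "+"),
          sep = " | "), character(1)))
}

test_that("universal agreements are the intersection of discovered sets", {
  trs <- list(h_trace("BET", c("a", "b")), h_trace("CLO", c("b", "c")),
              h_trace("DEG", "b"))
  expect_equal(universal_agreements(trs), "b")
  trs2 <- list(h_trace("BET", c("a", "b")), h_trace("CLO", c("b", "a")))
  expect_setequal(universal_agreements(trs2), c("a", "b"))
  trs3 <- list(h_trace("BET", "a"), h_trace("CLO", "b"), h_trace("DEG", "c"))
  expect_length(universal_agreements(trs3), 0)
  expect_error(universal_agreements(list(h_trace("BET", "a"))), "at least 2")
  expect_error(universal_agreements(list(h_trace("BET", "a"),
                                         h_trace("BET", "b"))), "duplicate")
})

test_that("supernode detection finds connected full-coverage toss-ups", {
  tri <- sn(c("x", "y", "x"), c("y", "z", "z"), c(0.5, 0.5, 0.5))
  trs <- list(h_trace("BET", "x"), h_trace("CLO", "y"), h_trace("DEG", "z"))
  found <- find_supernodes(tri, trs, character())
  expect_length(found, 1)
  expect_equal(supernode_members(found[[1]]), c("x", "y", "z"))

  # adjacency: x by BET alone, y by CLO and DEG
  adj <- sn("x", "y", 0.5)
  trs2 <- list(h_trace("BET", "x"), h_trace("CLO", "y"), h_trace("DEG", "y"))
  found2 <- find_supernodes(adj, trs2, character())
  expect_length(found2, 1)
  expect_equal(supernode_members(found2[[1]]), c("x", "y"))
  expect_equal(sn_sig(found2[[1]]), c("x | BET", "y | CLO+DEG"))

  # two CLO-only nodes adjacent: coverage fails, no supernode
  trs3 <- list(h_trace("BET", character()), h_trace("CLO", c("x", "y")),
               h_trace("DEG", character()))
  expect_length(find_supernodes(adj, trs3, character()), 0)

  # disconnected pair with right coverage: still no supernode
  disc <- signed_network(nodes = c("x", "y"))
  expect_length(find_supernodes(disc, trs2, character()), 0)

  # agreements are excluded from the disagreement pool
  found4 <- find_supernodes(tri, list(h_trace("BET", c("q", "x")),
                                      h_trace("CLO", c("q", "y")),
                                      h_trace("DEG", c("q", "z"))), "q")
  expect_length(found4, 1)
})

test_that("the worked overlapping-supernode merges reproduce verbatim", {
  # central triad + adjacency sharing its betweenness pick
  central <- mk_sn(BET = "B1", CLO = "C1", DEG = "D1")
  adj1 <- mk_sn(BET = "B1", `CLO+DEG` = "CD1")
  m <- merge_supernodes(list(central, adj1))
  expect_length(m, 1)
  expect_equal(sn_sig(m[[1]]),
               c("B1 | BET", "C1,CD1 | CLO", "CD1,D1 | DEG"))

  # upper triad absorbing two adjacencies
  upper <- mk_sn(BET = "B3", CLO = "C5", DEG = "D2")
  m2 <- merge_supernodes(list(upper,
                              mk_sn(BET = "B3", `CLO+DEG` = "CD3"),
                              mk_sn(BET = "B3", `CLO+DEG` = "CD4")))
  expect_length(m2, 1)
  expect_equal(sn_sig(m2[[1]]),
               c("B3 | BET", "C5,CD3,CD4 | CLO", "CD3,CD4,D2 | DEG"))

  # ...and the resulting supernode merging again with a fourth adjacency
  m3 <- merge_supernodes(c(m2, list(mk_sn(BET = "B4", `CLO+DEG` = "CD3"))))
  expect_length(m3, 1)
  expect_equal(sn_sig(m3[[1]]),
               c("B3,B4 | BET", "C5,CD3,CD4 | CLO", "CD3,CD4,D2 | DEG"))
})

test_that("triad/triad and adjacency/adjacency merge rules hold", {
  # triads sharing two nodes
  m <- merge_supernodes(list(mk_sn(BET = "x", CLO = "y", DEG = "w"),
                             mk_sn(BET = "x", CLO = "y", DEG = "z")))
  expect_length(m, 1)
  expect_equal(sn_sig(m[[1]]), c("w,z | DEG", "x | BET", "y | CLO"))
  # triads sharing one node
  m2 <- merge_supernodes(list(mk_sn(BET = "x", CLO = "v", DEG = "w"),
                              mk_sn(BET = "x", CLO = "y", DEG = "z")))
  expect_length(m2, 1)
  expect_equal(sn_sig(m2[[1]]), c("v,y | CLO", "w,z | DEG", "x | BET"))
  # adjacencies sharing their singleton
  m3 <- merge_supernodes(list(mk_sn(BET = "x", `CLO+DEG` = "y"),
                              mk_sn(BET = "x", `CLO+DEG` = "z")))
  expect_length(m3, 1)
  expect_equal(sn_sig(m3[[1]]), c("x | BET", "y,z | CLO+DEG"))
  # disjoint supernodes stay apart
  m4 <- merge_supernodes(list(mk_sn(BET = "a", CLO = "b", DEG = "c"),
                              mk_sn(BET = "p", CLO = "q", DEG = "r")))
  expect_length(m4, 2)
})

test_that("supernodes cover every backbone exactly once, before and after merging", {
  expect_error(mk_sn(BET = "a", `BET+CLO` = "b"), "more than once")
  tri <- mk_sn(BET = "B1", CLO = "C1", DEG = "D1")
  adj <- mk_sn(BET = "B1", `CLO+DEG` = "CD1")
  for (x in merge_supernodes(list(tri, adj))) {
    expect_setequal(supernode_backbones(x), c("BET", "CLO", "DEG"))
  }
})

test_that("rank scoring follows the discovery-order rules", {
  trs <- list(h_trace("BET", c("n", "x", "q", "w")),
              h_trace("CLO", c("y", "n", "q")),
              h_trace("DEG", c("q", "z", "n")))
  # universal agreement: mean over backbones; n has ranks 1, 2, 3
  r <- rank_elements(list("n"), trs)
  expect_equal(r$rank_score, 2)
  # supernode triad: mean of each member under its own backbone
  snx <- mk_sn(BET = "x", CLO = "y", DEG = "z")  # ranks 2, 1, 2
  r2 <- rank_elements(list(snx), trs)
  expect_equal(r2$rank_score, mean(c(2, 1, 2)))
  # merged position uses whichever member was discovered first
  snm <- mk_sn(BET = c("w", "x"), `CLO+DEG` = "q")  # min(4,2)=2; q: (3+1)/2
  r3 <- rank_elements(list(snm), trs)
  expect_equal(r3$rank_score, mean(c(2, 2)))
  # elements are sorted ascending by score (the supernode scores 5/3 < 2)
  r4 <- rank_elements(list("n", snx), trs)
  expect_equal(r4$members, c("x|y|z", "n"))
  expect_equal(r4$position, c(1, 2))
  expect_error(rank_elements(list("absent"), trs), "absent")
})

test_that("consensus is the identity when every backbone agrees", {
  g <- sn("a", "b", 0.8)
  r <- matria(g, backbones = c("CLO", "DEG"))
  expect_equal(nrow(r$elements), 1)
  expect_equal(r$elements$members, "a")
  expect_length(r$supernodes, 0)
  expect_length(r$unresolvable, 0)
  expect_equal(r$unimportant, "b")
})

test_that("an edgeless network is entirely unimportant", {
  g <- signed_network(nodes = c("a", "b", "c"))
  r <- matria(g)
  expect_equal(nrow(r$elements), 0)
  expect_setequal(r$unimportant, c("a", "b", "c"))
})

test_that("the four consensus classes partition the node set", {
  for (s in 1:6) {
    g <- generate_network(n_nodes = 24, topology = c("modular", "scale_free")[1 + s %% 2],
                          n_modules = 3, seed = 40 + s)
    r <- matria(g)
    members <- unlist(lapply(r$supernodes, supernode_members))
    all_classes <- c(r$agreed, members, r$unresolvable, r$unimportant)
    expect_equal(sort(all_classes), network_nodes(g))
    # post-merge disjointness
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("rank vectors expand with tied-last uncovered nodes", {
  g <- sn(c("a", "b"), c("b", "c"), c(0.8, 0.7), nodes = c("a", "b", "c", "d"))
  trs <- list(h_trace("CLO", c("b", "a")), h_trace("DEG", c("b", "a")))
  r <- structure(list(elements = rank_elements(list("a", "b"), trs),
                      agreed = c("a", "b"), supernodes = list(),
                      unresolvable = character(), unimportant = c("c", "d"),
                      traces = trs, backbones = c("CLO", "DEG"),
                      nodes = network_nodes(g)),
                 class = "matria_ranking")
  v <- expanded_rank_vector(r)
  expect_equal(v$rank[v$node %in% c("c", "d")], c(3, 3))
  expect_equal(v$rank[v$node == "b"], 1)  # b ranked 1 by both backbones

  tr <- h_trace("DEG", c("b", "a"))
  vt <- expanded_rank_vector(tr, g)
  expect_equal(stats::setNames(vt$rank, vt$node),
               c(a = 2, b = 1, c = 3, d = 3))
})

test_that("supernode members inherit their element's position", {
  tri <- sn(c("x", "y", "x"), c("y", "z", "z"), c(0.5, 0.5, 0.5),
            nodes = c("q", "x", "y", "z"))
  trs <- list(h_trace("BET", c("q", "x")), h_trace("CLO", c("q", "y")),
              h_trace("DEG", c("q", "z")))
  snx <- find_supernodes(tri, trs, "q")[[1]]
  r <- structure(list(elements = rank_elements(list("q", snx), trs),
                      agreed = "q", supernodes = list(snx),
                      unresolvable = character(), unimportant = character(),
                      traces = trs, backbones = c("BET", "CLO", "DEG"),
                      nodes = network_nodes(tri)),
                 class = "matria_ranking")
  v <- expanded_rank_vector(r)
  expect_equal(v$rank[v$node %in% c("x", "y", "z")], c(2, 2, 2))
})

test_that("spearman matches its closed forms and validates inputs", {
  u <- tibble::tibble(node = letters[1:4], rank = 1:4)
  expect_equal(spearman(u, u), 1.0)
  v <- tibble::tibble(node = letters[1:4], rank = 4:1)
  expect_equal(spearman(u, v), -1.0)
  w <- tibble::tibble(node = letters[1:4], rank = c(1, 2, 4, 3))
  expect_equal(spearman(u, w), 0.8)
  expect_error(spearman(u, tibble::tibble(node = letters[2:5], rank = 1:4)),
               "different node sets")
  expect_error(spearman(u[1:2, ], v[1:2, ]), "at least 3")
  m <- spearman_matrix(list(A = u, B = v, C = w))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
})
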