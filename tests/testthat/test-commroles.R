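two_bridged_k4 <- function(env = parent.frame()) {
  lines <- c("a1 a2", "a1 a3", "a1 a4", "a2 a3", "a2 a4", "a3 a4",
             "b1 b2", "b1 b3", "b1 b4", "b2 b3", "b2 b4", "b3 b4",
             "a1 b1")
  read_edge_list(withr::local_tempfile(lines = lines, .local_envir = env))
}

test_that("Potts quality reproduces hand-evaluated values", {
  g <- random_graph(10, 0.4, seed = 1)
  nm <- igraph::V(g)$name
  expect_equal(potts_quality(g, stats::setNames(rep(1, 10), nm), 1), 0)

  k2 <- read_edge_list(withr::local_tempfile(lines = "a b"))
  expect_equal(potts_quality(k2, c(a = 1, b = 2), 1), -0.5)

  s <- planted_modular_graph(c(4, 4), 1, 0, seed = 1)
  expect_equal(potts_quality(s$network, s$partition, 1), 0.5)

  empty <- read_edge_list(withr::local_tempfile(lines = character(0)))
  expect_error(potts_quality(empty + igraph::vertices("a"),
                             c(a = 1), 1), "empty")
})

test_that("Potts quality agrees with igraph modularity across resolutions", {
  for (s in 1:4) {
    g <- random_graph(15, 0.3, seed = s)
    part <- detect_communities(g, gamma = 1, n_restarts = 5, seed = s)
    for (gamma in c(0.5, 1, 2)) {
      expect_equal(potts_quality(g, part, gamma),
                   igraph::modularity(g, part[igraph::V(g)$name],
                                      resolution = gamma),
                   tolerance = 1e-12)
    }
  }
})

test_that("community detection recovers planted structure exactly", {
  g <- two_bridged_k4()
  part <- detect_communities(g, gamma = 1, n_restarts = 10, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[c("a1", "a2", "a3", "a4")])), 1)
  expect_equal(length(unique(part[c("b1", "b2", "b3", "b4")])), 1)

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  expect_equal(length(unique(detect_communities(k6, 1, 5, 1))), 1)
})

test_that("detected partitions attain the exhaustive optimum on small graphs", {
  for (s in 1:6) {
    g <- random_graph(sample(5:7, 1), runif(1, 0.35, 0.7), seed = 100 + s)
    if (igraph::ecount(g) == 0) next
    part <- detect_communities(g, gamma = 1, n_restarts = 10, seed = s)
    expect_equal(potts_quality(g, part, 1), bf_best_partition(g, 1),
                 tolerance = 1e-9)
  }
})

test_that("higher resolution yields more communities on a clique ring", {
  cliques <- lapply(0:3, function(k) {
    nodes <- sprintf("c%d_%d", k, 1:5)
    outer(nodes, nodes, paste)[upper.tri(diag(5))]
  })
  bridges <- c("c0_1 c1_1", "c1_2 c2_1", "c2_2 c3_1", "c3_2 c0_2")
  g <- read_edge_list(withr::local_tempfile(lines = c(unlist(cliques), bridges)))
  # at gamma = 0.1 the resolution limit merges adjacent cliques; at gamma = 3
  # each clique stands alone
  n_low <- length(unique(detect_communities(g, gamma = 0.1, 10, 1)))
  n_high <- length(unique(detect_communities(g, gamma = 3, 10, 1)))
  expect_gt(n_high, n_low)
})

test_that("within-community z-scores match the arithmetic oracle", {
  # community with kappa = (3,1,1,1): z for the first node is 1.5/0.866
  g <- read_edge_list(withr::local_tempfile(lines = c("h a", "h b", "h c")))
  part <- c(h = 1, a = 1, b = 1, c = 1)
  z <- within_community_z(g, part)
  expect_equal(z[["h"]], (3 - 1.5) / sqrt(mean((c(3, 1, 1, 1) - 1.5)^2)))
  expect_equal(z[["h"]], 1.7321, tolerance = 1e-4)
  expect_equal(sum(z), 0, tolerance = 1e-9)

  # all kappa equal: degenerate sigma gives z = 0
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  expect_equal(unname(within_community_z(k3, c(x = 1, y = 1, z = 1))),
               rep(0, 3))
})

test_that("per-community z means vanish where sigma is positive", {
  s <- planted_modular_graph(c(12, 12, 12), 0.5, 0.05, seed = 9)
  part <- detect_communities(s$network, 1, 10, 2)
  z <- within_community_z(s$network, part)
  for (cc in unique(part)) {
    zc <- z[names(part)[part == cc]]
    if (stats::sd(zc) > 0) expect_equal(mean(zc), 0, tolerance = 1e-9)
  }
})

test_that("participation coefficients match split-degree arithmetic", {
  g <- read_edge_list(withr::local_tempfile(lines = c(
    "v a1", "v a2", "v b1", "v b2", "a1 a2")))
  p <- participation_coefficient(g, c(v = 1, a1 = 1, a2 = 1, b1 = 2, b2 = 2))
  expect_equal(p[["v"]], 0.5)                 # degree 4 split 2/2
  expect_equal(p[["a1"]], 0)                  # all links internal

  g3 <- read_edge_list(withr::local_tempfile(lines = c("v a", "v b", "v c")))
  p3 <- participation_coefficient(g3, c(v = 1, a = 1, b = 2, c = 3))
  expect_equal(p3[["v"]], 2 / 3)              # degree 3 split 1/1/1
})

test_that("kappa bookkeeping conserves degree", {
  g <- random_graph(20, 0.2, seed = 5)
  part <- detect_communities(g, 1, 5, 5)
  km <- hubnet:::kappa_matrix(g, part)
  expect_equal(rowSums(km), igraph::degree(g)[rownames(km)],
               ignore_attr = TRUE)
})

test_that("role assignment follows the cartographic thresholds", {
  z <- c(a = 0, b = 3.0, c = 1.0, d = 2.5, e = 0, f = 3, g = 0.4)
  p <- c(a = 0, b = 0.1, c = 0.7, d = 0.5, e = 0.9, f = 0.8, g = 0.3)
  roles <- assign_roles(z, p)
  expect_equal(as.character(roles),
               c("R1", "R5", "R3", "R6", "R4", "R7", "R2"))
})

test_that("canonical partitions are invariant under label permutation", {
  part <- c(a = 5, b = 5, c = 9, d = 9, e = 9, f = 2)
  perm <- c(a = "x", b = "x", c = "low", d = "low", e = "low", f = "q")
  expect_identical(canonicalise_partition(part), canonicalise_partition(perm))
  expect_equal(unname(canonicalise_partition(part)[c("c", "a", "f")]),
               c(1L, 2L, 3L))
})

test_that("per-node Jaccard distances reproduce the stated endpoints", {
  expect_equal(jaccard_node(c("i", "a"), c("i", "a")), 0)
  expect_equal(jaccard_node(c("i", "a"), c("i", "b")), 2 / 3)
  expect_equal(jaccard_node(c("i", "a"), c("i", "a", "b", "c")), 0.5)
  expect_error(jaccard_node(character(0), "a"), "non-empty")
})

test_that("partition comparison: identity, halving and focal-only overlap", {
  s <- planted_modular_graph(c(10, 10), 0.7, 0.05, seed = 13)
  part <- detect_communities(s$network, 1, 5, 1)
  roles <- node_roles(s$network, part)
  rl <- stats::setNames(roles$role, roles$node)
  cmp <- compare_partitions(part, part, roles1 = rl, roles2 = rl)
  expect_equal(cmp$mean_jaccard, 0)
  expect_equal(cmp$role_overlap_pct, 100)

  # splitting every community of size s in half gives J = 0.5 per node
  nodes <- sprintf("n%02d", 1:8)
  p1 <- stats::setNames(rep(1:2, each = 4), nodes)
  p2 <- stats::setNames(rep(1:4, each = 2), nodes)
  cmp2 <- compare_partitions(p1, p2)
  expect_equal(cmp2$mean_jaccard, 0.5)

  # communities of size 100 sharing only the focal node
  g1 <- c("i", sprintf("a%02d", 1:99))
  g2 <- c("i", sprintf("b%02d", 1:99))
  expect_equal(jaccard_node(g1, g2), 1 - 1 / 199)
  expect_error(compare_partitions(p1, p2, common = character(0)), "common")
})

test_that("planted partitions are recovered across seeds", {
  ok <- 0
  for (s in 1:10) {
    syn <- planted_modular_graph(c(30, 30, 30), 0.4, 0.02, seed = s)
    part <- detect_communities(syn$network, gamma = 1, n_restarts = 5,
                               seed = 100 + s)
    cmp <- compare_partitions(syn$partition, part)
    if (cmp$mean_jaccard < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
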