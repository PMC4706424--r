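ring_edges <- function(nodes) {
  data.frame(from = nodes, to = nodes[c(2:length(nodes), 1)],
             stringsAsFactors = FALSE)
}
clique_edges <- function(nodes) {
  p <- utils::combn(nodes, 2)
  data.frame(from = p[1, ], to = p[2, ], stringsAsFactors = FALSE)
}
graph_of <- function(edges, isolated = character(0)) {
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = unique(c(edges$from, edges$to, isolated))))
}

test_that("cohesiveness matches its definition in both penalty modes", {
  tri <- graph_of(clique_edges(c("A", "B", "C")))
  expect_equal(cohesiveness(c("A", "B", "C"), tri, penalty = 0), 1)
  star <- graph_of(data.frame(from = "X", to = c("Y", "Z")))
  expect_equal(cohesiveness("X", star, penalty = 0), 0)
  # constant-penalty form: w_in = 3, w_bound = 1, p = 2 -> 3/6
  g <- graph_of(rbind(clique_edges(c("A", "B", "C")),
                      data.frame(from = "C", to = "D")))
  expect_equal(cohesiveness(c("A", "B", "C"), g, penalty = 2,
                            penalty_scale = "constant"), 0.5)
  # per-node form on the same set: 3/(3 + 1 + 2*3)
  expect_equal(cohesiveness(c("A", "B", "C"), g, penalty = 2), 3 / 10)
  # agreement with the from-scratch oracle on random sets
  ed <- rbind(clique_edges(sprintf("K%d", 1:5)), ring_edges(sprintf("R%d", 1:4)),
              data.frame(from = "K1", to = "R1"))
  gg <- graph_of(ed)
  withr::with_seed(2, {
    for (i in 1:10) {
      v <- sample(igraph::V(gg)$name, sample(2:6, 1))
      expect_equal(cohesiveness(v, gg), cohesiveness_oracle(v, ed))
    }
  })
})

test_that("cohesiveness responds correctly to added internal/boundary edges", {
  base <- clique_edges(c("A", "B", "C", "D"))[-1, ]  # near-clique
  v <- c("A", "B", "C", "D")
  f0 <- cohesiveness(v, graph_of(base))
  # adding an internal edge never decreases f
  f_in <- cohesiveness(v, graph_of(clique_edges(v)))
  expect_gte(f_in, f0)
  # adding a boundary edge never increases it
  f_bd <- cohesiveness(v, graph_of(rbind(base, data.frame(from = "A", to = "Z"))))
  expect_lte(f_bd, f0)
})

test_that("growth recovers an isolated clique and stops at isolated seeds", {
  g <- graph_of(clique_edges(sprintf("K%d", 1:5)), isolated = "LONER")
  expect_equal(grow_module("K3", g), sprintf("K%d", 1:5))
  expect_equal(grow_module("LONER", g), "LONER")
})

test_that("greedy growth attains the exhaustive cohesiveness maximum on a toy graph", {
  # 6-clique with a 4-node tail; the clique is the unique global optimum
  ed <- rbind(clique_edges(sprintf("C%d", 1:6)),
              data.frame(from = c("C1", "T1", "T2", "T3"),
                         to = c("T1", "T2", "T3", "T4")))
  g <- graph_of(ed)
  got <- grow_module("C4", g)
  f_got <- cohesiveness(got, g)
  # brute force over all connected node sets containing the seed
  nodes <- igraph::V(g)$name
  best <- 0
  for (size in 1:10) {
    for (s in utils::combn(nodes, size, simplify = FALSE)) {
      if (!("C4" %in% s)) next
      if (!igraph::is_connected(igraph::induced_subgraph(g, s))) next
      best <- max(best, cohesiveness(s, g))
    }
  }
  expect_equal(f_got, best)
  expect_equal(got, sprintf("C%d", 1:6))
})

test_that("returned modules are local maxima of cohesiveness", {
  withr::with_seed(8, {
    cfg <- network_sim_config(30, background_degree = 1,
                              planted_modules = list(
                                list(nodes = sprintf("N%03d", 1:7), p_in = 0.95)),
                              seed = 8)
    g <- simulate_network(cfg)
    m <- grow_module("N001", g)
    f <- cohesiveness(m, g)
    others <- setdiff(igraph::V(g)$name, m)
    nbrs <- others[vapply(others, function(v)
      any(igraph::V(g)$name[igraph::neighbors(g, v)] %in% m), logical(1))]
    for (v in nbrs) expect_lte(cohesiveness(c(m, v), g), f + 1e-12)
    if (length(m) > 1) {
      for (v in m) expect_lte(cohesiveness(setdiff(m, v), g), f + 1e-12)
    }
  })
})

test_that("module filters enforce the size and density thresholds", {
  # 7-node tree: density 6/21 < 0.3, filtered even though cohesive
  tree <- graph_of(data.frame(from = c("A", "A", "B", "B", "C", "C"),
                              to = c("B", "C", "D", "E", "F", "G")))
  expect_length(detect_modules(tree), 0)
  # 6 nodes total can never reach min_size 7
  small <- graph_of(clique_edges(sprintf("S%d", 1:6)))
  expect_length(detect_modules(small), 0)
  # but the same 6-clique passes with min_size 6
  expect_length(detect_modules(small, min_size = 6), 1)
})

test_that("two planted cliques joined by an edge give exactly two clean modules", {
  a <- sprintf("A%d", 1:8); b <- sprintf("B%d", 1:8)
  g <- graph_of(rbind(clique_edges(a), clique_edges(b),
                      data.frame(from = "A1", to = "B1")))
  mods <- detect_modules(g)
  expect_length(mods, 2)
  sets <- lapply(mods, `[[`, "nodes")
  expect_equal(max(vapply(sets, jaccard, numeric(1), a)), 1)
  expect_equal(max(vapply(sets, jaccard, numeric(1), b)), 1)
  for (m in mods) {
    expect_gte(m$density, 0.3)
    expect_lt(m$p_value, 0.05)
    expect_gte(length(m$nodes), 7)
  }
})

test_that("module detection is deterministic, order included", {
  cfg <- network_sim_config(40, background_degree = 0.02 * 39,
                            planted_modules = list(
                              list(nodes = sprintf("N%03d", 1:8), p_in = 0.9),
                              list(nodes = sprintf("N%03d", 20:27), p_in = 0.9)),
                            seed = 17)
  g <- simulate_network(cfg)
  expect_identical(detect_modules(g), detect_modules(g))
})

test_that("haircut trims pendant members without touching core ones", {
  # for a 5-clique, w_bound + p|V| exceeds w_in, so greedy growth provably
  # absorbs the pendants; the haircut restores the dense core
  clique <- sprintf("K%d", 1:5)
  g <- graph_of(rbind(clique_edges(clique),
                      data.frame(from = c("K1", "K2"), to = c("P1", "P2"))))
  mods <- detect_modules(g, min_size = 5)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$nodes, clique)
  # with haircut disabled the pendants stay in the grown module
  mods0 <- detect_modules(g, min_size = 5, haircut = 0)
  expect_true(all(c("P1", "P2") %in% mods0[[1]]$nodes))
})
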