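edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

test_that("background integration merges orientations and drops self-loops", {
  g <- integrate_background(edge_df("A", "B"), edge_df("B", "A", "C", "C"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$source_count, 2)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_error(integrate_background(edge_df("X", "X")), "empty")

  # disjoint lists: unions of nodes and edges
  g2 <- integrate_background(edge_df("A", "B"), edge_df("C", "D"))
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C", "D"))

  # idempotence: re-integrating the integrated edges changes nothing
  ed <- igraph::as_data_frame(g2, "edges")[, c("from", "to")]
  g3 <- integrate_background(ed, ed)
  expect_equal(igraph::ecount(g3), igraph::ecount(g2))
  expect_setequal(igraph::V(g3)$name, igraph::V(g2)$name)
})

test_that("terminal mapping reports unmapped symbols and canonicalizes", {
  g <- integrate_background(edge_df("TP53", "MDM2", "MDM2", "MMP9"))
  m <- map_terminals(g, deg_set(up = c("tp53", "BRCA1"), down = "MMP9"))
  expect_setequal(m$terminals, c("TP53", "MMP9"))
  expect_equal(m$unmapped, "BRCA1")
  expect_error(map_terminals(g, deg_set(up = "NOPE")), "no DEG maps")
  m2 <- map_terminals(g, c("TP53", "MDM2", "MMP9"))
  expect_length(m2$unmapped, 0)
})

test_that("one-intermediary candidates need >= 2 terminal neighbors", {
  # star: center non-DEG with 3 DEG leaves, plus a spur with one terminal nbr
  g <- integrate_background(edge_df("HUB", "D1", "HUB", "D2", "HUB", "D3",
                                    "SPUR", "D1", "SPUR", "X"))
  cand <- one_intermediary_candidates(g, c("D1", "D2", "D3"))
  expect_equal(cand, "HUB")
  # a terminal adjacent to terminals is not a candidate
  g2 <- integrate_background(edge_df("D1", "D2", "D2", "D3"))
  expect_length(one_intermediary_candidates(g2, c("D1", "D2", "D3")), 0)
})

test_that("Steiner subnetwork solves simple instances exactly", {
  path <- integrate_background(edge_df("A", "B", "B", "C"))
  st <- steiner_subnetwork(path, c("A", "C"))
  expect_equal(st$total_cost, 2)
  expect_setequal(igraph::V(st$graph)$name, c("A", "B", "C"))

  tri <- integrate_background(edge_df("A", "B", "B", "C", "A", "C"))
  st2 <- steiner_subnetwork(tri, c("A", "B", "C"))
  expect_equal(st2$total_cost, 2)   # spanning tree of the triangle

  # isolated terminal: kept as singleton with a warning
  g3 <- integrate_background(edge_df("A", "B", "X", "Y"))
  expect_warning(st3 <- steiner_subnetwork(g3, c("A", "B", "X")), "X")
  expect_true("X" %in% igraph::V(st3$graph)$name)
  expect_equal(st3$total_cost, 1)
})

test_that("Steiner output is a pruned forest containing every terminal", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      g <- igraph::sample_gnp(14, 0.25)
      igraph::V(g)$name <- sprintf("V%02d", 1:14)
      terms <- sample(igraph::V(g)$name, 5)
      st <- suppressWarnings(steiner_subnetwork(g, terms))
      sg <- st$graph
      expect_true(all(terms %in% igraph::V(sg)$name))
      comp <- igraph::components(sg)
      # forest: edges = nodes - components
      expect_equal(igraph::ecount(sg), igraph::vcount(sg) - comp$no)
      # no pruned leaf is a terminal: every non-terminal has degree >= 2
      nonterm <- setdiff(igraph::V(sg)$name, terms)
      if (length(nonterm)) {
        expect_true(all(igraph::degree(sg, nonterm) >= 2))
      }
    }
  })
})

test_that("KMB approximation stays within 2x of the exhaustive optimum", {
  withr::with_seed(11, {
    ratios <- numeric(0)
    done <- 0
    while (done < 15) {
      g <- igraph::sample_gnp(12, 0.22)
      igraph::V(g)$name <- sprintf("V%02d", 1:12)
      if (!igraph::is_connected(g)) next
      terms <- sample(igraph::V(g)$name, 4)
      done <- done + 1
      opt <- steiner_opt_cost(g, terms)
      got <- steiner_subnetwork(g, terms)$total_cost
      expect_gte(got, opt)
      ratios <- c(ratios, got / opt)
    }
    expect_true(all(ratios <= 2))
  })
})

test_that("Steiner result is deterministic and isomorphism-stable", {
  g <- integrate_background(edge_df("A", "B", "B", "C", "A", "D", "D", "C",
                                    "C", "E", "B", "E"))
  a <- steiner_subnetwork(g, c("A", "E"))
  b <- steiner_subnetwork(g, c("A", "E"))
  expect_identical(igraph::as_data_frame(a$graph, "edges"),
                   igraph::as_data_frame(b$graph, "edges"))
})

test_that("analysis subnetwork restores induced edges among selected nodes", {
  # two DEG cliquelets joined via a linker; linker adjacency must come back
  g <- integrate_background(edge_df("D1", "D2", "D2", "D3", "D1", "D3",
                                    "D3", "L", "L", "D4", "D4", "D5",
                                    "L", "D5", "B1", "B2"))
  degs <- deg_set(up = c("D1", "D2", "D3"), down = c("D4", "D5"))
  sub <- analysis_subnetwork(g, degs)
  expect_true("L" %in% igraph::V(sub)$name)
  expect_false("B1" %in% igraph::V(sub)$name)
  # induced edge D1-D3 present even if not needed by the tree
  expect_true(igraph::are_adjacent(sub, "D1", "D3"))
  expect_equal(sort(attr(sub, "terminals")), sprintf("D%d", 1:5))
  dirs <- stats::setNames(igraph::V(sub)$direction, igraph::V(sub)$name)
  expect_equal(unname(dirs["D4"]), "down")
  expect_equal(unname(dirs["L"]), "none")
})
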