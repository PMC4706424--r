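#' Integrate interaction edge lists into one background network
#'
#' Takes any number of `from`/`to` data frames (or file paths readable by
#' [read_edge_list()]) and returns their union as a simple undirected graph.
#' `(A,B)` and `(B,A)` are merged, self-loops dropped, and the edge attribute
#' `source_count` records how many input pairs supported each edge.
#'
#' @param ... Edge-list data frames and/or paths.
#' @return A named undirected `igraph` with edge attribute `source_count`.
#' @export
integrate_background <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  # expand character vectors of paths into one input per file
  inputs <- do.call(c, lapply(inputs, function(x) {
    if (is.character(x)) as.list(x) else list(x)
  }))
  if (!length(inputs)) stop("need at least one edge list")
  edges <- lapply(inputs, function(x) {
    if (is.character(x)) x <- read_edge_list(x)
    stopifnot(is.data.frame(x), all(c("from", "to") %in% names(x)))
    data.frame(from = canonicalize_symbols(x$from),
               to = canonicalize_symbols(x$to), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, edges)
  all <- all[all$from != all$to, , drop = FALSE]
  if (!nrow(all)) stop("empty edge union after dropping self-loops")
  a <- pmin(all$from, all$to)
  b <- pmax(all$from, all$to)
  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  uniq <- !duplicated(key)
  d <- data.frame(from = a[uniq], to = b[uniq],
                  source_count = as.integer(cnt[key[uniq]]),
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(d, directed = FALSE)
}

#' Map DEGs onto the background network
#'
#' @param network A named `igraph`.
#' @param degs A [deg_set()] or character vector of symbols.
#' @return List with `terminals` (symbols found in the network) and
#'   `unmapped` (symbols not found; reported, never silently dropped).
#' @export
map_terminals <- function(network, degs) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0) stop("background network is empty")
  symbols <- if (inherits(degs, "DEGSet")) c(degs$up, degs$down) else degs
  symbols <- unique(canonicalize_symbols(symbols))
  terminals <- intersect(symbols, igraph::V(network)$name)
  if (!length(terminals)) stop("no DEG maps to the background network")
  list(terminals = terminals, unmapped = setdiff(symbols, terminals))
}

#' One-intermediary linker candidates
#'
#' Non-terminal nodes adjacent to at least two distinct terminals: the
#' proteins through which mapped DEGs can be linked with a single
#' intermediary.
#'
#' @param network A named `igraph`.
#' @param terminals Character vector of terminal symbols.
#' @return Character vector of candidate symbols (sorted).
#' @export
one_intermediary_candidates <- function(network, terminals) {
  stopifnot(igraph::is_igraph(network))
  adj <- adjacency_names(network)
  nodes <- setdiff(names(adj), terminals)
  hits <- vapply(nodes, function(v) sum(adj[[v]] %in% terminals) >= 2L, logical(1))
  sort(nodes[hits])
}

# Sorted-neighbor adjacency list keyed by node name; sorting fixes the
# lexicographic tie-breaks used in BFS / MST below.
adjacency_names <- function(g) {
  al <- igraph::as_adj_list(g)
  names(al) <- igraph::V(g)$name
  lapply(al, function(x) sort(igraph::V(g)$name[as.integer(x)]))
}

# Deterministic BFS from `src` over the sorted adjacency list: among equal
# length shortest paths the lexicographically smallest parent is chosen.
bfs_tree_from <- function(adj, src) {
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  parent <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(dist = dist, parent = parent)
}

path_from_parents <- function(parent, src, dst) {
  path <- dst
  while (path[1] != src) path <- c(parent[[path[1]]], path)
  path
}

#' Steiner subnetwork connecting mapped DEGs
#'
#' Kou-Markowsky-Berman 2-approximation of the Steiner minimal tree with unit
#' edge weights, run per terminal connected component: metric closure over
#' the terminals, minimum spanning tree of the closure (Prim with
#' lexicographic tie-breaks), expansion of closure edges into shortest paths,
#' spanning tree of the expanded subgraph, and pruning of non-terminal
#' leaves. The result is a forest whose cost (edge count) is at most
#' `2 * (1 - 1/l)` times the optimum, `l` being the number of terminal
#' leaves in the optimal tree. Terminals sharing a component with no other
#' terminal are returned as singleton components with a warning.
#'
#' @param network A named `igraph` (unit edge weights).
#' @param terminals Character vector of terminal symbols in the network.
#' @return A `SteinerSubnetwork`: list with `graph` (the forest as `igraph`),
#'   `terminals`, `total_cost` (edge count) and `singletons`.
#' @export
steiner_subnetwork <- function(network, terminals) {
  stopifnot(igraph::is_igraph(network))
  terminals <- unique(canonicalize_symbols(terminals))
  missing <- setdiff(terminals, igraph::V(network)$name)
  if (length(missing)) stop("terminal(s) not in network: ", paste(missing, collapse = ", "))
  adj <- adjacency_names(network)

  comp <- igraph::components(network)
  memb <- stats::setNames(comp$membership, igraph::V(network)$name)
  groups <- split(terminals, memb[terminals])
  singletons <- unlist(groups[lengths(groups) == 1L], use.names = FALSE)
  if (length(singletons)) {
    warning("terminal(s) in no component with another terminal: ",
            paste(singletons, collapse = ", "))
  }

  tree_edges <- character(0)
  tree_edge_df <- data.frame(from = character(), to = character(),
                             stringsAsFactors = FALSE)
  keep_nodes <- character(0)
  for (grp in groups[lengths(groups) > 1L]) {
    grp <- sort(grp)
    bfs <- lapply(grp, function(t) bfs_tree_from(adj, t))
    names(bfs) <- grp
    dmat <- do.call(rbind, lapply(grp, function(t) bfs[[t]]$dist[grp]))
    rownames(dmat) <- grp
    mst <- prim_mst_lex(dmat)
    # expand each closure edge into its deterministic shortest path
    sub_edges <- character(0)
    for (i in seq_len(nrow(mst))) {
      p <- path_from_parents(bfs[[mst$from[i]]]$parent, mst$from[i], mst$to[i])
      sub_edges <- c(sub_edges,
                     paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]),
                           sep = "\r"))
    }
    sub_edges <- unique(sub_edges)
    em <- do.call(rbind, strsplit(sub_edges, "\r", fixed = TRUE))
    sub_nodes <- sort(unique(as.vector(em)))
    sub_adj <- lapply(stats::setNames(sub_nodes, sub_nodes), function(v) {
      sort(unique(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])))
    })
    # spanning tree of the expanded subgraph, then prune non-terminal leaves
    span <- bfs_tree_from(sub_adj, grp[1])
    ed <- data.frame(from = unname(span$parent[!is.na(span$parent)]),
                     to = names(span$parent)[!is.na(span$parent)],
                     stringsAsFactors = FALSE)
    deg <- table(c(ed$from, ed$to))
    repeat {
      leaves <- names(deg)[deg == 1L]
      drop <- setdiff(leaves, grp)
      if (!length(drop)) break
      keep <- !(ed$from %in% drop | ed$to %in% drop)
      ed <- ed[keep, , drop = FALSE]
      deg <- table(c(ed$from, ed$to))
    }
    tree_edge_df <- rbind(tree_edge_df, ed)
    keep_nodes <- c(keep_nodes, unique(c(ed$from, ed$to)))
  }

  g <- igraph::graph_from_data_frame(
    tree_edge_df, directed = FALSE,
    vertices = data.frame(name = unique(c(keep_nodes, terminals)),
                          stringsAsFactors = FALSE))
  structure(list(graph = g, terminals = terminals,
                 total_cost = igraph::ecount(g), singletons = singletons),
            class = "SteinerSubnetwork")
}

#' @export
print.SteinerSubnetwork <- function(x, ...) {
  cat(sprintf("SteinerSubnetwork: %d nodes, %d edges, %d terminals (%d singleton)\n",
              igraph::vcount(x$graph), x$total_cost, length(x$terminals),
              length(x$singletons)))
  invisible(x)
}

# Prim MST over a symmetric distance matrix with deterministic tie-breaking:
# among minimum-weight candidate edges, the lexicographically smallest
# (new node, attachment node) pair wins.
prim_mst_lex <- function(dmat) {
  nodes <- rownames(dmat)
  in_tree <- nodes[1]
  out <- setdiff(nodes, in_tree)
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  while (length(out)) {
    sub <- dmat[in_tree, out, drop = FALSE]
    best <- min(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    pick <- cand[order(out[cand[, 2]], in_tree[cand[, 1]])[1], , drop = FALSE]
    a <- in_tree[pick[1]]
    b <- out[pick[2]]
    edges <- rbind(edges, data.frame(from = a, to = b, stringsAsFactors = FALSE))
    in_tree <- c(in_tree, b)
    out <- setdiff(out, b)
  }
  edges
}

#' Annotate a network with DEG status
#'
#' @param network A named `igraph`.
#' @param degs A [deg_set()].
#' @return The graph with vertex attributes `is_deg` and `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
annotate_degs <- function(network, degs) {
  stopifnot(inherits(degs, "DEGSet"))
  nm <- igraph::V(network)$name
  dir <- rep("none", length(nm))
  dir[nm %in% degs$up] <- "up"
  dir[nm %in% degs$down] <- "down"
  igraph::V(network)$is_deg <- dir != "none"
  igraph::V(network)$direction <- dir
  network
}

#' Analysis subnetwork passed to module detection
#'
#' Union construction: the Steiner-tree nodes, the mapped terminals and the
#' one-intermediary candidates, with *all* background edges induced among
#' them restored (a bare tree would make density-based module detection
#' degenerate).
#'
#' @param network Background `igraph`.
#' @param degs A [deg_set()].
#' @return Annotated induced `igraph`; attributes `terminals` and `unmapped`
#'   record the DEG mapping.
#' @export
analysis_subnetwork <- function(network, degs) {
  mapped <- map_terminals(network, degs)
  st <- steiner_subnetwork(network, mapped$terminals)
  linkers <- one_intermediary_candidates(network, mapped$terminals)
  nodes <- sort(unique(c(igraph::V(st$graph)$name, mapped$terminals, linkers)))
  sub <- igraph::induced_subgraph(network, nodes)
  sub <- annotate_degs(sub, degs)
  attr(sub, "terminals") <- mapped$terminals
  attr(sub, "unmapped") <- mapped$unmapped
  attr(sub, "steiner_cost") <- st$total_cost
  sub
}
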