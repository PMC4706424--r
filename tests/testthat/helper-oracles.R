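# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, exhaustive enumeration, direct
# formulas.

# Exhaustive pfp for a small rank matrix (genes x studies) by enumerating
# every joint permutation of the per-study rank vectors.
exhaustive_pfp <- function(rank_mat) {
  k <- ncol(rank_mat)
  G <- nrow(rank_mat)
  obs_rp <- apply(rank_mat, 1, function(r) prod(r)^(1 / k))
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  study_perms <- lapply(seq_len(k), function(j) perms_of(rank_mat[, j]))
  idx <- expand.grid(lapply(study_perms, seq_along))
  null_rps <- numeric(0)
  for (r in seq_len(nrow(idx))) {
    cols <- lapply(seq_len(k), function(j) study_perms[[j]][[idx[r, j]]])
    m <- do.call(cbind, cols)
    null_rps <- c(null_rps, apply(m, 1, function(x) prod(x)^(1 / k)))
  }
  n_perm <- nrow(idx)
  x <- rank(obs_rp, ties.method = "max")
  pfp <- vapply(seq_len(G), function(g) {
    sum(null_rps <= obs_rp[g] * (1 + 1e-9)) / (n_perm * x[g])
  }, numeric(1))
  ord <- order(obs_rp)
  pfp[ord] <- cummax(pfp[ord])
  pmin(pfp, 1)
}

# Exact minimum Steiner tree cost (unit weights) by exhaustive search over
# supersets of the terminal set: the optimum equals min |S| - 1 over
# connected induced supersets.
steiner_opt_cost <- function(g, terminals) {
  others <- setdiff(igraph::V(g)$name, terminals)
  for (extra in 0:length(others)) {
    if (extra == 0L) {
      if (igraph::is_connected(igraph::induced_subgraph(g, terminals))) {
        return(length(terminals) - 1L)
      }
      next
    }
    combs <- utils::combn(others, extra, simplify = FALSE)
    for (s in combs) {
      if (igraph::is_connected(igraph::induced_subgraph(g, c(terminals, s)))) {
        return(length(terminals) + extra - 1L)
      }
    }
  }
  stop("terminals not connectable")
}

# Plain-queue BFS distances from one source over an edge data frame.
bfs_oracle <- function(edges, src) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- c(edges$to[edges$from == u], edges$from[edges$to == u])
    for (v in nb) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# Cohesiveness from first principles (per-node penalty).
cohesiveness_oracle <- function(nodes, edges, penalty = 2, per_node = TRUE) {
  inside <- edges$from %in% nodes & edges$to %in% nodes
  boundary <- xor(edges$from %in% nodes, edges$to %in% nodes)
  w_in <- sum(inside)
  w_bound <- sum(boundary)
  pterm <- if (per_node) penalty * length(nodes) else penalty
  if (w_in == 0) 0 else w_in / (w_in + w_bound + pterm)
}

# Jaccard index between node sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Small deterministic expression study built directly from a value matrix.
toy_study <- function(id, group, mat, classes) {
  expression_study(id, group, mat, stats::setNames(classes, colnames(mat)))
}

# A study whose per-gene fold changes are exactly `fc` (controls constant 5).
study_with_fc <- function(id, group, fc, n_tumor = 2, n_control = 2) {
  genes <- names(fc)
  m <- matrix(5, nrow = length(genes), ncol = n_tumor + n_control,
              dimnames = list(genes, c(sprintf("%s_T%d", id, seq_len(n_tumor)),
                                       sprintf("%s_C%d", id, seq_len(n_control)))))
  m[, seq_len(n_tumor)] <- 5 + log2(fc)
  toy_study(id, group, m, c(rep("tumor", n_tumor), rep("control", n_control)))
}

# Wheel-with-ring toy module: center adjacent to 8 periphery nodes, the
# periphery forming a ring; the unique structural hub is the center.
wheel_module_graph <- function() {
  periphery <- sprintf("P%d", 1:8)
  edges <- rbind(
    data.frame(from = "CENTER", to = periphery, stringsAsFactors = FALSE),
    data.frame(from = periphery, to = periphery[c(2:8, 1)],
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = FALSE)
}
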