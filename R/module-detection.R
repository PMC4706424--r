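#' Cohesiveness of a node set
#'
#' `f(V) = w_in / (w_in + w_bound + p(V))` with unit edge weights: `w_in`
#' counts edges with both ends in `V`, `w_bound` edges with exactly one end
#' in `V`. The penalty term models undiscovered interactions of the member
#' proteins; in the reference formulation it grows with the set,
#' `p(V) = penalty * |V|` (`penalty_scale = "per_node"`, the default). This
#' scaling is what stops greedy growth from absorbing every pendant
#' neighbor: a degree-1 external node always increases
#' `w_in / (w_in + w_bound + const)`, so a constant penalty cannot reject
#' it. The constant form `p(V) = penalty` remains available via
#' `penalty_scale = "constant"`. `f` is defined as 0 when `w_in = 0` and
#' the denominator vanishes.
#'
#' @param nodes Character vector of member node names (non-empty).
#' @param network A named `igraph`.
#' @param penalty Non-negative penalty (default 2, the reference default).
#' @param penalty_scale `"per_node"` (penalty * |V|) or `"constant"`.
#' @return Cohesiveness in `[0, 1]`.
#' @export
cohesiveness <- function(nodes, network, penalty = 2,
                         penalty_scale = c("per_node", "constant")) {
  penalty_scale <- match.arg(penalty_scale)
  stopifnot(length(nodes) >= 1, igraph::is_igraph(network))
  w_in <- igraph::ecount(igraph::induced_subgraph(network, nodes))
  w_bound <- sum(igraph::degree(network, nodes)) - 2 * w_in
  pterm <- if (penalty_scale == "per_node") penalty * length(nodes) else penalty
  den <- w_in + w_bound + pterm
  if (den == 0) return(0)
  w_in / den
}

# Internal: incremental greedy growth over a precomputed adjacency list.
grow_from <- function(seed, adj, deg, penalty, per_node = TRUE) {
  members <- seed
  in_set <- stats::setNames(rep(FALSE, length(adj)), names(adj))
  in_set[seed] <- TRUE
  w_in <- 0
  w_bound <- deg[[seed]]
  pterm <- function(n) if (per_node) penalty * n else penalty
  f <- if (w_in + w_bound + pterm(1) == 0) 0 else w_in / (w_in + w_bound + pterm(1))

  move_f <- function(node, action) {
    din <- sum(in_set[adj[[node]]])
    if (action == "add") {
      wi <- w_in + din
      wb <- w_bound - din + (deg[[node]] - din)
      nn <- length(members) + 1L
    } else {
      wi <- w_in - din
      wb <- w_bound + din - (deg[[node]] - din)
      nn <- length(members) - 1L
    }
    den <- wi + wb + pterm(nn)
    if (den == 0 || wi == 0) 0 else wi / den
  }

  repeat {
    ext <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))), members)
    rem <- if (length(members) > 1L) members else character(0)
    cand_nodes <- c(ext, rem)
    if (!length(cand_nodes)) break
    cand_action <- c(rep("add", length(ext)), rep("remove", length(rem)))
    fn <- vapply(seq_along(cand_nodes),
                 function(i) move_f(cand_nodes[i], cand_action[i]), numeric(1))
    best <- max(fn)
    if (best <= f + 1e-12) break  # strict improvement only: local maximum
    sel <- which(fn >= best - 1e-12)
    # deterministic tie-break: addition before removal, then node name
    pick <- sel[order(cand_action[sel] != "add", cand_nodes[sel])[1]]
    node <- cand_nodes[pick]
    din <- sum(in_set[adj[[node]]])
    if (cand_action[pick] == "add") {
      w_in <- w_in + din
      w_bound <- w_bound - din + (deg[[node]] - din)
      members <- c(members, node)
      in_set[node] <- TRUE
    } else {
      w_in <- w_in - din
      w_bound <- w_bound + din - (deg[[node]] - din)
      members <- setdiff(members, node)
      in_set[node] <- FALSE
    }
    f <- fn[pick]
  }
  sort(members)
}

#' Grow a cohesive module from a seed node
#'
#' Greedy local search: repeatedly applies the single best
#' add-external-neighbor or remove-member step that strictly increases the
#' cohesiveness, stopping at a local maximum. Ties are broken
#' deterministically (addition before removal, then lexicographic node
#' order), so the result is a pure function of the graph and seed.
#'
#' @param seed Seed node name (must be in the network).
#' @param network A named `igraph`.
#' @param penalty Cohesiveness penalty (default 2).
#' @param penalty_scale See [cohesiveness()].
#' @return Sorted character vector of member node names.
#' @export
grow_module <- function(seed, network, penalty = 2,
                        penalty_scale = c("per_node", "constant")) {
  penalty_scale <- match.arg(penalty_scale)
  stopifnot(igraph::is_igraph(network))
  if (!(seed %in% igraph::V(network)$name)) stop("seed not in network")
  adj <- adjacency_names(network)
  deg <- lengths(adj)
  grow_from(seed, adj, deg, penalty, penalty_scale == "per_node")
}

#' Detect dense, possibly overlapping modules
#'
#' Grows a candidate module from every node (seeds visited in decreasing
#' degree order, lexicographic on ties, skipping nodes already covered by an
#' earlier candidate), merges candidate pairs whose overlap score
#' `omega(A,B) = |A∩B|^2 / (|A||B|)` reaches `overlap_merge`, scores each
#' surviving module, and filters on the minimum size, minimum density and
#' quality p-value. The quality p-value is a one-sided Mann-Whitney U test
#' comparing, over member nodes, in-module versus out-of-module edge counts
#' (an alternative one-sided binomial edge test is available via
#' `p_method = "binomial"`).
#'
#' @param network A named `igraph`.
#' @param min_size Minimum module size (default 7 nodes).
#' @param min_density Minimum density `2m/(n(n-1))` (default 0.3).
#' @param alpha Quality p-value threshold (default 0.05).
#' @param overlap_merge Overlap score at or above which modules merge
#'   (default 0.8).
#' @param penalty Cohesiveness penalty (default 2).
#' @param penalty_scale See [cohesiveness()].
#' @param haircut Haircut threshold in `[0, 1)` (default 0.5): after merging,
#'   members whose in-module degree is below `haircut` times the module's
#'   mean in-module degree are trimmed iteratively. Greedy cohesiveness
#'   maxima provably retain any degree-1 boundary neighbor whenever
#'   `w_bound + p|V| > w_in`, so without this transformation pendant nodes
#'   contaminate otherwise dense modules; 0 disables.
#' @param p_method `"mann_whitney"` (default) or `"binomial"`.
#' @return List of modules sorted by decreasing cohesiveness; each is a list
#'   with `id`, `nodes`, `density`, `cohesiveness`, `p_value`. Class
#'   `ModuleList`.
#' @export
detect_modules <- function(network, min_size = 7L, min_density = 0.3,
                           alpha = 0.05, overlap_merge = 0.8, penalty = 2,
                           penalty_scale = c("per_node", "constant"),
                           haircut = 0.5,
                           p_method = c("mann_whitney", "binomial")) {
  stopifnot(igraph::is_igraph(network))
  p_method <- match.arg(p_method)
  penalty_scale <- match.arg(penalty_scale)
  per_node <- penalty_scale == "per_node"
  if (igraph::vcount(network) == 0) {
    return(structure(list(), class = "ModuleList"))
  }
  adj <- adjacency_names(network)
  deg <- lengths(adj)
  seeds <- names(adj)[order(-deg, names(adj))]

  candidates <- list()
  covered <- character(0)
  for (s in seeds) {
    if (s %in% covered) next
    m <- grow_from(s, adj, deg, penalty, per_node)
    candidates[[length(candidates) + 1L]] <- m
    covered <- unique(c(covered, m))
  }

  # merge highly overlapping candidates until stable
  repeat {
    if (length(candidates) < 2L) break
    merged <- FALSE
    for (i in seq_along(candidates)[-1]) {
      for (j in seq_len(i - 1L)) {
        a <- candidates[[j]]; b <- candidates[[i]]
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov >= overlap_merge) {
          candidates[[j]] <- sort(union(a, b))
          candidates[[i]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  candidates <- unique(candidates)
  if (haircut > 0) {
    candidates <- unique(lapply(candidates, haircut_trim, adj = adj,
                                threshold = haircut))
  }

  out <- list()
  for (m in candidates) {
    n <- length(m)
    if (n < min_size) next
    w_in <- igraph::ecount(igraph::induced_subgraph(network, m))
    density <- if (n > 1) 2 * w_in / (n * (n - 1)) else 0
    if (density < min_density) next
    p <- module_quality_p(m, adj, deg, p_method)
    if (is.na(p) || p >= alpha) next
    out[[length(out) + 1L]] <- list(
      nodes = m, density = density,
      cohesiveness = cohesiveness(m, network, penalty, penalty_scale),
      p_value = p)
  }
  if (length(out)) {
    ord <- order(-vapply(out, `[[`, numeric(1), "cohesiveness"),
                 vapply(out, function(x) x$nodes[1], character(1)))
    out <- out[ord]
    for (i in seq_along(out)) out[[i]]$id <- sprintf("M%02d", i)
  }
  structure(out, class = "ModuleList")
}

# Iteratively trim members whose in-module degree falls below
# threshold * mean in-module degree (the reference tool's haircut
# transformation).
haircut_trim <- function(members, adj, threshold) {
  repeat {
    if (length(members) < 2L) return(members)
    in_deg <- vapply(members, function(v) sum(adj[[v]] %in% members), numeric(1))
    cut <- threshold * mean(in_deg)
    drop <- members[in_deg < cut]
    if (!length(drop) || length(drop) == length(members)) return(sort(members))
    members <- setdiff(members, drop)
  }
}

module_quality_p <- function(members, adj, deg, p_method) {
  in_counts <- vapply(members, function(v) sum(adj[[v]] %in% members), numeric(1))
  out_counts <- deg[members] - in_counts
  if (p_method == "mann_whitney") {
    suppressWarnings(
      stats::wilcox.test(in_counts, out_counts, alternative = "greater",
                         exact = FALSE)$p.value)
  } else {
    # one-sided binomial: are member edge endpoints biased inward?
    k <- sum(in_counts)            # 2 * internal edges
    n <- sum(in_counts + out_counts)
    if (n == 0) return(NA_real_)
    stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  }
}

#' @export
print.ModuleList <- function(x, ...) {
  cat(sprintf("ModuleList: %d module(s)\n", length(x)))
  for (m in x) {
    cat(sprintf("  %s: %d nodes, density %.3f, cohesiveness %.3f, p = %.3g\n",
                m$id, length(m$nodes), m$density, m$cohesiveness, m$p_value))
  }
  invisible(x)
}
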