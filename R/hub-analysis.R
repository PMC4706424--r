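#' Average shortest-path distance from a node to the DEGs
#'
#' Mean unweighted shortest-path length from `node` to every reachable DEG in
#' the subnetwork, excluding the node itself when it is a DEG. Unreachable
#' DEGs are excluded from the mean (their count is reported by
#' [select_hubs()]); a node reaching no DEG gets `NA` and can never be a hub.
#'
#' @param node Node name.
#' @param subnet A named `igraph`.
#' @param deg_nodes Character vector of DEG node names in the subnet.
#' @return Mean distance (numeric scalar, possibly `NA`).
#' @export
avg_distance_to_degs <- function(node, subnet, deg_nodes) {
  stopifnot(igraph::is_igraph(subnet))
  targets <- setdiff(intersect(deg_nodes, igraph::V(subnet)$name), node)
  if (!length(targets)) stop("no DEG node (other than `node`) in the subnetwork")
  d <- igraph::distances(subnet, v = node, to = targets)
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Flag hub genes within a module
#'
#' A module member is a hub when its average shortest-path distance to the
#' DEGs is strictly below the module's lower quartile of such distances
#' *and* its degree in the analysis subnetwork reaches `degree_min`. The
#' default comparison is `>= degree_min` (reported hub degrees in practice
#' include the cutoff value itself); `strict_degree = TRUE` switches to a
#' strict `>`.
#'
#' @param module Character vector of module node names, or a module entry
#'   from [detect_modules()].
#' @param subnet The analysis subnetwork (`igraph`).
#' @param deg_nodes Character vector of DEG node names.
#' @param degree_min Degree cutoff (default 6).
#' @param strict_degree Use `degree > degree_min` instead of `>=`.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A `HubReport` data frame (`node`, `avg_dist_to_degs`, `sum_dist`,
#'   `n_reachable_degs`, `n_unreachable_degs`, `degree`, `is_hub`) with the
#'   lower-quartile cutoff in attribute `"quartile_cutoff"`.
#' @export
select_hubs <- function(module, subnet, deg_nodes, degree_min = 6L,
                        strict_degree = FALSE, quartile_type = 7) {
  if (is.list(module) && !is.null(module$nodes)) module <- module$nodes
  stopifnot(igraph::is_igraph(subnet), is.character(module))
  if (length(module) < 4L) {
    stop("module has fewer than 4 nodes; the lower quartile is ill-defined")
  }
  missing <- setdiff(module, igraph::V(subnet)$name)
  if (length(missing)) stop("module node(s) not in subnet: ", paste(missing, collapse = ", "))
  deg_nodes <- intersect(deg_nodes, igraph::V(subnet)$name)
  if (!length(deg_nodes)) stop("no DEG node in the subnetwork")

  dmat <- igraph::distances(subnet, v = module, to = deg_nodes)
  stats_per_node <- lapply(seq_along(module), function(i) {
    d <- dmat[i, setdiff(deg_nodes, module[i])]
    reach <- is.finite(d)
    list(avg = if (any(reach)) mean(d[reach]) else NA_real_,
         sum = if (any(reach)) sum(d[reach]) else NA_real_,
         n_reach = sum(reach), n_unreach = sum(!reach))
  })
  avg <- vapply(stats_per_node, `[[`, numeric(1), "avg")
  cutoff <- stats::quantile(avg, 0.25, na.rm = TRUE, type = quartile_type,
                            names = FALSE)
  degree <- igraph::degree(subnet, module)
  deg_ok <- if (strict_degree) degree > degree_min else degree >= degree_min
  is_hub <- !is.na(avg) & avg < cutoff & deg_ok

  out <- data.frame(
    node = module,
    avg_dist_to_degs = avg,
    sum_dist = vapply(stats_per_node, `[[`, numeric(1), "sum"),
    n_reachable_degs = vapply(stats_per_node, `[[`, numeric(1), "n_reach"),
    n_unreachable_degs = vapply(stats_per_node, `[[`, numeric(1), "n_unreach"),
    degree = as.integer(degree),
    is_hub = is_hub,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "quartile_cutoff") <- cutoff
  class(out) <- c("HubReport", class(out))
  out
}

#' @export
print.HubReport <- function(x, ...) {
  cat(sprintf("HubReport: %d nodes, lower-quartile cutoff %.3f, %d hub(s)\n",
              nrow(x), attr(x, "quartile_cutoff"), sum(x$is_hub)))
  print.data.frame(x, ...)
  invisible(x)
}
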