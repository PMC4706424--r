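#' Configuration for the multi-study expression simulator
#'
#' Describes a two-platform-group, multi-study cohort in the shape the
#' meta-analysis assumes: every study measures (a random panel of) the same
#' gene universe on the log2 scale, shares the same planted up/down-regulated
#' genes, and carries its own additive batch offset. The defaults emulate a
#' realistic multi-cohort microarray design: three studies per platform
#' group, 20 tumor vs 10 control samples each, log2 effect size 1.5
#' (fold change ~2.8) for planted genes, residual noise SD 0.7 and batch
#' SD 0.5 on the log2 scale.
#'
#' @param n_genes Number of genes in the universe (symbols `G0001`, ...).
#' @param n_studies_per_group Studies simulated per platform group (I and II).
#' @param samples_per_study Named vector `c(tumor = , control = )`.
#' @param planted_up,planted_down Named numeric vectors: names are gene
#'   symbols from the universe, values are positive log2 effect sizes.
#' @param batch_sd SD of the per-study additive batch offset (log2 units).
#' @param noise_sd Residual SD per measurement (log2 units).
#' @param baseline_mean,baseline_sd Gene baseline log2 means are drawn
#'   Normal(baseline_mean, baseline_sd), i.e. log-normal linear intensities
#'   on the scale typical of RMA-normalized arrays.
#' @param panel_overlap Fraction of the gene universe measured by each study
#'   (in (0, 1]); panels always contain the planted genes.
#' @param seed Integer seed; the simulator is a pure function of its config.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 500L,
                              n_studies_per_group = 3L,
                              samples_per_study = c(tumor = 20L, control = 10L),
                              planted_up = numeric(),
                              planted_down = numeric(),
                              batch_sd = 0.5,
                              noise_sd = 0.7,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              panel_overlap = 1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_studies_per_group >= 1)
  if (!all(c("tumor", "control") %in% names(samples_per_study)) ||
      any(samples_per_study[c("tumor", "control")] < 1)) {
    stop("samples_per_study must give positive 'tumor' and 'control' counts")
  }
  if (!(panel_overlap > 0 && panel_overlap <= 1)) {
    stop("panel_overlap must be in (0, 1]")
  }
  if (batch_sd < 0 || noise_sd < 0) stop("SDs must be non-negative")
  genes <- gene_universe(n_genes)
  for (pl in list(planted_up, planted_down)) {
    if (length(pl)) {
      if (is.null(names(pl)) || !all(nzchar(names(pl)))) {
        stop("planted gene vectors must be named by gene symbol")
      }
      if (!all(is.finite(pl))) stop("planted effect sizes must be finite")
      unknown <- setdiff(names(pl), genes)
      if (length(unknown)) {
        stop("planted gene(s) outside the simulated universe: ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  if (length(intersect(names(planted_up), names(planted_down)))) {
    stop("a gene cannot be planted both up and down")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_studies_per_group = as.integer(n_studies_per_group),
         samples_per_study = samples_per_study,
         planted_up = planted_up, planted_down = planted_down,
         batch_sd = batch_sd, noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         panel_overlap = panel_overlap, seed = as.integer(seed),
         genes = genes),
    class = "SimulationConfig")
}

gene_universe <- function(n_genes) {
  width <- max(4L, nchar(as.character(n_genes)))
  sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
}

#' Simulate a multi-study expression cohort
#'
#' Each study's log2 matrix is
#' `gene baseline + study batch offset + class effect (planted genes in tumor
#' samples only, sign per direction) + Gaussian noise`. Baselines are shared
#' across studies; batch offsets differ per study, creating exactly the
#' cross-study shift that rank-based meta-analysis is meant to tolerate.
#'
#' @param cfg A [simulation_config()].
#' @return List of [expression_study()] objects (groups I and II).
#' @export
simulate_expression_studies <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  planted <- c(names(cfg$planted_up), names(cfg$planted_down))
  effect <- stats::setNames(numeric(cfg$n_genes), cfg$genes)
  effect[names(cfg$planted_up)] <- cfg$planted_up
  effect[names(cfg$planted_down)] <- -cfg$planted_down
  n_t <- cfg$samples_per_study[["tumor"]]
  n_c <- cfg$samples_per_study[["control"]]
  panel_size <- max(ceiling(cfg$panel_overlap * cfg$n_genes), length(planted))

  withr::with_seed(cfg$seed, {
    baseline <- stats::setNames(
      stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd), cfg$genes)
    studies <- list()
    for (group in c("I", "II")) {
      for (s in seq_len(cfg$n_studies_per_group)) {
        study_id <- sprintf("%s_%d", group, s)
        free <- setdiff(cfg$genes, planted)
        extra <- panel_size - length(planted)
        panel <- sort(c(planted, if (extra > 0) sample(free, min(extra, length(free)))))
        batch <- stats::rnorm(1, 0, cfg$batch_sd)
        classes <- c(rep("tumor", n_t), rep("control", n_c))
        sample_ids <- sprintf("%s_%s%02d", study_id,
                              ifelse(classes == "tumor", "T", "C"),
                              c(seq_len(n_t), seq_len(n_c)))
        mu <- baseline[panel] + batch
        vals <- matrix(mu, nrow = length(panel), ncol = n_t + n_c)
        vals[, classes == "tumor"] <- vals[, classes == "tumor"] + effect[panel]
        vals <- vals + stats::rnorm(length(vals), 0, cfg$noise_sd)
        dimnames(vals) <- list(panel, sample_ids)
        studies[[study_id]] <- expression_study(
          study_id, group, vals, stats::setNames(classes, sample_ids))
      }
    }
    studies
  })
}

#' Configuration for the background-network simulator
#'
#' An Erdos-Renyi background with planted dense modules (each node set gets
#' internal edges with its own, higher, probability) and an optional planted
#' hub wired to a stated target set. The simple random background keeps the
#' density and cohesiveness thresholds of module detection meaningful; a
#' preferential-attachment background is available for exercising the degree
#' criterion.
#'
#' @param n_nodes Number of nodes (named `N001`, ... unless `nodes` given).
#' @param background_degree Mean degree of the random background.
#' @param planted_modules List of `list(nodes = <chr>, p_in = <prob>)`.
#' @param planted_hub Optional `list(node = <chr>, targets = <chr>)`; the hub
#'   is connected to every target.
#' @param model `"erdos_renyi"` (default) or `"preferential_attachment"`.
#' @param nodes Optional explicit node names.
#' @param seed Integer seed.
#' @return A `NetworkSimConfig` list.
#' @export
network_sim_config <- function(n_nodes,
                               background_degree = 2,
                               planted_modules = list(),
                               planted_hub = NULL,
                               model = c("erdos_renyi", "preferential_attachment"),
                               nodes = NULL,
                               seed = 1L) {
  model <- match.arg(model)
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 0, background_degree >= 0)
  if (is.null(nodes)) {
    width <- max(3L, nchar(as.character(max(n_nodes, 1L))))
    nodes <- sprintf(paste0("N%0", width, "d"), seq_len(n_nodes))
  }
  stopifnot(length(nodes) == n_nodes)
  p_bg <- if (n_nodes > 1) min(1, background_degree / (n_nodes - 1)) else 0
  for (m in planted_modules) {
    if (!all(c("nodes", "p_in") %in% names(m))) {
      stop("each planted module needs `nodes` and `p_in`")
    }
    if (!all(m$nodes %in% nodes)) stop("planted module node outside the graph")
    if (m$p_in <= p_bg) {
      stop("planted internal edge probability must exceed the background probability")
    }
  }
  # Two modules sharing >=2 nodes with different p_in would prescribe two
  # different probabilities for the same potential edges.
  if (length(planted_modules) > 1) {
    for (i in seq_along(planted_modules)[-1]) for (j in seq_len(i - 1)) {
      shared <- intersect(planted_modules[[i]]$nodes, planted_modules[[j]]$nodes)
      if (length(shared) >= 2 &&
          planted_modules[[i]]$p_in != planted_modules[[j]]$p_in) {
        stop("overlapping planted modules with contradictory edge probabilities")
      }
    }
  }
  if (!is.null(planted_hub)) {
    if (!all(c(planted_hub$node, planted_hub$targets) %in% nodes)) {
      stop("planted hub or target outside the graph")
    }
  }
  structure(
    list(n_nodes = n_nodes, nodes = nodes, background_degree = background_degree,
         p_background = p_bg, planted_modules = planted_modules,
         planted_hub = planted_hub, model = model, seed = as.integer(seed)),
    class = "NetworkSimConfig")
}

#' Simulate a background interaction network with planted structure
#'
#' @param cfg A [network_sim_config()].
#' @return A simple undirected named `igraph`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "NetworkSimConfig"))
  withr::with_seed(cfg$seed, {
    g <- if (cfg$n_nodes == 0) {
      igraph::make_empty_graph(0, directed = FALSE)
    } else if (cfg$model == "erdos_renyi") {
      igraph::sample_gnp(cfg$n_nodes, cfg$p_background)
    } else {
      igraph::sample_pa(cfg$n_nodes, m = max(1, round(cfg$background_degree / 2)),
                        directed = FALSE)
    }
    if (cfg$n_nodes > 0) igraph::V(g)$name <- cfg$nodes
    for (m in cfg$planted_modules) {
      pairs <- utils::combn(sort(m$nodes), 2)
      keep <- stats::runif(ncol(pairs)) < m$p_in
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      }
    }
    if (!is.null(cfg$planted_hub)) {
      tg <- setdiff(cfg$planted_hub$targets, cfg$planted_hub$node)
      g <- igraph::add_edges(g, as.vector(rbind(cfg$planted_hub$node, tg)))
    }
    igraph::simplify(g)
  })
}

#' Simulate an immunohistochemistry cohort
#'
#' Draws per-specimen staining-intensity grades (0-3) and percent-positive
#' values (0-100) from per-group Gaussian parameters, rounding/clipping to the
#' valid ranges. Groups with `n = 0` are absent from the output.
#'
#' @param group_params Data frame with columns `group`, `protein`, `n`,
#'   `intensity_mean`, `intensity_sd`, `percent_mean`, `percent_sd`.
#' @param seed Integer seed.
#' @return Data frame of IHC records (`specimen`, `group`, `protein`,
#'   `intensity`, `percent_positive`).
#' @export
simulate_ihc_cohort <- function(group_params, seed = 1L) {
  need <- c("group", "protein", "n", "intensity_mean", "intensity_sd",
            "percent_mean", "percent_sd")
  miss <- setdiff(need, names(group_params))
  if (length(miss)) stop("group_params missing column(s): ", paste(miss, collapse = ", "))
  if (any(group_params$intensity_sd < 0) || any(group_params$percent_sd < 0)) {
    stop("SDs must be non-negative")
  }
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(group_params)), function(i) {
      p <- group_params[i, ]
      if (p$n <= 0) return(NULL)
      intensity <- pmin(3, pmax(0, round(stats::rnorm(p$n, p$intensity_mean, p$intensity_sd))))
      percent <- pmin(100, pmax(0, stats::rnorm(p$n, p$percent_mean, p$percent_sd)))
      data.frame(
        specimen = sprintf("%s_%s_%02d", p$group, p$protein, seq_len(p$n)),
        group = p$group, protein = p$protein,
        intensity = as.integer(intensity),
        percent_positive = percent,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
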