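#' Pipeline configuration
#'
#' Collects every input and stage threshold for [run_pipeline()]. Studies may
#' be given either as [expression_study()] objects or as
#' `list(matrix = <path>, classes = <path>)` pairs, which are loaded with
#' [read_expression()]. Every threshold default equals the corresponding
#' stage default (pfp < 0.01, fold change >= 2, module size >= 7,
#' density >= 0.3, module p < 0.05, hub degree >= 6).
#'
#' @param studies_group_I,studies_group_II Lists of studies (objects or
#'   path pairs) for platform groups I and II.
#' @param edge_lists Character vector of edge-list paths, or list of
#'   `from`/`to` data frames.
#' @param testing_studies Optional list of independent studies for the
#'   validation stage.
#' @param gmt Optional path to a GMT file (or a named list of sets) for the
#'   enrichment stage.
#' @param fdr_thresh,fc_thresh DEG-calling thresholds.
#' @param n_perm Permutations for the pfp estimate.
#' @param min_size,min_density,alpha,overlap_merge,penalty Module-detection
#'   settings.
#' @param degree_min Hub degree cutoff.
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @param outdir Output directory for stage JSON/GraphML files.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(studies_group_I, studies_group_II, edge_lists,
                            testing_studies = list(), gmt = NULL,
                            fdr_thresh = 0.01, fc_thresh = 2.0,
                            n_perm = 1000L,
                            min_size = 7L, min_density = 0.3, alpha = 0.05,
                            overlap_merge = 0.8, penalty = 2,
                            degree_min = 6L,
                            seed, outdir) {
  if (missing(seed)) stop("`seed` is mandatory: the pfp stage is stochastic")
  stopifnot(fdr_thresh > 0, fdr_thresh <= 1, fc_thresh > 0, n_perm >= 100,
            min_size >= 1, min_density >= 0, min_density <= 1,
            alpha > 0, alpha <= 1, overlap_merge > 0, overlap_merge <= 1,
            penalty >= 0, degree_min >= 0)
  structure(
    list(studies_group_I = studies_group_I,
         studies_group_II = studies_group_II,
         edge_lists = edge_lists, testing_studies = testing_studies,
         gmt = gmt,
         fdr_thresh = fdr_thresh, fc_thresh = fc_thresh, n_perm = as.integer(n_perm),
         min_size = as.integer(min_size), min_density = min_density,
         alpha = alpha, overlap_merge = overlap_merge, penalty = penalty,
         degree_min = as.integer(degree_min),
         seed = as.integer(seed), outdir = outdir),
    class = "PipelineConfig")
}

resolve_studies <- function(studies, group) {
  lapply(studies, function(s) {
    if (inherits(s, "ExpressionStudy")) return(s)
    if (is.list(s) && all(c("matrix", "classes") %in% names(s))) {
      return(read_expression(s$matrix, s$classes, group))
    }
    stop("each study must be an ExpressionStudy or list(matrix=, classes=)")
  })
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full hub-gene discovery pipeline
#'
#' Stages, in order: rank-product DEG meta-analysis per platform group with
#' cross-group intersection; background-network integration and Steiner
#' subnetwork extraction; cohesiveness module detection; hub selection;
#' validated-rate computation on training and testing studies; gene-set
#' enrichment (when a GMT is configured, against the background of genes
#' measured in both platform groups). Each stage writes a JSON (the network
#' stage also a GraphML) under `outdir`; a manifest records the files, their
#' MD5 hashes and every threshold, so a rerun with the same config is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$outdir, name)

  ## stage 1: DEG meta-analysis
  degs <- run_stage("deg", {
    st_I <- resolve_studies(config$studies_group_I, "I")
    st_II <- resolve_studies(config$studies_group_II, "II")
    rp_I <- rank_product_analysis(st_I, config$n_perm, config$seed)
    rp_II <- rank_product_analysis(st_II, config$n_perm, config$seed + 2L)
    degs_I <- call_degs(rp_I, config$fdr_thresh, config$fc_thresh)
    degs_II <- call_degs(rp_II, config$fdr_thresh, config$fc_thresh)
    combined <- intersect_groups(degs_I, degs_II)
    write_report(list(
      group_I = list(up = degs_I$up, down = degs_I$down),
      group_II = list(up = degs_II$up, down = degs_II$down),
      combined = list(up = combined$up, down = combined$down),
      thresholds = list(fdr = config$fdr_thresh, fc = config$fc_thresh,
                        n_perm = config$n_perm, seed = config$seed)),
      out("degs.json"))
    list(combined = combined, studies_I = st_I, studies_II = st_II,
         rp_I = rp_I, rp_II = rp_II)
  })
  files <- c(files, out("degs.json"))

  ## stage 2: network integration + Steiner subnetwork
  net <- run_stage("network", {
    if (!length(config$edge_lists)) stop("no edge lists configured")
    background <- integrate_background(config$edge_lists)
    subnet <- analysis_subnetwork(background, degs$combined)
    export_graphml(subnet, out("subnet.graphml"))
    write_report(list(
      background = list(nodes = igraph::vcount(background),
                        edges = igraph::ecount(background)),
      subnet = list(nodes = igraph::vcount(subnet),
                    edges = igraph::ecount(subnet),
                    steiner_cost = attr(subnet, "steiner_cost")),
      terminals = sort(attr(subnet, "terminals")),
      unmapped = sort(attr(subnet, "unmapped"))),
      out("network.json"))
    subnet
  })
  files <- c(files, out("subnet.graphml"), out("network.json"))

  ## stage 3: module detection
  modules <- run_stage("modules", {
    mods <- detect_modules(net, config$min_size, config$min_density,
                           config$alpha, config$overlap_merge, config$penalty)
    write_report(lapply(unclass(mods), function(m) {
      list(id = m$id, nodes = m$nodes, density = m$density,
           cohesiveness = m$cohesiveness, p_value = m$p_value)
    }), out("modules.json"))
    mods
  })
  files <- c(files, out("modules.json"))

  ## stage 4: hub selection
  hubs <- run_stage("hubs", {
    deg_nodes <- intersect(c(degs$combined$up, degs$combined$down),
                           igraph::V(net)$name)
    reports <- lapply(modules, function(m) {
      if (length(m$nodes) < 4L) return(NULL)
      r <- select_hubs(m$nodes, net, deg_nodes, config$degree_min)
      list(module = m$id, quartile_cutoff = attr(r, "quartile_cutoff"),
           table = r)
    })
    reports <- reports[!vapply(reports, is.null, logical(1))]
    hub_genes <- sort(unique(unlist(lapply(reports, function(r) {
      r$table$node[r$table$is_hub]
    }))))
    write_report(list(
      modules = lapply(reports, function(r) {
        list(module = r$module, quartile_cutoff = r$quartile_cutoff,
             nodes = r$table)
      }),
      hub_genes = hub_genes), out("hubs.json"))
    list(reports = reports, hub_genes = hub_genes)
  })
  files <- c(files, out("hubs.json"))

  ## stage 5: validated rates on training + testing data
  validation <- run_stage("validation", {
    gene_dirs <- hub_directions(hubs$hub_genes, degs$combined, degs$rp_I)
    vt <- if (length(gene_dirs)) {
      validation_table(gene_dirs,
                       training_studies = c(degs$studies_I, degs$studies_II),
                       testing_studies = resolve_studies(config$testing_studies, "I"))
    } else {
      list(per_dataset = NULL, pooled = NULL)
    }
    write_report(list(per_dataset = vt$per_dataset, pooled = vt$pooled),
                 out("validation.json"))
    vt
  })
  files <- c(files, out("validation.json"))

  ## stage 6: gene-set enrichment
  enr <- run_stage("enrichment", {
    if (is.null(config$gmt)) {
      write_report(list(skipped = "no GMT configured"), out("enrichment.json"))
      NULL
    } else {
      sets <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
      bg <- intersect(
        unique(unlist(lapply(degs$studies_I, `[[`, "genes"))),
        unique(unlist(lapply(degs$studies_II, `[[`, "genes"))))
      deg_all <- intersect(c(degs$combined$up, degs$combined$down), bg)
      tab <- enrich(deg_all, bg, sets)
      write_report(tab, out("enrichment.json"))
      tab
    }
  })
  files <- c(files, out("enrichment.json"))

  files <- unique(files)
  manifest <- list(
    stages = c("deg", "network", "modules", "hubs", "validation", "enrichment"),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    config = list(fdr_thresh = config$fdr_thresh, fc_thresh = config$fc_thresh,
                  n_perm = config$n_perm, min_size = config$min_size,
                  min_density = config$min_density, alpha = config$alpha,
                  overlap_merge = config$overlap_merge, penalty = config$penalty,
                  degree_min = config$degree_min, seed = config$seed))
  write_report(manifest, out("manifest.json"))
  invisible(manifest)
}

# Direction attached to a hub gene for validation: the DEG direction when the
# gene is a DEG; otherwise the sign of its group-I meta fold change (a hub
# need not itself pass the DEG thresholds).
hub_directions <- function(hub_genes, combined_degs, rp_I) {
  if (!length(hub_genes)) return(stats::setNames(character(0), character(0)))
  dir <- stats::setNames(rep(NA_character_, length(hub_genes)), hub_genes)
  dir[hub_genes %in% combined_degs$up] <- "up"
  dir[hub_genes %in% combined_degs$down] <- "down"
  open <- names(dir)[is.na(dir)]
  if (length(open)) {
    fc <- stats::setNames(rp_I$table$fc, rp_I$table$gene)
    dir[open] <- ifelse(!is.na(fc[open]) & fc[open] < 1, "down", "up")
  }
  dir
}
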