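#' Demo pipeline configuration on the bundled toy fixture
#'
#' Builds a complete, fast end-to-end input set for [run_pipeline()]: six
#' training studies (three per platform group) and one independent testing
#' study are simulated into `dir` as TSV files with [write_expression()],
#' while the interaction network (a 30-protein toy with a 7-node
#' wheel module around a non-DEG hub, a 6-gene down-regulated chain and a
#' sparse background ring) and the gene-set collection come from the files
#' bundled under `inst/extdata/toy/`.
#'
#' The simulated cohort uses a 300-gene panel with six planted up-regulated
#' genes (the wheel periphery, log2 effect 2.2), six planted down-regulated
#' genes (the chain, log2 effect 2.2) and a mildly up-regulated hub gene
#' (`G0013`, log2 effect 0.8, below the fold-change threshold -- the
#' PDIA3-like situation where a hub is not itself a DEG), 8 tumor / 5
#' control samples per study, residual SD 0.5 and batch SD 0.5.
#'
#' @param dir Directory for the simulated study files and pipeline output.
#' @param seed Integer seed driving both the simulation and the pipeline.
#' @param n_perm Permutations for the pfp stage (default 200).
#' @return A [pipeline_config()] whose `outdir` is `file.path(dir, "results")`.
#' @export
demo_pipeline_config <- function(dir, seed = 1L, n_perm = 200L) {
  seed <- as.integer(seed)
  up <- stats::setNames(rep(2.2, 6), sprintf("G%04d", 1:6))
  down <- stats::setNames(rep(2.2, 6), sprintf("G%04d", 7:12))
  hub <- c(G0013 = 0.8)
  cfg <- simulation_config(
    n_genes = 300, n_studies_per_group = 3,
    samples_per_study = c(tumor = 8, control = 5),
    planted_up = c(up, hub), planted_down = down,
    batch_sd = 0.5, noise_sd = 0.5, seed = seed)
  train <- simulate_expression_studies(cfg)
  cfg_test <- cfg
  cfg_test$n_studies_per_group <- 1L
  cfg_test$seed <- seed + 1L
  test <- simulate_expression_studies(cfg_test)[["I_1"]]
  test$study_id <- "TEST_1"

  study_dir <- file.path(dir, "studies")
  dir.create(study_dir, showWarnings = FALSE, recursive = TRUE)
  as_paths <- function(st) {
    mp <- file.path(study_dir, paste0(st$study_id, "_matrix.tsv"))
    cp <- file.path(study_dir, paste0(st$study_id, "_classes.tsv"))
    write_expression(st, mp, cp)
    list(matrix = mp, classes = cp)
  }
  paths <- lapply(train, as_paths)
  test_paths <- as_paths(test)

  toy <- system.file("extdata", "toy", package = "hubnet")
  pipeline_config(
    studies_group_I = paths[grepl("^I_", names(paths))],
    studies_group_II = paths[grepl("^II_", names(paths))],
    edge_lists = file.path(toy, c("ppi_interactions_a.tsv",
                                  "ppi_interactions_b.sif")),
    testing_studies = list(test_paths),
    gmt = file.path(toy, "toy_sets.gmt"),
    n_perm = as.integer(n_perm),
    seed = seed,
    outdir = file.path(dir, "results"))
}
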