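#' Read a gene-level expression matrix and its sample classes
#'
#' The matrix file is a TSV whose header row holds sample ids and whose first
#' column holds gene symbols; the class file is a two-column TSV
#' (`sample`, `class`) mapping every sample id to `tumor` or `control`.
#' Symbols are upper-cased; duplicate rows are collapsed by per-sample mean.
#' Matrices are assumed to be on the log2 scale already (the scale RMA-style
#' normalization produces); set `log2_input = FALSE` for linear intensities,
#' which are then log2(x + 1)-transformed on load.
#'
#' @param matrix_path Path to the expression TSV.
#' @param class_path Path to the sample-class TSV.
#' @param platform_group `"I"` or `"II"`.
#' @param study_id Study label; defaults to the matrix file name.
#' @param log2_input Is the matrix already log2? Default `TRUE`.
#' @return An [expression_study()] object.
#' @export
read_expression <- function(matrix_path, class_path, platform_group,
                            study_id = tools::file_path_sans_ext(basename(matrix_path)),
                            log2_input = TRUE) {
  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("expression matrix needs a gene column plus >=1 sample")
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1]])
  if (!log2_input) values <- log2(values + 1)

  cls <- utils::read.table(class_path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(cls) < 2L) stop("class file must have columns: sample, class")
  class_of <- stats::setNames(as.character(cls[[2]]), as.character(cls[[1]]))
  expression_study(study_id, platform_group, values, class_of)
}

#' Write an expression study as TSV
#'
#' Writes the matrix (6 decimal places) and the two-column class table so that
#' [read_expression()] round-trips the study.
#'
#' @param study An [expression_study()] object.
#' @param matrix_path,class_path Output paths.
#' @export
write_expression <- function(study, matrix_path, class_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  m <- format(round(study$values, 6), trim = TRUE, scientific = FALSE)
  out <- cbind(gene = rownames(study$values), m)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = study$samples, class = unname(study$class_of[study$samples])),
    class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, class_path))
}

#' Read a protein-interaction edge list (two-column TSV or SIF)
#'
#' SIF lines are `source<TAB or space>interaction-type<TAB or space>target`;
#' TSV lines are `source<TAB>target`. Symbols are upper-cased; pair order is
#' preserved for provenance; confidence scores are not parsed.
#'
#' @param path Path to a `.tsv`/`.txt` (2 columns) or `.sif` (3 columns) file.
#' @return A data frame with columns `from` and `to`, one row per input pair.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  is_sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  split_on <- if (is_sif) "[\t ]+" else "\t"
  parts <- strsplit(lines, split_on)
  expected <- if (is_sif) 3L else 2L
  bad <- which(lengths(parts) != expected)
  if (length(bad)) {
    stop(sprintf("malformed line %d in '%s': expected %d fields, found %d",
                 which(keep)[bad[1]], path, expected, lengths(parts)[bad[1]]))
  }
  m <- do.call(rbind, parts)
  if (is_sif) m <- m[, c(1L, 3L), drop = FALSE]
  data.frame(from = canonicalize_symbols(m[, 1]),
             to = canonicalize_symbols(m[, 2]),
             stringsAsFactors = FALSE)
}

#' Read several edge lists at once
#'
#' @param paths Character vector of edge-list paths.
#' @return A list of `from`/`to` data frames, one per path.
#' @export
read_edge_lists <- function(paths) lapply(paths, read_edge_list)

#' Write an edge list as TSV or SIF
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`; SIF uses the interaction type `pp`.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- if (format == "sif") {
    paste(edges$from, "pp", edges$to, sep = "\t")
  } else {
    paste(edges$from, edges$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Member symbols are canonicalized like expression symbols.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in GMT: ", nms[duplicated(nms)][1])
  }
  sets <- lapply(parts, function(p) unique(canonicalize_symbols(p[-(1:2)])))
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), nms)
  sets
}

#' Write a result object as schema-stable JSON
#'
#' @param x Any list-like result object.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Export / import a network as GraphML
#'
#' GraphML carries node attributes (e.g. `is_deg`, `direction`, `is_hub`)
#' alongside the topology.
#'
#' @param network An `igraph` object.
#' @param path Output (or input) path.
#' @export
export_graphml <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("id" %in% igraph::vertex_attr_names(g) &&
      !("name" %in% igraph::vertex_attr_names(g))) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  g
}

#' Read / write an IHC score table
#'
#' The TSV has columns `specimen`, `group`, `protein`, `intensity`,
#' `percent_positive`.
#'
#' @param path Path to the TSV.
#' @return Data frame of IHC records.
#' @export
read_ihc <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("specimen", "group", "protein", "intensity", "percent_positive")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("IHC table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_ihc
#' @param records Data frame of IHC records.
#' @export
write_ihc <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
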