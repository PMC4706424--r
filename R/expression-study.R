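#' Construct an expression study
#'
#' An `ExpressionStudy` bundles one normalized, gene-level log2 expression
#' matrix (genes x samples) with its tumor/control sample classes and the
#' platform-group tag used to decide which studies are meta-analyzed together.
#'
#' Gene symbols are canonicalized (upper case, whitespace stripped); duplicate
#' symbols after canonicalization are collapsed by per-sample mean, matching
#' the behaviour of [read_expression()].
#'
#' @param study_id Character scalar identifying the study.
#' @param platform_group `"I"` or `"II"`.
#' @param values Numeric matrix of log2 intensities with gene symbols as row
#'   names and sample ids as column names.
#' @param class_of Named character vector mapping every sample id to
#'   `"tumor"` or `"control"`.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(study_id, platform_group, values, class_of) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  platform_group <- match.arg(platform_group, c("I", "II"))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene symbols as rownames and sample ids as colnames")
  }
  rownames(values) <- canonicalize_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    values <- collapse_duplicate_genes(values)
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")

  samples <- colnames(values)
  missing_class <- setdiff(samples, names(class_of))
  if (length(missing_class)) {
    stop("sample(s) missing from class table: ", paste(missing_class, collapse = ", "))
  }
  extra <- setdiff(names(class_of), samples)
  if (length(extra)) {
    stop("class table sample(s) absent from matrix: ", paste(extra, collapse = ", "))
  }
  class_of <- class_of[samples]
  if (!all(class_of %in% c("tumor", "control"))) {
    stop("sample classes must be 'tumor' or 'control'")
  }
  counts <- table(factor(class_of, levels = c("tumor", "control")))
  if (any(counts < 2)) {
    warning("study '", study_id, "' has fewer than 2 samples in a class (",
            paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  structure(
    list(study_id = study_id, platform_group = platform_group,
         genes = rownames(values), samples = samples,
         values = values, class_of = class_of),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s' (group %s): %d genes x %d samples (%d tumor / %d control)\n",
              x$study_id, x$platform_group, length(x$genes), length(x$samples),
              sum(x$class_of == "tumor"), sum(x$class_of == "control")))
  invisible(x)
}

# Upper-case and strip whitespace; deliberately no alias resolution
# (symbol aliasing such as BGH3/TGFBI is documented, not rewritten).
canonicalize_symbols <- function(x) toupper(trimws(x))

# Collapse duplicate gene rows by per-sample mean.
collapse_duplicate_genes <- function(values) {
  grp <- rownames(values)
  sums <- rowsum(values, grp)
  n <- as.vector(table(grp)[rownames(sums)])
  sums / n
}
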