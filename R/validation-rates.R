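#' Validated rate of a candidate gene in one study
#'
#' The fraction of tumor samples whose expression lies on the DEG-direction
#' side of the control mean: strictly above it for an up gene, strictly below
#' for a down gene (a tumor sample exactly at the control mean does not
#' validate). Comparison is on the stored log2 scale, equivalent to the
#' linear scale for this monotone threshold.
#'
#' @param study An [expression_study()] object.
#' @param gene Gene symbol.
#' @param direction `"up"` or `"down"`.
#' @return Fraction in `[0, 1]`, or `NA` when the gene is not measured;
#'   attributes `n_tumor` and `n_validated` carry the counts used.
#' @export
validated_rate <- function(study, gene, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(study, "ExpressionStudy"))
  gene <- canonicalize_symbols(gene)
  if (!(gene %in% rownames(study$values))) {
    return(structure(NA_real_, n_tumor = 0L, n_validated = 0L))
  }
  ctl <- study$values[gene, study$class_of == "control"]
  if (!length(ctl)) stop("study has no control sample")
  thr <- mean(ctl)
  tum <- study$values[gene, study$class_of == "tumor"]
  hits <- if (direction == "up") sum(tum > thr) else sum(tum < thr)
  structure(hits / length(tum), n_tumor = length(tum),
            n_validated = as.integer(hits))
}

#' Per-dataset fold changes and validated rates for candidate genes
#'
#' Computes, for each candidate gene and each training/testing study, the
#' linear fold change and the validated rate, plus pooled rates. Pooled rates
#' are count-pooled (`sum(concordant tumor samples) / sum(tumor samples)`),
#' not means of per-dataset rates.
#'
#' @param genes Named character vector: names are gene symbols, values their
#'   fixed directions (`"up"`/`"down"`) from the DEG stage.
#' @param training_studies,testing_studies Lists of [expression_study()]
#'   objects (either may be empty).
#' @return A `ValidationReport`: list with `per_dataset` (gene, study, role,
#'   fc, rate, n_tumor, n_validated) and `pooled` (gene, direction, plus
#'   rate/count columns for training, testing and overall).
#' @export
validation_table <- function(genes, training_studies = list(),
                             testing_studies = list()) {
  if (is.null(names(genes)) || !all(genes %in% c("up", "down"))) {
    stop("`genes` must be a named character vector of directions ('up'/'down')")
  }
  syms <- canonicalize_symbols(names(genes))
  dirs <- stats::setNames(unname(genes), syms)

  one_role <- function(studies, role) {
    do.call(rbind, lapply(studies, function(st) {
      fc <- study_fold_changes(st)
      do.call(rbind, lapply(syms, function(g) {
        r <- validated_rate(st, g, dirs[[g]])
        data.frame(gene = g, study = st$study_id, role = role,
                   fc = if (g %in% names(fc)) unname(fc[g]) else NA_real_,
                   rate = as.numeric(r),
                   n_tumor = attr(r, "n_tumor"),
                   n_validated = attr(r, "n_validated"),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  per <- rbind(one_role(training_studies, "training"),
               one_role(testing_studies, "testing"))

  pool <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(stats::setNames(rep(NA_real_, length(syms)), syms))
    }
    ok <- !is.na(df$rate)
    v <- tapply(df$n_validated[ok], df$gene[ok], sum)
    n <- tapply(df$n_tumor[ok], df$gene[ok], sum)
    r <- stats::setNames(rep(NA_real_, length(syms)), syms)
    r[names(v)] <- as.numeric(v) / as.numeric(n)
    r
  }
  pooled <- data.frame(
    gene = syms, direction = unname(dirs),
    rate_training = unname(pool(per[per$role == "training", , drop = FALSE])),
    rate_testing = unname(pool(per[per$role == "testing", , drop = FALSE])),
    rate_total = unname(pool(per)),
    stringsAsFactors = FALSE)
  structure(list(per_dataset = per, pooled = pooled), class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport (count-pooled rates):\n")
  print.data.frame(x$pooled, ...)
  invisible(x)
}
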