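#' Immunoreactivity score (IRS)
#'
#' Staining-intensity grade (0 negative, 1 weak, 2 moderate, 3 strong)
#' multiplied by the percentage of positive cells (0-100), giving a score in
#' [0, 300]. Grade 0 is admitted for negative staining (a reported group mean
#' of 0 requires a zero factor).
#'
#' @param intensity Integer grade(s) in `{0, 1, 2, 3}`.
#' @param percent_positive Percentage(s) in `[0, 100]`.
#' @return Numeric score(s) in `[0, 300]`.
#' @export
irs_score <- function(intensity, percent_positive) {
  if (!all(intensity %in% 0:3)) stop("intensity grade must be in {0, 1, 2, 3}")
  if (any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must be in [0, 100]")
  }
  intensity * percent_positive
}

#' Per-group, per-protein IHC score summary
#'
#' @param records Data frame of IHC records (`group`, `protein`, `intensity`,
#'   `percent_positive`).
#' @return Data frame with `group`, `protein`, `n`, `mean`, `sd` (sample SD,
#'   `NA` for a single record) of the IRS.
#' @export
group_summary <- function(records) {
  scores <- irs_score(records$intensity, records$percent_positive)
  key <- interaction(records$group, records$protein, drop = TRUE, sep = "\r")
  agg <- lapply(split(scores, key), function(v) {
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(group = parts[, 1], protein = parts[, 2],
                    do.call(rbind, agg), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$protein, out$group), , drop = FALSE]
}

#' Classical one-way ANOVA on scores by group
#'
#' `F = MS_between / MS_within` with its F-distribution p-value, via
#' [stats::lm()]/[stats::anova()]. When every group has zero internal
#' variance the statistic is undefined; `NA` is returned with a warning.
#'
#' @param scores Numeric vector of scores.
#' @param groups Group labels (coerced to factor), same length as `scores`.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
one_way_anova <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  fit <- suppressWarnings(stats::anova(stats::lm(scores ~ groups)))
  ss_tot <- sum(fit[, "Sum Sq"])
  if (fit["Residuals", "Sum Sq"] <= 1e-12 * max(ss_tot, 1)) {
    warning("zero within-group variance everywhere; F undefined")
    return(list(F = NA_real_, p = NA_real_,
                df = unname(fit$Df)))
  }
  list(F = fit["groups", "F value"], p = fit["groups", "Pr(>F)"],
       df = unname(fit$Df))
}

#' Pearson correlation with t-based two-sided p-value
#'
#' @param x,y Numeric vectors (>= 3 paired observations).
#' @return List with `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need >= 3 paired observations")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
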