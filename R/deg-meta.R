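#' Per-study linear fold changes
#'
#' `FC_g = 2^(mean(log2 tumor) - mean(log2 control))` per gene, the quantity
#' that is ranked within each study before rank aggregation.
#'
#' @param study An [expression_study()] object.
#' @return Named numeric vector of linear-scale fold changes.
#' @export
study_fold_changes <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  tum <- study$values[, study$class_of == "tumor", drop = FALSE]
  ctl <- study$values[, study$class_of == "control", drop = FALSE]
  if (!ncol(tum) || !ncol(ctl)) stop("study needs >=1 tumor and >=1 control sample")
  mt <- rowMeans(tum, na.rm = TRUE)
  mc <- rowMeans(ctl, na.rm = TRUE)
  if (any(!is.finite(mt)) || any(!is.finite(mc))) {
    stop("gene with no finite values in one class: ",
         paste(utils::head(names(which(!is.finite(mt) | !is.finite(mc)))), collapse = ", "))
  }
  2^(mt - mc)
}

#' Rank genes within one study
#'
#' Rank 1 is the most extreme gene in the requested direction (largest fold
#' change for `"up"`, smallest for `"down"`); ties receive average ranks.
#'
#' @param fc Named numeric vector of linear fold changes.
#' @param direction `"up"` or `"down"`.
#' @return Named numeric vector of ranks.
#' @export
rank_within_study <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(fc) < 2L) stop("need >=2 genes to rank")
  if (direction == "up") rank(-fc, ties.method = "average")
  else rank(fc, ties.method = "average")
}

#' Rank product
#'
#' Geometric mean of a gene's ranks across the `k` studies that measured it;
#' a small value means consistently extreme ranks.
#'
#' @param ranks Numeric vector of within-study ranks.
#' @return The rank product `(prod(ranks))^(1/k)`.
#' @export
rank_product <- function(ranks) {
  if (!length(ranks)) stop("empty rank list")
  exp(mean(log(ranks)))
}

# Build the gene x study rank matrix for one direction.
# Genes absent from a study are NA there and are ranked only among the
# genes that study measured.
rank_matrix <- function(studies, direction) {
  fcs <- lapply(studies, study_fold_changes)
  genes <- sort(unique(unlist(lapply(fcs, names))))
  rm <- matrix(NA_real_, length(genes), length(studies),
               dimnames = list(genes, vapply(studies, `[[`, "", "study_id")))
  for (j in seq_along(fcs)) {
    r <- rank_within_study(fcs[[j]], direction)
    rm[names(r), j] <- r
  }
  rm
}

# Core pfp estimator on a rank matrix. Null rank products are obtained by
# permuting each study's rank vector independently n_perm times; for a gene
# with observed RP r at position x in the observed ordering,
# pfp = #{null RP <= r} / (n_perm * x), then made monotone non-decreasing
# down the observed ranking and capped at 1. Observed-vs-null comparisons use
# a 1e-9 relative tolerance so exact rational ties in the discrete rank
# products are counted on the correct side despite floating-point rounding.
pfp_from_rank_matrix <- function(rank_mat, n_perm, seed) {
  if (n_perm < 100) stop("n_perm must be >= 100 for a usable pfp estimate")
  k <- rowSums(!is.na(rank_mat))
  ranked <- k >= 2
  logr <- log(rank_mat)
  obs_rp <- exp(rowSums(logr, na.rm = TRUE) / k)

  null_logsum <- matrix(0, nrow(rank_mat), n_perm)
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(rank_mat))) {
      idx <- which(!is.na(rank_mat[, j]))
      v <- logr[idx, j]
      if (length(idx) > 1L) {
        perm <- vapply(seq_len(n_perm), function(b) sample(v), numeric(length(idx)))
        null_logsum[idx, ] <- null_logsum[idx, ] + perm
      } else if (length(idx) == 1L) {
        null_logsum[idx, ] <- null_logsum[idx, ] + v
      }
    }
  })

  pfp <- rep(NA_real_, nrow(rank_mat))
  rp_out <- rep(NA_real_, nrow(rank_mat))
  if (any(ranked)) {
    rp_r <- obs_rp[ranked]
    null_rp <- exp(null_logsum[ranked, , drop = FALSE] / k[ranked])
    sorted_null <- sort(as.vector(null_rp))
    x <- rank(rp_r, ties.method = "max")
    cnt <- findInterval(rp_r * (1 + 1e-9), sorted_null)
    p <- cnt / (n_perm * x)
    ord <- order(rp_r)
    p[ord] <- cummax(p[ord])
    pfp[ranked] <- pmin(p, 1)
    rp_out[ranked] <- rp_r
  }
  data.frame(gene = rownames(rank_mat), k = k, rp = rp_out, pfp = pfp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation pfp estimate for one platform group and direction
#'
#' Estimates, per gene, the proportion of false predictions (pfp; a
#' permutation-based FDR) attached to its rank product across the studies of
#' one group. Genes measured in fewer than two studies are reported with
#' `NA` rank product and pfp (present but unranked).
#'
#' @param studies List of [expression_study()] objects (one platform group).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param direction `"up"` or `"down"`.
#' @return Data frame with columns `gene`, `k`, `rp`, `pfp`.
#' @export
estimate_pfp <- function(studies, n_perm = 1000L, seed = 1L,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  pfp_from_rank_matrix(rank_matrix(studies, direction), n_perm, seed)
}

#' Rank-product meta-analysis for one platform group
#'
#' Runs both directions and attaches the group-level fold change (geometric
#' mean across the studies measuring the gene, consistent with the log-scale
#' ranks).
#'
#' @inheritParams estimate_pfp
#' @return A `RankProductResult`: list with the per-gene `table`
#'   (`gene`, `k`, `fc`, `rp_up`, `pfp_up`, `rp_down`, `pfp_down`) and the
#'   permutation settings.
#' @export
rank_product_analysis <- function(studies, n_perm = 1000L, seed = 1L) {
  if (!length(studies)) stop("no studies supplied")
  up <- estimate_pfp(studies, n_perm, seed, "up")
  down <- estimate_pfp(studies, n_perm, seed + 1L, "down")
  fcs <- lapply(studies, study_fold_changes)
  logfc_sum <- stats::setNames(numeric(nrow(up)), up$gene)
  nfc <- stats::setNames(integer(nrow(up)), up$gene)
  for (fc in fcs) {
    logfc_sum[names(fc)] <- logfc_sum[names(fc)] + log2(fc)
    nfc[names(fc)] <- nfc[names(fc)] + 1L
  }
  tab <- data.frame(
    gene = up$gene, k = up$k,
    fc = 2^(logfc_sum / nfc),
    rp_up = up$rp, pfp_up = up$pfp,
    rp_down = down$rp, pfp_down = down$pfp,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 studies = vapply(studies, `[[`, "", "study_id")),
            class = "RankProductResult")
}

#' @export
print.RankProductResult <- function(x, ...) {
  cat(sprintf("RankProductResult: %d genes across %d studies (%s), n_perm = %d\n",
              nrow(x$table), length(x$studies),
              paste(x$studies, collapse = ", "), x$n_perm))
  invisible(x)
}

#' Construct a DEG set
#'
#' @param up,down Character vectors of gene symbols; must be disjoint.
#' @param provenance Optional list recording the thresholds used.
#' @return A `DEGSet`.
#' @export
deg_set <- function(up = character(), down = character(), provenance = list()) {
  up <- unique(canonicalize_symbols(up))
  down <- unique(canonicalize_symbols(down))
  if (length(intersect(up, down))) {
    stop("a gene cannot be both up- and down-regulated: ",
         paste(intersect(up, down), collapse = ", "))
  }
  structure(list(up = up, down = down, provenance = provenance), class = "DEGSet")
}

#' @export
print.DEGSet <- function(x, ...) {
  cat(sprintf("DEGSet: %d up, %d down\n", length(x$up), length(x$down)))
  invisible(x)
}

#' Call differentially expressed genes
#'
#' A gene is called up if `pfp_up < fdr_thresh` and its group fold change is
#' `>= fc_thresh` (inclusive); down if `pfp_down < fdr_thresh` and
#' `fc <= 1/fc_thresh`.
#'
#' @param rp A `RankProductResult`.
#' @param fdr_thresh pfp threshold (default 0.01; 0.05 also in common use).
#' @param fc_thresh Linear fold-change threshold (default 2).
#' @return A [deg_set()] with thresholds recorded in `provenance`.
#' @export
call_degs <- function(rp, fdr_thresh = 0.01, fc_thresh = 2.0) {
  stopifnot(inherits(rp, "RankProductResult"), fdr_thresh > 0, fc_thresh > 0)
  tab <- rp$table
  up <- tab$gene[!is.na(tab$pfp_up) & tab$pfp_up < fdr_thresh & tab$fc >= fc_thresh]
  down <- tab$gene[!is.na(tab$pfp_down) & tab$pfp_down < fdr_thresh &
                     tab$fc <= 1 / fc_thresh]
  deg_set(up, down,
          provenance = list(fdr_thresh = fdr_thresh, fc_thresh = fc_thresh,
                            n_perm = rp$n_perm, seed = rp$seed,
                            studies = rp$studies))
}

#' Intersect DEG calls from the two platform groups
#'
#' A gene survives only if called in both groups with the same direction.
#'
#' @param degs_I,degs_II [deg_set()] objects.
#' @return A [deg_set()] of the concordant intersection.
#' @export
intersect_groups <- function(degs_I, degs_II) {
  stopifnot(inherits(degs_I, "DEGSet"), inherits(degs_II, "DEGSet"))
  deg_set(intersect(degs_I$up, degs_II$up),
          intersect(degs_I$down, degs_II$down),
          provenance = list(group_I = degs_I$provenance,
                            group_II = degs_II$provenance))
}
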