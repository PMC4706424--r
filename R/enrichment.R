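#' Gene-set over-representation test
#'
#' One-sided hypergeometric upper-tail test per gene set:
#' `P(X >= k)` for `k` DEGs falling in a set of size `K` when `n` DEGs are
#' drawn from a background of `N` genes. Sets are intersected with the
#' background first; sets with zero overlap are excluded before
#' Benjamini-Hochberg correction across the tested sets.
#'
#' @param deg_genes Character vector of DEG symbols (must lie in the
#'   background).
#' @param background_genes Character vector: the measured gene universe.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param fdr_thresh FDR used to set the `significant` flag (default 0.05).
#' @return Data frame sorted by ascending FDR with columns `set`, `k`, `K`,
#'   `n`, `N`, `p`, `fdr`, `significant`, `genes` (overlap, comma-separated).
#' @export
enrich <- function(deg_genes, background_genes, sets, fdr_thresh = 0.05) {
  background <- unique(canonicalize_symbols(background_genes))
  if (!length(background)) stop("empty background")
  degs <- unique(canonicalize_symbols(deg_genes))
  stray <- setdiff(degs, background)
  if (length(stray)) {
    stop("DEG(s) not in the background: ", paste(utils::head(stray), collapse = ", "))
  }
  if (!length(sets)) stop("no gene sets supplied")

  N <- length(background)
  n <- length(degs)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(canonicalize_symbols(sets[[nm]])), background)
    K <- length(members)
    hit <- intersect(degs, members)
    k <- length(hit)
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_thresh
  out <- out[order(out$fdr, out$p, out$set), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "k", "K", "n", "N", "p", "fdr", "significant", "genes")]
}
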