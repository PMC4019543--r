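#' Signed fold changes between two sample groups
#'
#' Computes per-gene fold changes from a log2 expression matrix with the
#' signed convention common in toxicogenomics reporting: with
#' r = 2^(mean log2 treated - mean log2 control), the fold change is r when
#' r >= 1 and -1/r when r < 1, so it never falls in the open interval
#' (-1, 1) and equals 1 when the groups agree exactly.
#'
#' @param expr Log2 expression matrix (genes/probe sets x samples).
#' @param groups 0/1 (control/treated) labels named by (or parallel to) the
#'   columns of `expr`, or a list with elements `control` and `treated` of
#'   sample ids.
#' @param contrast Optional metadata list (e.g. dose, time) attached to the
#'   result.
#' @return Data frame `gene_id`, `log2_ratio`, `fold_change`, in row order
#'   of `expr`, with `contrast` as an attribute.
#' @export
fold_change <- function(expr, groups, contrast = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.list(groups) && !is.null(groups$control)) {
    ctrl <- groups$control
    trt <- groups$treated
  } else {
    if (!is.null(names(groups))) groups <- groups[colnames(expr)]
    groups <- as.integer(groups)
    ctrl <- colnames(expr)[groups == 0L]
    trt <- colnames(expr)[groups == 1L]
  }
  if (length(ctrl) == 0L || length(trt) == 0L) {
    stop("both groups need at least one sample")
  }
  lr <- rowMeans(expr[, trt, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  r <- 2^lr
  fc <- ifelse(r >= 1, r, -1 / r)
  out <- data.frame(gene_id = rownames(expr), log2_ratio = unname(lr),
                    fold_change = unname(fc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  out
}

#' Select differentially expressed genes by fold-change threshold
#'
#' The threshold applies to the magnitude of the signed fold change; it is
#' deliberately a required, explicit choice downstream (no silent default
#' in the pipeline driver).
#'
#' @param fc_table A [fold_change()] result.
#' @param threshold Minimum absolute fold change (>= 1).
#' @return Character vector of gene ids, sorted.
#' @export
select_differential <- function(fc_table, threshold = 2) {
  stopifnot(threshold >= 1)
  sort(fc_table$gene_id[abs(fc_table$fold_change) >= threshold])
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts the gene-set members among n genes drawn
#' without replacement from a background of N genes containing K members.
#' The sum is accumulated in log space for numerical stability.
#'
#' @param N Background size.
#' @param K Set size within the background.
#' @param n Foreground (differential) gene count.
#' @param k Observed overlap.
#' @return The p-value.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N (got N=", N, " K=", K, " n=", n, " k=", k, ")")
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  exp(m + log(sum(exp(logp - m))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values with monotonicity enforcement; thresholding the
#' adjusted values at alpha reproduces the classical step-up rejection
#' set. Input order is preserved.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Hypergeometric gene-set enrichment with FDR control
#'
#' Tests each gene set for over-representation of the foreground
#' (differential) genes against the background universe, adjusting across
#' all tested sets with Benjamini-Hochberg and flagging sets significant
#' at FDR < `alpha`. Sets are intersected with the background before
#' counting.
#'
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param foreground Character vector of differential genes; must be a
#'   subset of `background`.
#' @param background Character vector: the gene universe (typically the
#'   genes represented in the library file).
#' @param alpha FDR significance threshold (default 0.05).
#' @return Data frame `set`, `N`, `K`, `n`, `k`, `p_value`,
#'   `fdr_adjusted_p`, `significant`, sorted by raw p then set name.
#' @export
enrich_sets <- function(gene_sets, foreground, background, alpha = 0.05) {
  background <- unique(background)
  foreground <- unique(foreground)
  stray <- setdiff(foreground, background)
  if (length(stray)) {
    stop("foreground gene(s) absent from background: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  N <- length(background)
  n <- length(foreground)
  res <- data.frame(
    set = names(gene_sets),
    N = N,
    K = vapply(gene_sets, function(s) length(intersect(s, background)), 0L),
    n = n,
    k = vapply(gene_sets, function(s) length(intersect(s, foreground)), 0L),
    stringsAsFactors = FALSE)
  res$p_value <- mapply(function(K, k) hypergeom_upper(N, K, n, k),
                        res$K, res$k)
  res$fdr_adjusted_p <- bh_adjust(res$p_value)
  res$significant <- res$fdr_adjusted_p < alpha
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
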