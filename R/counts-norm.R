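#' Aggregate variant-level counts to gene level
#'
#' Gene expression is the sum of the counts of the gene's transcript
#' variants; per-sample totals are conserved exactly.
#'
#' @param counts integer matrix, variants x samples, rownames = variant ids.
#' @param pattern variant-suffix regex passed to \code{\link{variant_gene}}.
#' @return integer matrix, genes x samples.
#' @export
gene_counts <- function(counts, pattern = "_seq[0-9]+$") {
  genes <- variant_gene(rownames(counts), pattern = pattern, warn = FALSE)
  out <- rowsum(counts, genes)
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-sample expressed-gene sets by a minimum read count
#'
#' A gene counts as expressed in a sample when it has at least
#' \code{min_reads} mapped reads (default 5).  Operates on raw counts;
#' the rule predates normalization.
#'
#' @param counts gene-level count matrix.
#' @param min_reads minimum mapped reads (default 5).
#' @return named list of character vectors, one per sample.
#' @export
expressed_genes <- function(counts, min_reads = 5L) {
  lapply(setNames(seq_len(ncol(counts)), colnames(counts)),
         function(j) rownames(counts)[counts[, j] >= min_reads])
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per sample against a reference column, the
#' weighted mean of per-gene log2 ratios (library-size-scaled) after
#' trimming the most extreme \code{logratio_trim} fraction by M and
#' \code{abs_trim} fraction by average absolute expression; weights are the
#' inverse asymptotic binomial variances.  The reference is the column whose
#' upper quartile of scaled counts is closest to the mean upper quartile.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts gene-level count matrix (>= 2 samples).
#' @param logratio_trim two-sided trim fraction on M (default 0.3).
#' @param abs_trim two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts", call. = FALSE)
  uq <- apply(counts, 2L, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# TMM factor of sample `obs` against reference `ref` (single pair)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0L || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2 ^ (sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-nonzero genes of the ratio of the
#' sample's count to the gene's geometric mean across samples.  This is the
#' count normalization used on the heatmap/display path.
#'
#' @param counts gene-level count matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors_median_ratio <- function(counts) {
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep))
    stop("no gene with nonzero counts in all samples", call. = FALSE)
  sub <- counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  f <- apply(sub, 2L, function(x) median(x / geo))
  setNames(f, colnames(counts))
}
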