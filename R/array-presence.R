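#' Quantile normalization
#'
#' Forces every column of the matrix to share the same value multiset: the
#' per-rank means across columns.  Within-column rank order is preserved;
#' tied values within a column receive the mean of the values their ranks
#' would have been assigned.
#'
#' @param m numeric matrix (e.g. probe-level log2 intensities), no missing
#'   values.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(2, 4, 6), b = c(3, 5, 7)))
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("quantile_normalize: missing values", call. = FALSE)
  if (ncol(m) < 1L) stop("quantile_normalize: no columns", call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    v <- numeric(length(x))
    v[o] <- ref
    # ties: average the rank-assigned reference values within each tie group
    out[, j] <- stats::ave(v, x, FUN = mean)
  }
  out
}

#' Two-way median polish
#'
#' Decomposes a matrix into overall + row + column effects + residuals by
#' alternating row- and column-median sweeps (rows first).  Iteration stops
#' after \code{max_iter} sweeps or when the total absolute adjustment in a
#' sweep falls below \code{tol}.
#'
#' @param m numeric matrix.
#' @param max_iter maximum number of full sweeps (default 10).
#' @param tol convergence tolerance on the total absolute change per sweep
#'   (default 0.01).
#' @return list with \code{overall}, \code{row} (row effects), \code{col}
#'   (column effects), \code{residuals}.
#' @export
median_polish <- function(m, max_iter = 10L, tol = 0.01) {
  r <- m
  overall <- 0
  rowe <- numeric(nrow(m))
  cole <- numeric(ncol(m))
  for (it in seq_len(max_iter)) {
    rm_ <- apply(r, 1L, median)
    r <- r - rm_
    rowe <- rowe + rm_
    cm_ <- median(rowe)
    rowe <- rowe - cm_
    overall <- overall + cm_
    cm2 <- apply(r, 2L, median)
    r <- r - matrix(cm2, nrow(r), ncol(r), byrow = TRUE)
    cole <- cole + cm2
    rm2 <- median(cole)
    cole <- cole - rm2
    overall <- overall + rm2
    if (sum(abs(rm_)) + sum(abs(cm2)) + abs(cm_) + abs(rm2) < tol) break
  }
  list(overall = overall, row = rowe, col = cole, residuals = r)
}

#' Summarize probe-level values to probeset expression
#'
#' Per probeset, runs a two-way (probes x arrays) median polish on the
#' normalized log2 probe values and reports expression on each array as
#' overall effect + array effect - the summarization step of the RMA-style
#' pipeline.  Probesets with a single probe pass through unchanged.
#'
#' @param normalized numeric matrix of log2 probe values (rownames = probe
#'   ids) after \code{\link{quantile_normalize}}.
#' @param probes probe library data.frame mapping \code{probe_id} to
#'   \code{probeset_id}.
#' @param max_iter,tol forwarded to \code{\link{median_polish}}.
#' @return expression matrix, probesets x arrays (log2 scale).
#' @export
summarize_probesets <- function(normalized, probes, max_iter = 10L,
                                tol = 0.01) {
  idx <- match(rownames(normalized), probes$probe_id)
  if (anyNA(idx))
    stop("probe(s) in matrix missing from probe library", call. = FALSE)
  sets <- split(seq_len(nrow(normalized)), probes$probeset_id[idx])
  out <- matrix(NA_real_, length(sets), ncol(normalized),
                dimnames = list(names(sets), colnames(normalized)))
  for (i in seq_along(sets)) {
    sub <- normalized[sets[[i]], , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[i, ] <- sub
    } else {
      mp <- median_polish(sub, max_iter = max_iter, tol = tol)
      out[i, ] <- mp$overall + mp$col
    }
  }
  out
}

#' PANP presence p-values from negative probesets
#'
#' For each array, the expression values of the negative probesets (those
#' with no probe aligning to the target species' transcriptome) form an
#' empirical background distribution.  A probeset's presence p-value is the
#' interpolated empirical survivor function of that background evaluated at
#' the probeset's expression: expression at or below the smallest negative
#' value gives p = 1, above the largest gives p = 0, and tied background
#' values share the conservative (larger) p.
#'
#' @param expr expression matrix (probesets x arrays) from
#'   \code{\link{summarize_probesets}}.
#' @param negatives character vector of negative probeset ids (must be rows
#'   of \code{expr}).
#' @param min_negatives minimum background size per array (default 50).
#' @return matrix of p-values in [0, 1], same shape as \code{expr}.
#' @export
panp_pvalues <- function(expr, negatives, min_negatives = 50L) {
  negatives <- intersect(negatives, rownames(expr))
  p <- expr
  for (j in seq_len(ncol(expr))) {
    y <- expr[negatives, j]
    if (length(y) < min_negatives)
      stop("array '", colnames(expr)[j], "': only ", length(y),
           " negative probesets (need >= ", min_negatives, ")",
           call. = FALSE)
    p[, j] <- survivor_p(expr[, j], y)
  }
  p
}

# interpolated empirical survivor function: at each unique background value
# u_i the p is the fraction of background >= u_i; linear between knots;
# 1 at/below the minimum, 0 above the maximum
survivor_p <- function(x, background) {
  u <- sort(unique(background))
  n <- length(background)
  sbg <- sort(background)
  # fraction of background >= u_i  (ties share the larger p)
  pk <- (n - findInterval(u, sbg, left.open = TRUE)) / n
  if (length(u) == 1L) return(ifelse(x > u, 0, 1))
  stats::approx(u, pk, xout = x, yleft = 1, yright = 0,
                method = "linear")$y
}

#' Presence/marginal/absence calls from PANP p-values
#'
#' @param pvalues p-value matrix from \code{\link{panp_pvalues}}.
#' @param p_present p threshold for a Present call (default 0.02).
#' @param p_marginal p threshold for a Marginal call (default 0.04);
#'   p above it gives Absent.
#' @return character matrix of calls ("P", "M", "A"), same shape.
#' @examples
#' pa_calls(matrix(c(0.02, 0.021, 1), 3, 1,
#'                 dimnames = list(c("a", "b", "c"), "arr1")))
#' @export
pa_calls <- function(pvalues, p_present = 0.02, p_marginal = 0.04) {
  if (!(p_present > 0 && p_present <= p_marginal && p_marginal <= 1))
    stop("thresholds must satisfy 0 < p_present <= p_marginal <= 1",
         call. = FALSE)
  calls <- ifelse(pvalues <= p_present, "P",
                  ifelse(pvalues <= p_marginal, "M", "A"))
  calls
}
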