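#' Replicate-free differential expression via simulated-replicate noise
#'
#' NOISeq-sim-style comparison of two unreplicated samples.  Technical
#' replicates are simulated per sample by multinomial subsampling: each of
#' \code{nss} replicates draws a library of size \code{round(u * total)}
#' with \code{u ~ Uniform(pnr - v, pnr + v)} from the sample's gene
#' proportions.  All within-sample replicate pairs contribute per-gene
#' \code{(|M|, D)} points to a pooled noise cloud (M = log2 ratio,
#' D = absolute difference, both on normalized expression with zeros
#' replaced by \code{k}).  The signal statistic per gene is the (M, D) of
#' the two normalized samples, and the DE probability is the fraction of
#' noise points dominated by the gene: \code{|M*| <= |M_g|} and
#' \code{D* <= D_g} (non-strict, resolving ties toward higher probability).
#'
#' @param counts gene-level count matrix containing both samples.
#' @param sample_a,sample_b column names of the two samples; M > 0 means
#'   higher in \code{sample_a}.
#' @param norm_factors optional named normalization factors (e.g. from
#'   \code{\link{tmm_factors}}); 1 for absent samples.
#' @param pnr size of each simulated replicate as a fraction of the parent
#'   library (default 0.2).
#' @param nss number of simulated replicates per sample (default 5).
#' @param v half-width of the uniform jitter on \code{pnr} (default 0.02).
#' @param k replacement for zero counts (default 0.5).
#' @param seed integer seed (default 42).
#' @return list with \code{results} (data.frame \code{gene}, \code{M},
#'   \code{D}, \code{prob}) and \code{noise} (data.frame \code{absM},
#'   \code{D}).
#' @export
noiseq_sim <- function(counts, sample_a, sample_b, norm_factors = NULL,
                       pnr = 0.2, nss = 5L, v = 0.02, k = 0.5,
                       seed = 42L) {
  if (pnr - v <= 0) stop("pnr - v must be positive", call. = FALSE)
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(counts) || sum(counts[, s]) == 0)
      stop("empty or missing sample: ", s, call. = FALSE)
  xa <- counts[, sample_a]
  xb <- counts[, sample_b]
  fa <- norm_factor_of(norm_factors, sample_a)
  fb <- norm_factor_of(norm_factors, sample_b)

  with_stage_seed(seed, 7L, {
    noise <- rbind(noise_points(xa, pnr, nss, v, k),
                   noise_points(xb, pnr, nss, v, k))
    ea <- normalized_expression(xa, fa, k)
    eb <- normalized_expression(xb, fb, k)
    M <- log2(ea / eb)
    D <- abs(ea - eb)
    prob <- dominance_prob(abs(M), D, noise$absM, noise$D)
    list(results = data.frame(gene = rownames(counts), M = M, D = D,
                              prob = prob, stringsAsFactors = FALSE,
                              row.names = NULL),
         noise = noise)
  })
}

norm_factor_of <- function(norm_factors, s) {
  if (is.null(norm_factors)) return(1)
  if (!is.null(names(norm_factors)) && s %in% names(norm_factors))
    return(norm_factors[[s]])
  1
}

# expression scaled to reads-per-million of the effective library
# (library size x normalization factor); zero counts replaced by k first
normalized_expression <- function(x, f, k) {
  eff <- sum(x) * f
  x[x == 0] <- k
  x / eff * 1e6
}

# pooled (|M|, D) of all within-sample simulated replicate pairs
noise_points <- function(x, pnr, nss, v, k) {
  total <- sum(x)
  prop <- x / total
  reps <- matrix(0, length(x), nss)
  sizes <- numeric(nss)
  for (r in seq_len(nss)) {
    sizes[r] <- round(runif(1, pnr - v, pnr + v) * total)
    reps[, r] <- rmultinom(1L, sizes[r], prop)
  }
  out <- list()
  for (r1 in seq_len(nss - 1L)) for (r2 in (r1 + 1L):nss) {
    e1 <- normalized_expression(reps[, r1], 1, k)
    e2 <- normalized_expression(reps[, r2], 1, k)
    out[[length(out) + 1L]] <- data.frame(absM = abs(log2(e1 / e2)),
                                          D = abs(e1 - e2))
  }
  do.call(rbind, out)
}

# fraction of noise points dominated by each (absM, D) signal point,
# non-strict dominance on both axes
dominance_prob <- function(absM, D, noise_absM, noise_D) {
  n <- length(noise_absM)
  ord <- order(noise_absM)
  nm <- noise_absM[ord]
  nd <- noise_D[ord]
  vapply(seq_along(absM), function(g) {
    im <- findInterval(absM[g], nm)  # noise points with absM <= signal
    if (im == 0L) return(0)
    sum(nd[seq_len(im)] <= D[g]) / n
  }, numeric(1))
}

#' Genes enriched in one sample across all its pairwise comparisons
#'
#' A gene is enriched in the focal sample when its DE probability exceeds
#' \code{q} \emph{and} it is upregulated in the focal sample (M > 0 with
#' contrasts emitted as (focal, other)) in \emph{all} supplied contrasts.
#'
#' @param contrasts named list of \code{noiseq_sim} \code{results}
#'   data.frames, each comparing the focal sample (first position, M > 0 =
#'   up in focal) with one other sample.
#' @param q probability threshold (default 0.9).
#' @param n_required number of contrasts required (default all supplied;
#'   the canonical design uses 3).
#' @return character vector of enriched gene ids.
#' @export
noiseq_enriched <- function(contrasts, q = 0.9,
                            n_required = length(contrasts)) {
  if (length(contrasts) < n_required)
    stop("missing contrast(s): need ", n_required, call. = FALSE)
  sets <- lapply(contrasts, function(res)
    res$gene[res$prob > q & res$M > 0])
  Reduce(intersect, sets)
}

#' Exact negative-binomial test for two unreplicated libraries
#'
#' Library sizes are equalized to their geometric mean by pseudo-counts
#' \code{y_i = round(x_i * sqrt(N1 N2) / N_i)}; conditional on the total
#' \code{s = y1 + y2}, each split \code{(a, s - a)} has probability
#' proportional to the product of two negative-binomial densities with
#' common mean \code{s / 2} and dispersion \code{phi}.  The two-sided
#' p-value sums the probabilities of all splits no more likely than the
#' observed one; at \code{phi = 0} this reduces to the conditional
#' binomial(s, 1/2) minimum-likelihood test.
#'
#' @param x1,x2 observed counts (non-negative integers, vectorized).
#' @param n1,n2 library sizes.
#' @param dispersion NB dispersion phi (default \code{0.8^2 = 0.64}).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' exact_nb_test(20, 2, 1e5, 1e5)        # strong difference
#' exact_nb_test(10, 10, 1e5, 1e5)       # identical -> 1
#' @export
exact_nb_test <- function(x1, x2, n1, n2, dispersion = 0.64) {
  if (any(!is.finite(c(x1, x2, n1, n2))) || any(c(x1, x2) < 0) ||
      any(c(n1, n2) <= 0))
    stop("counts must be >= 0 and library sizes > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  nstar <- sqrt(n1 * n2)
  y1 <- round(x1 * nstar / n1)
  y2 <- round(x2 * nstar / n2)
  vapply(seq_along(y1), function(i)
    nb_split_pvalue(y1[i], y2[i], dispersion), numeric(1))
}

# two-sided minimum-likelihood p for the split (y1, y2) of s = y1 + y2
nb_split_pvalue <- function(y1, y2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  logp <- if (phi == 0) {
    dbinom(a, s, 0.5, log = TRUE)
  } else {
    dnbinom(a, mu = s / 2, size = 1 / phi, log = TRUE) +
      dnbinom(s - a, mu = s / 2, size = 1 / phi, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[y1 + 1L]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (a validated wrapper around
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Enriched and DE gene sets from exact-test results
#'
#' The focal-enriched set contains genes upregulated in the focal sample
#' with FDR below \code{fdr_cut} in \emph{all} focal contrasts.  Among the
#' non-focal pairwise comparisons one pair may be designated special
#' (canonically the egg-vs-central comparison): for that pair the raw
#' p-value threshold \code{raw_cut} substitutes for the FDR rule.  The union
#' of all pairwise-DE genes is returned alongside.
#'
#' @param focal_contrasts named list of data.frames (\code{gene},
#'   \code{logFC}, \code{p}, \code{fdr}), one per focal-vs-other
#'   comparison, logFC > 0 = up in focal.
#' @param other_contrasts optional named list of the remaining pairwise
#'   comparisons in the same format.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param raw_cut raw p threshold for the special pair (default 0.001).
#' @param special_pair name (in \code{other_contrasts}) of the pair tested
#'   on raw p instead of FDR; \code{NULL} for none.
#' @return list with \code{enriched} (character vector) and
#'   \code{de_union} (character vector over all supplied contrasts).
#' @export
exact_test_enriched <- function(focal_contrasts, other_contrasts = list(),
                                fdr_cut = 0.05, raw_cut = 0.001,
                                special_pair = NULL) {
  check_de_cols <- function(df, nm) {
    if (!all(c("gene", "logFC", "p", "fdr") %in% names(df)))
      stop("contrast '", nm, "': needs columns gene, logFC, p, fdr",
           call. = FALSE)
  }
  Map(check_de_cols, focal_contrasts, names(focal_contrasts))
  Map(check_de_cols, other_contrasts, names(other_contrasts))
  enriched <- Reduce(intersect, lapply(focal_contrasts, function(df)
    df$gene[df$logFC > 0 & df$fdr < fdr_cut]))
  de_of <- function(df, nm) {
    if (!is.null(special_pair) && identical(nm, special_pair))
      df$gene[df$p < raw_cut]
    else
      df$gene[df$fdr < fdr_cut]
  }
  all_contrasts <- c(focal_contrasts, other_contrasts)
  de_union <- unique(unlist(Map(de_of, all_contrasts,
                                names(all_contrasts)),
                            use.names = FALSE))
  list(enriched = enriched, de_union = de_union)
}
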